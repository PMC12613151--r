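# Per-class calibration files: a YAML mapping of class -> {c1, c2,
# r_squared, n_points, source}. The packaged default carries the published
# PC/PE/PS coefficients. Classes without a fitted calibration (e.g. PA, PG,
# PI) never borrow one silently: look-ups fail unless the caller supplies a
# calibration explicitly.

#' Packaged default sn-ratio calibrations
#'
#' Published per-class coefficients: PC (c1 0.40, c2 1.91),
#' PE (0.38, 1.66) and PS (0.72, 1.33), derived from calibration mixtures
#' of sn-isomer standard pairs at seven SNA:SNB mixing ratios.
#'
#' @return named list of [sn_calibration()] objects keyed by class.
#' @export
default_sn_calibrations <- function() {
  path <- system.file("extdata", "sn_calibrations.yaml", package = "snlipid",
                      mustWork = TRUE)
  read_sn_calibrations(path)
}

#' Read sn-ratio calibrations from a YAML file
#'
#' @param path YAML file: top-level mapping class -> keys `c1`, `c2` and
#'   optionally `r_squared`, `n_points`, `source`.
#' @return named list of `sn_calibration` objects.
#' @export
read_sn_calibrations <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw) || is.null(names(raw)))
    stop_snlipid("io", "calibration file must be a mapping of class -> coefficients")
  out <- lapply(names(raw), function(cls) {
    rec <- raw[[cls]]
    for (key in c("c1", "c2")) {
      if (is.null(rec[[key]]))
        stop_snlipid("io", "calibration for class %s lacks key '%s'", cls, key)
    }
    sn_calibration(cls, c1 = rec$c1, c2 = rec$c2,
                   r_squared = rec$r_squared %||% NA_real_,
                   n_points = rec$n_points %||% NA_integer_,
                   source = rec$source %||% path)
  })
  names(out) <- names(raw)
  out
}

#' Write sn-ratio calibrations to a YAML file
#'
#' @param calibrations named list of `sn_calibration` objects.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_sn_calibrations <- function(calibrations, path) {
  stopifnot(is.list(calibrations), !is.null(names(calibrations)))
  payload <- lapply(calibrations, function(cal) {
    stopifnot(inherits(cal, "sn_calibration"))
    rec <- list(c1 = cal$c1, c2 = cal$c2, source = cal$source)
    if (!is.na(cal$r_squared)) rec$r_squared <- cal$r_squared
    if (!is.na(cal$n_points)) rec$n_points <- cal$n_points
    rec
  })
  yaml::write_yaml(payload, path)
  invisible(path)
}

#' Look up the calibration for a lipid class
#'
#' @param lipid_class class string, or a `lipid_annotation`.
#' @param calibrations named list of calibrations; defaults to the packaged
#'   set. A class absent from the list is an error — calibrations are never
#'   borrowed across classes implicitly.
#' @return an `sn_calibration`.
#' @export
sn_calibration_for <- function(lipid_class,
                               calibrations = default_sn_calibrations()) {
  if (inherits(lipid_class, "lipid_annotation"))
    lipid_class <- lipid_class$lipid_class
  cal <- calibrations[[lipid_class]]
  if (is.null(cal))
    stop_snlipid("contract",
      "no sn-ratio calibration for class %s; supply one explicitly",
      lipid_class)
  cal
}

`%||%` <- function(a, b) if (is.null(a)) b else a
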