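# Scheduled PRM target lists for trapped-ion-mobility acquisition: each
# target is a box in retention time x m/z x mobility with a collision
# energy. Defaults follow the validated acquisition windows: 1 Da isolation,
# 60 s total RT window, 0.03 V·s/cm² total mobility window, 45 eV.

.MOBILITY_RANGE <- list(positive = c(0.55, 1.87), negative = c(0.55, 1.86))
.MZ_RANGE <- c(100, 1350)

#' Build a scheduled PRM target list from 4D lipid descriptors
#'
#' One scheduled acquisition entry per descriptor row, applying the default
#' windows (center ± half-window) and validating every field against the
#' instrument scan ranges. For PA, PI and PS the carboxylate fragments are
#' weak at the standard collision energy, so a higher per-class energy may
#' be supplied via `ce_overrides`.
#'
#' @param descriptors data frame with columns `lipid` (shorthand name),
#'   `mz` (precursor m/z, Da), `rt` (seconds), `mobility` (1/K0, V·s/cm²)
#'   and `polarity` ("positive"/"negative"); optional `ce` per row.
#' @param isolation_width precursor isolation width in Da.
#' @param rt_window total RT window in seconds (applied as center ± half).
#' @param mobility_window total mobility window in V·s/cm².
#' @param collision_energy default collision energy in eV.
#' @param ce_overrides named numeric vector of per-class collision energies,
#'   e.g. `c(PS = 55)`.
#' @return a `prm_target_list` data frame: `lipid`, `precursor_mz`,
#'   `isolation_width`, `rt_center`, `rt_start`, `rt_stop`,
#'   `mobility_center`, `mobility_start`, `mobility_stop`,
#'   `collision_energy`, `polarity`.
#' @export
build_target_list <- function(descriptors, isolation_width = 1,
                              rt_window = 60, mobility_window = 0.03,
                              collision_energy = 45,
                              ce_overrides = NULL) {
  descriptors <- as.data.frame(descriptors)
  need <- c("lipid", "mz", "rt", "mobility", "polarity")
  if (!all(need %in% names(descriptors)))
    stop_snlipid("contract", "descriptors need columns %s",
                 paste(need, collapse = ", "))
  if (rt_window <= 0 || mobility_window <= 0)
    stop_snlipid("contract", "windows must be positive")
  out_cols <- c("lipid", "precursor_mz", "isolation_width", "rt_center",
                "rt_start", "rt_stop", "mobility_center", "mobility_start",
                "mobility_stop", "collision_energy", "polarity")
  if (nrow(descriptors) == 0L) {
    out <- as.data.frame(stats::setNames(
      c(list(character()), rep(list(numeric()), 9), list(character())),
      out_cols))
    class(out) <- c("prm_target_list", "data.frame")
    return(out)
  }

  errs <- character()
  for (i in seq_len(nrow(descriptors))) {
    row <- descriptors[i, ]
    pol <- as.character(row$polarity)
    if (!pol %in% names(.MOBILITY_RANGE)) {
      errs <- c(errs, sprintf("row %d (%s): unknown polarity '%s'",
                              i, row$lipid, pol))
      next
    }
    if (is.na(row$mz) || row$mz < .MZ_RANGE[1] || row$mz > .MZ_RANGE[2])
      errs <- c(errs, sprintf(
        "row %d (%s): field mz = %s outside scan range [%g, %g]",
        i, row$lipid, row$mz, .MZ_RANGE[1], .MZ_RANGE[2]))
    rng <- .MOBILITY_RANGE[[pol]]
    if (is.na(row$mobility) || row$mobility < rng[1] || row$mobility > rng[2])
      errs <- c(errs, sprintf(
        "row %d (%s): field mobility = %s outside scan range [%g, %g]",
        i, row$lipid, row$mobility, rng[1], rng[2]))
    if (is.na(row$rt) || row$rt < 0)
      errs <- c(errs, sprintf("row %d (%s): field rt = %s invalid",
                              i, row$lipid, row$rt))
    # annotation must parse: a malformed name fails the row, not the run
    tryCatch(parse_lipid(as.character(row$lipid)),
             error = function(e) {
               errs <<- c(errs, sprintf("row %d: %s", i, conditionMessage(e)))
             })
  }
  if (length(errs) > 0L)
    stop_snlipid("validation", "descriptor validation failed:\n  %s",
                 paste(errs, collapse = "\n  "))

  ce <- if ("ce" %in% names(descriptors) && !all(is.na(descriptors$ce))) {
    ifelse(is.na(descriptors$ce), collision_energy, descriptors$ce)
  } else rep(collision_energy, nrow(descriptors))
  if (!is.null(ce_overrides)) {
    cls <- vapply(as.character(descriptors$lipid),
                  function(s) parse_lipid(s)$lipid_class, character(1))
    hit <- cls %in% names(ce_overrides)
    ce[hit] <- ce_overrides[cls[hit]]
  }

  out <- data.frame(
    lipid = as.character(descriptors$lipid),
    precursor_mz = descriptors$mz,
    isolation_width = isolation_width,
    rt_center = descriptors$rt,
    rt_start = descriptors$rt - rt_window / 2,
    rt_stop = descriptors$rt + rt_window / 2,
    mobility_center = descriptors$mobility,
    mobility_start = descriptors$mobility - mobility_window / 2,
    mobility_stop = descriptors$mobility + mobility_window / 2,
    collision_energy = as.numeric(ce),
    polarity = as.character(descriptors$polarity),
    row.names = NULL)
  class(out) <- c("prm_target_list", "data.frame")
  out
}

#' Scheduled-target concurrency over retention time
#'
#' Counts, per RT bin, how many targets' scheduling windows cover the bin
#' center — a direct check on whether the instrument duty cycle can serve
#' every scheduled target.
#'
#' @param targets a [build_target_list()] result (needs `rt_start`,
#'   `rt_stop`).
#' @param bin_seconds RT bin width in seconds.
#' @return list with `max_concurrent` and a data frame `histogram`
#'   (`rt_bin` center, `n_targets`).
#' @export
schedule_concurrency <- function(targets, bin_seconds = 1) {
  targets <- as.data.frame(targets)
  if (nrow(targets) == 0L)
    return(list(max_concurrent = 0L,
                histogram = data.frame(rt_bin = numeric(),
                                       n_targets = integer())))
  stopifnot(all(c("rt_start", "rt_stop") %in% names(targets)),
            bin_seconds > 0)
  lo <- min(targets$rt_start); hi <- max(targets$rt_stop)
  centers <- seq(lo + bin_seconds / 2, hi, by = bin_seconds)
  counts <- vapply(centers, function(t) {
    sum(targets$rt_start <= t & targets$rt_stop >= t)
  }, integer(1))
  list(max_concurrent = max(counts),
       histogram = data.frame(rt_bin = centers, n_targets = counts))
}

#' Write a target list as vendor-neutral CSV
#'
#' Deterministic row order (by polarity, then RT, then m/z) and fixed float
#' formatting so repeated exports are byte-identical.
#'
#' @param targets a `prm_target_list`.
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_target_list <- function(targets, path) {
  targets <- as.data.frame(targets)
  ord <- order(targets$polarity, targets$rt_center, targets$precursor_mz,
               targets$lipid)
  targets <- targets[ord, , drop = FALSE]
  num <- vapply(targets, is.numeric, logical(1))
  targets[num] <- lapply(targets[num], function(x) sprintf("%.6f", x))
  utils::write.csv(targets, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a target list CSV written by [write_target_list()]
#'
#' @param path CSV path.
#' @return a `prm_target_list` data frame.
#' @export
read_target_list <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  num <- setdiff(names(out), c("lipid", "polarity"))
  out[num] <- lapply(out[num], as.numeric)
  class(out) <- c("prm_target_list", "data.frame")
  out
}
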