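# The "SN regression" model: an exponential calibration linking the SNA
# isomer fraction f in a two-isomer sn-positional mixture to the observed
# sn2/sn1 carboxylate fragment peak-area ratio,
#
#     ratio(f) = c1 * exp(c2 * f),    f in [0, 1].
#
# c1 is the ratio of the pure chain-swapped (SNB) isomer; c1*exp(c2) the
# ratio of the pure stated-order (SNA) isomer. The model is fitted
# log-linearly and inverted in closed form:
#
#     f = ln(ratio / c1) / c2,
#
# with estimates outside [0, 1] clamped and flagged (raw > 1 marks an
# isomerically pure SNA standard).

#' Construct an sn-ratio calibration from known coefficients
#'
#' Builds a calibration object directly from coefficients, e.g. the
#' published per-class values shipped with the package
#' (see [default_sn_calibrations()]). Use [fit_sn_calibration()] to fit
#' one from calibration-mixture measurements.
#'
#' @param lipid_class lipid class the calibration applies to (e.g. "PC").
#' @param c1 positive coefficient 1: the predicted sn2/sn1 ratio at SNA
#'   fraction 0 (pure SNB).
#' @param c2 coefficient 2: exponential slope per unit SNA fraction.
#' @param r_squared coefficient of determination of the log-linear fit,
#'   if known.
#' @param n_points number of calibration points behind the coefficients.
#' @param proportions_used SNA fractions of the calibration design.
#' @param source free-text provenance note.
#' @return an object of class `sn_calibration`.
#' @export
sn_calibration <- function(lipid_class, c1, c2, r_squared = NA_real_,
                           n_points = NA_integer_, proportions_used = NULL,
                           source = "user") {
  stopifnot(is.character(lipid_class), length(lipid_class) == 1L)
  if (!is.numeric(c1) || length(c1) != 1L || c1 <= 0)
    stop_snlipid("contract", "coefficient 1 must be a positive scalar")
  if (!is.numeric(c2) || length(c2) != 1L)
    stop_snlipid("contract", "coefficient 2 must be a numeric scalar")
  structure(list(lipid_class = lipid_class, c1 = c1, c2 = c2,
                 r_squared = r_squared, n_points = as.integer(n_points),
                 proportions_used = proportions_used, data = NULL,
                 source = source),
            class = "sn_calibration")
}

#' The seven-point SNA-fraction calibration design
#'
#' SNA:SNB volume mixing ratios 1:8, 1:4, 1:2, 1:1, 2:1, 4:1, 8:1 expressed
#' as SNA fractions of the mixture.
#'
#' @return sorted numeric vector of SNA fractions.
#' @export
calibration_proportions <- function() {
  c(1 / 9, 1 / 5, 1 / 3, 1 / 2, 2 / 3, 4 / 5, 8 / 9)
}

#' Fit the exponential sn-ratio calibration
#'
#' Ordinary least squares on the log-linearised model
#' `ln(ratio) = ln(c1) + c2 * f`. The log-linear fit is exactly invertible
#' and deterministic, which is why it is preferred over an iterative
#' nonlinear exponential fit.
#'
#' @param fractions SNA fractions in `[0, 1]`, at least 3 distinct values.
#' @param ratios observed mean sn2/sn1 peak-area ratios, all positive
#'   (average per-standard ratios across standards of a class first, with
#'   [average_sn_ratio()]).
#' @param lipid_class class label stored on the result.
#' @return an `sn_calibration` with fitted `c1`, `c2`, `r_squared`,
#'   `n_points`, `proportions_used` and the training data attached.
#' @seealso [predict.sn_calibration()], [sn_deconvolve()]
#' @export
fit_sn_calibration <- function(fractions, ratios, lipid_class = "PC") {
  fractions <- as.numeric(fractions)
  ratios <- as.numeric(ratios)
  if (length(fractions) != length(ratios))
    stop_snlipid("contract", "fractions and ratios must have equal length")
  keep <- !is.na(fractions) & !is.na(ratios)
  fractions <- fractions[keep]; ratios <- ratios[keep]
  if (length(fractions) < 3L || length(unique(fractions)) < 3L)
    stop_snlipid("fit", "need at least 3 distinct calibration fractions")
  if (any(ratios <= 0))
    stop_snlipid("fit", "all calibration ratios must be positive")
  if (any(fractions < 0 | fractions > 1))
    stop_snlipid("contract", "SNA fractions must lie in [0, 1]")

  fit <- stats::lm(log(ratios) ~ fractions)
  b <- stats::coef(fit)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((log(ratios) - mean(log(ratios)))^2)
  r2 <- if (tss < 1e-24) 1 else 1 - rss / tss

  out <- sn_calibration(lipid_class, c1 = unname(exp(b[1])),
                        c2 = unname(b[2]), r_squared = r2,
                        n_points = length(fractions),
                        proportions_used = sort(unique(fractions)),
                        source = "fitted")
  out$data <- data.frame(fraction = fractions, ratio = ratios)
  out
}

#' sn2/sn1 peak-area ratio of one standard
#'
#' @param sn2_area,sn1_area integrated peak areas of the sn2- and
#'   sn1-derived carboxylate fragments; both must be positive.
#' @param transition optional transition identity reported on error.
#' @return `sn2_area / sn1_area`.
#' @export
compute_sn_ratio <- function(sn2_area, sn1_area, transition = NULL) {
  if (!is.numeric(sn2_area) || !is.numeric(sn1_area))
    stop_snlipid("contract", "peak areas must be numeric")
  bad <- sn2_area <= 0 | sn1_area <= 0 | is.na(sn2_area) | is.na(sn1_area)
  if (any(bad)) {
    stop_snlipid("missing_fragment",
      "non-positive or missing fragment peak area%s",
      if (is.null(transition)) "" else paste0(" for transition ", transition),
      data = list(transition = transition))
  }
  sn2_area / sn1_area
}

#' Average per-standard sn2/sn1 ratios across a class
#'
#' The per-mixture ratio used for calibration is the arithmetic mean of the
#' ratios of all standards of a class, making the calibration independent of
#' acyl chain length and unsaturation.
#'
#' @param ratios non-empty numeric vector of positive per-standard ratios.
#' @return arithmetic mean.
#' @export
average_sn_ratio <- function(ratios) {
  ratios <- as.numeric(ratios)
  if (length(ratios) == 0L)
    stop_snlipid("contract", "cannot average an empty set of ratios")
  if (any(is.na(ratios) | ratios <= 0))
    stop_snlipid("contract", "all ratios must be positive")
  mean(ratios)
}

#' Predict sn2/sn1 ratios from SNA fractions
#'
#' Evaluates the forward model `c1 * exp(c2 * f)`.
#'
#' @param object an `sn_calibration`.
#' @param fractions SNA fractions in `[0, 1]`; defaults to the fractions the
#'   calibration was built on, or the standard design.
#' @param ... unused.
#' @return numeric vector of predicted ratios.
#' @export
predict.sn_calibration <- function(object, fractions = NULL, ...) {
  if (is.null(fractions)) {
    fractions <- object$proportions_used
    if (is.null(fractions)) fractions <- calibration_proportions()
  }
  fractions <- as.numeric(fractions)
  if (any(is.na(fractions) | fractions < 0 | fractions > 1))
    stop_snlipid("contract", "SNA fractions must lie in [0, 1]")
  object$c1 * exp(object$c2 * fractions)
}

#' Invert the calibration: apportion a mixture between sn isomers
#'
#' Solves `f = ln(ratio / c1) / c2` for each observed sn2/sn1 ratio and
#' reports SNA/SNB percentages. Raw estimates outside `[0, 1]` are clamped:
#' a raw estimate above 1 (ratio above the pure-SNA ratio `c1 * exp(c2)`)
#' flags the species as isomerically pure SNA (`pure_flag`); by symmetry a
#' raw estimate below 0 clamps to pure SNB. SNA and SNB percentages always
#' sum to exactly 100.
#'
#' @param ratio positive observed sn2/sn1 peak-area ratio(s).
#' @param calibration an `sn_calibration` with nonzero `c2`.
#' @return an `sn_deconvolution` data frame with columns `observed_ratio`,
#'   `sna_percent`, `snb_percent`, `clamped`, `pure_flag`.
#' @examples
#' cal <- default_sn_calibrations()$PC
#' sn_deconvolve(1.0396, cal) # about 50/50
#' @export
sn_deconvolve <- function(ratio, calibration) {
  stopifnot(inherits(calibration, "sn_calibration"))
  ratio <- as.numeric(ratio)
  if (any(is.na(ratio) | ratio <= 0))
    stop_snlipid("contract", "observed ratios must be positive")
  if (calibration$c2 == 0)
    stop_snlipid("contract",
      "calibration with zero coefficient 2 cannot be inverted")
  raw <- log(ratio / calibration$c1) / calibration$c2
  sna <- 100 * pmin(pmax(raw, 0), 1)
  out <- data.frame(observed_ratio = ratio, sna_percent = sna,
                    snb_percent = 100 - sna,
                    clamped = raw < 0 | raw > 1, pure_flag = raw > 1)
  class(out) <- c("sn_deconvolution", "data.frame")
  out
}

#' Isomeric purity from a phospholipase A2 digest
#'
#' PLA2 cleaves the sn2 acyl chain of a glycerophospholipid, leaving a lyso
#' species that carries the sn1 chain. In a digest of a nominally
#' sn-resolved standard, the share of total lyso signal carried by the
#' nominal sn1 chain therefore measures the standard's isomeric purity,
#' assuming equal detector response of the lyso products.
#'
#' @param lyso_areas named numeric vector of lyso peak areas; names are
#'   chain tokens such as `"16:0"`.
#' @param nominal the sn-resolved diacyl `lipid_annotation` of the standard.
#' @return purity in percent. If the nominal sn1 chain is absent from
#'   `lyso_areas`, returns 0 with a warning.
#' @export
pla2_purity <- function(lyso_areas, nominal) {
  stopifnot(inherits(nominal, "lipid_annotation"))
  if (nominal$level != "sn_position" || length(nominal$chains) != 2L)
    stop_snlipid("contract", "nominal standard must be an sn-resolved diacyl")
  lyso_areas <- lyso_areas[!is.na(lyso_areas)]
  if (length(lyso_areas) == 0L || all(lyso_areas <= 0))
    stop_snlipid("contract", "need at least one positive lyso peak area")
  sn1 <- format_fatty_acyl(nominal$chains[[1]])
  if (!sn1 %in% names(lyso_areas)) {
    warning(sprintf("nominal sn1 chain %s absent from lyso areas; purity 0",
                    sn1), call. = FALSE)
    return(0)
  }
  100 * unname(lyso_areas[[sn1]]) / sum(lyso_areas)
}

#' @export
print.sn_calibration <- function(x, digits = 4, ...) {
  cat(sprintf("sn-ratio calibration [%s]\n", x$lipid_class))
  cat(sprintf("  ratio(f) = %.*g * exp(%.*g * f)   (f = SNA fraction)\n",
              digits, x$c1, digits, x$c2))
  bits <- c(
    if (!is.na(x$r_squared))
      sprintf("r^2 (log-linear) = %.*g", digits, x$r_squared),
    if (!is.na(x$n_points)) sprintf("n = %d points", x$n_points))
  if (length(bits)) cat("  ", paste(bits, collapse = ", "), "\n", sep = "")
  cat(sprintf("  source: %s\n", x$source))
  invisible(x)
}

#' @export
coef.sn_calibration <- function(object, ...) {
  c(c1 = object$c1, c2 = object$c2)
}

#' @export
summary.sn_calibration <- function(object, ...) {
  out <- list(calibration = object,
              pure_snb_ratio = object$c1,
              pure_sna_ratio = object$c1 * exp(object$c2))
  class(out) <- "summary.sn_calibration"
  out
}

#' @export
print.summary.sn_calibration <- function(x, digits = 4, ...) {
  print(x$calibration, digits = digits)
  cat(sprintf("  predicted pure-isomer ratios: SNB %.*g, SNA %.*g\n",
              digits, x$pure_snb_ratio, digits, x$pure_sna_ratio))
  if (!is.null(x$calibration$data)) {
    cat("  calibration points:\n")
    print(x$calibration$data, digits = digits)
  }
  invisible(x)
}

#' @export
residuals.sn_calibration <- function(object, type = c("ratio", "log"), ...) {
  type <- match.arg(type)
  if (is.null(object$data))
    stop_snlipid("contract", "calibration carries no training data")
  pred <- predict(object, object$data$fraction)
  if (type == "ratio") object$data$ratio - pred
  else log(object$data$ratio) - log(pred)
}

#' @export
plot.sn_calibration <- function(x, n = 101, ...) {
  f <- seq(0, 1, length.out = n)
  graphics::plot(f, predict(x, f), type = "l",
                 xlab = "SNA fraction", ylab = "sn2/sn1 ratio",
                 main = sprintf("sn-ratio calibration [%s]", x$lipid_class),
                 ...)
  if (!is.null(x$data))
    graphics::points(x$data$fraction, x$data$ratio, pch = 19)
  invisible(x)
}

#' Simulate calibration-series ratios from a calibration
#'
#' Convenience `simulate()` method wrapping
#' [simulate_calibration_series()].
#'
#' @param object an `sn_calibration`.
#' @param nsim number of series to simulate.
#' @param seed seed for the noise model.
#' @param fractions design fractions; default the calibration's.
#' @param cv lognormal area noise CV in percent (0 = noiseless).
#' @param ... unused.
#' @return data frame of `sim`, `fraction`, `ratio`.
#' @export
simulate.sn_calibration <- function(object, nsim = 1, seed = NULL,
                                    fractions = NULL, cv = 0, ...) {
  if (is.null(fractions)) {
    fractions <- object$proportions_used
    if (is.null(fractions)) fractions <- calibration_proportions()
  }
  if (!is.null(seed)) set.seed(seed)
  out <- do.call(rbind, lapply(seq_len(nsim), function(i) {
    s <- simulate_calibration_series(object, proportions = fractions,
      noise = noise_model(if (cv > 0) "lognormal" else "none", cv = cv))
    cbind(sim = i, s)
  }))
  out
}
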