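# Internal-standard quantification and method-validation statistics.

#' Normalise an analyte peak area to its internal standard
#'
#' Quantification is single-point: the analyte area divided by the area of
#' the class-matched internal standard (ISTD), scaled by the spiked ISTD
#' amount.
#'
#' @param analyte_area analyte peak area.
#' @param istd_area ISTD peak area; a non-positive area marks the sample as
#'   failed (with a warning) rather than silently propagating.
#' @param istd_amount spiked ISTD amount (pmol or concentration units; the
#'   result inherits them).
#' @return data frame with `normalized_value`, `concentration`, `failed`.
#' @export
normalize_to_istd <- function(analyte_area, istd_area, istd_amount = 1) {
  stopifnot(is.numeric(analyte_area), is.numeric(istd_area),
            is.numeric(istd_amount))
  n <- max(length(analyte_area), length(istd_area))
  analyte_area <- rep_len(analyte_area, n)
  istd_area <- rep_len(istd_area, n)
  failed <- is.na(istd_area) | istd_area <= 0
  if (any(failed))
    warning(sprintf("%d sample(s) with non-positive ISTD area flagged as failed",
                    sum(failed)), call. = FALSE)
  nv <- ifelse(failed, NA_real_, analyte_area / istd_area)
  data.frame(normalized_value = nv, concentration = nv * istd_amount,
             failed = failed)
}

#' Coefficient of variation in percent
#'
#' `100 * sd / mean` with the sample (n-1) standard deviation.
#'
#' @param values numeric vector, length >= 2, nonzero mean.
#' @return CV in percent.
#' @export
compute_cv <- function(values) {
  values <- as.numeric(values)
  values <- values[!is.na(values)]
  if (length(values) < 2L)
    stop_snlipid("contract", "CV needs at least 2 values")
  m <- mean(values)
  if (m == 0) stop_snlipid("contract", "CV undefined for zero mean")
  100 * stats::sd(values) / m
}

#' Identify replicate outliers by narrow IQR fences
#'
#' Flags values outside `[Q1 - k*IQR, Q3 + k*IQR]` with quartiles by linear
#' interpolation between order statistics (`stats::quantile` type 7). The
#' default multiplier 0.1 is a deliberately stringent fence used to screen
#' low-reproducibility MS2 replicates; the conventional exploratory value
#' is 1.5.
#'
#' @param values numeric vector, length >= 4.
#' @param multiplier IQR fence multiplier `k`.
#' @return integer indices of outlying values (possibly empty).
#' @export
iqr_outliers <- function(values, multiplier = 0.1) {
  values <- as.numeric(values)
  if (length(values) < 4L)
    stop_snlipid("contract", "IQR outlier screen needs at least 4 values")
  q <- stats::quantile(values, c(0.25, 0.75), na.rm = TRUE, names = FALSE,
                       type = 7)
  iqr <- q[2] - q[1]
  which(values < q[1] - multiplier * iqr | values > q[2] + multiplier * iqr)
}

#' LOD and LOQ from a calibration dilution series
#'
#' Ordinary least squares of area on concentration; the limits follow the
#' residual-scatter convention `LOD = 3.3 * sigma / slope` and
#' `LOQ = 10 * sigma / slope`, with `sigma` the residual standard deviation
#' of the fit.
#'
#' @param series a data frame with columns `concentration` and `area`
#'   (e.g. a [simulate_dilution_series()] result), at least 5 distinct
#'   positive concentration levels.
#' @return list with `lod`, `loq`, `slope`, `intercept`, `sigma`,
#'   `r_squared`, `failed`. A non-positive slope returns a failure record
#'   (with warning) rather than meaningless limits.
#' @export
lod_loq <- function(series) {
  series <- as.data.frame(series)
  if (!all(c("concentration", "area") %in% names(series)))
    stop_snlipid("contract", "series needs columns concentration, area")
  keep <- stats::complete.cases(series[, c("concentration", "area")])
  series <- series[keep, ]
  if (length(unique(series$concentration)) < 5L)
    stop_snlipid("contract", "need at least 5 distinct concentration levels")
  if (any(series$concentration <= 0))
    stop_snlipid("contract", "concentrations must be positive")
  fit <- stats::lm(area ~ concentration, data = series)
  b <- stats::coef(fit)
  slope <- unname(b[2]); intercept <- unname(b[1])
  sigma <- sqrt(sum(stats::residuals(fit)^2) / stats::df.residual(fit))
  r2 <- {
    tss <- sum((series$area - mean(series$area))^2)
    if (tss < 1e-24) 1 else 1 - sum(stats::residuals(fit)^2) / tss
  }
  if (slope <= 0) {
    warning("non-positive calibration slope; LOD/LOQ not defined",
            call. = FALSE)
    return(list(lod = NA_real_, loq = NA_real_, slope = slope,
                intercept = intercept, sigma = sigma, r_squared = r2,
                failed = TRUE))
  }
  list(lod = 3.3 * sigma / slope, loq = 10 * sigma / slope, slope = slope,
       intercept = intercept, sigma = sigma, r_squared = r2, failed = FALSE)
}

#' MS1/MS2 quantification concordance
#'
#' The ratio of the MS2-based to the MS1-based normalised value for the same
#' species; concordant quantification lies in the closed interval
#' `[0.7, 1.3]`.
#'
#' @param ms1_value,ms2_value ISTD-normalised values from the MS1 precursor
#'   and MS2 quantifier workflows.
#' @param bounds concordance interval, closed on both ends.
#' @return data frame with `ratio` and `in_range`.
#' @export
ms1_ms2_concordance <- function(ms1_value, ms2_value, bounds = c(0.7, 1.3)) {
  stopifnot(is.numeric(ms1_value), is.numeric(ms2_value))
  if (any(ms1_value <= 0, na.rm = TRUE))
    stop_snlipid("contract", "MS1 normalised value must be positive")
  ratio <- ms2_value / ms1_value
  data.frame(ratio = ratio,
             in_range = ratio >= bounds[1] & ratio <= bounds[2])
}

#' Spike recovery in percent
#'
#' @param measured_pct measured abundance of the spiked species (percent).
#' @param expected_pct spiked-in abundance (percent), positive.
#' @return recovery in percent: `100 * measured / expected`.
#' @export
spike_recovery <- function(measured_pct, expected_pct) {
  if (any(expected_pct <= 0))
    stop_snlipid("contract", "expected spike abundance must be positive")
  100 * measured_pct / expected_pct
}

#' Choose the internal standard minimising replicate CV
#'
#' When several ISTDs are available for a class, the one yielding the
#' lowest coefficient of variation of the normalised analyte values across
#' replicates is selected.
#'
#' @param normalized_by_istd named list: for each candidate ISTD, the vector
#'   of ISTD-normalised analyte values across replicates (length >= 2).
#' @return list with `istd` (chosen name) and `cv` (named CVs of all
#'   candidates, percent).
#' @export
choose_istd <- function(normalized_by_istd) {
  stopifnot(is.list(normalized_by_istd), length(normalized_by_istd) >= 1L,
            !is.null(names(normalized_by_istd)))
  cvs <- vapply(normalized_by_istd, compute_cv, numeric(1))
  list(istd = names(cvs)[which.min(cvs)], cv = cvs)
}
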