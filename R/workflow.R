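#' Deconvolve a set of peak groups into sn-isomer percentages
#'
#' For every peak group with exactly two fragment rows (the sn1 and sn2
#' carboxylate transitions of a two-isomer mixture), computes the sn2/sn1
#' ratio, looks up the class calibration and inverts it.
#'
#' @param groups list of [peak_group()] objects (e.g. from
#'   [read_transition_report()]).
#' @param calibrations named list of calibrations per class; default the
#'   packaged set.
#' @return data frame with one row per group: `sample_id`, `precursor`,
#'   `observed_ratio`, `sna_percent`, `snb_percent`, `clamped`,
#'   `pure_flag`.
#' @export
deconvolve_sn_groups <- function(groups,
                                 calibrations = default_sn_calibrations()) {
  rows <- lapply(groups, function(g) {
    stopifnot(inherits(g, "peak_group"))
    if (nrow(g$fragments) != 2L)
      stop_snlipid("contract",
        "group %s|%s needs exactly 2 fragment rows for sn deconvolution",
        g$sample_id, format_lipid(g$precursor))
    cal <- sn_calibration_for(g$precursor, calibrations)
    # sn-resolved precursors identify the sn1/sn2 transitions by chain
    # token; otherwise the first fragment row is taken as sn1
    fr <- g$fragments
    if (g$precursor$level == "sn_position") {
      toks <- vapply(g$precursor$chains, format_fatty_acyl, character(1))
      i1 <- match(toks[1], fr$fragment)
      i2 <- match(toks[2], fr$fragment)
      if (is.na(i1) || is.na(i2))
        stop_snlipid("missing_fragment",
          "group %s|%s lacks the %s carboxylate transition",
          g$sample_id, format_lipid(g$precursor),
          toks[which(is.na(c(i1, i2)))[1]])
    } else {
      i1 <- 1L; i2 <- 2L
    }
    ratio <- compute_sn_ratio(fr$area[i2], fr$area[i1],
                              transition = format_lipid(g$precursor))
    dec <- sn_deconvolve(ratio, cal)
    cbind(data.frame(sample_id = g$sample_id,
                     precursor = format_lipid(g$precursor)),
          as.data.frame(dec))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out
}

#' Apportion every multi-isomer peak group among compositional isomers
#'
#' @param groups list of [peak_group()] objects.
#' @return row-bound [compositional_fractions()] results.
#' @export
apportion_groups <- function(groups) {
  rows <- lapply(groups, function(g) as.data.frame(compositional_fractions(g)))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
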