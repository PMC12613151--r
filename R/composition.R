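# Compositional-isomer deconvolution: coeluting lipids sharing a sum
# composition (e.g. PC 36:2 = 18:0_18:2 and 18:1_18:1) are apportioned by
# summing each isomer's diagnostic acyl-chain fragments and normalising
# against the MS1 precursor area P. Raw fractions (fragment sum / P, as the
# method defines them) need not sum to 1 because fragment yield differs from
# precursor response; apportionment of the MS1 signal therefore uses the
# renormalised shares, which conserve P exactly.

#' Construct a peak group
#'
#' One precursor's integrated MS1 area plus its labelled fragment areas for
#' one sample — the unit the deconvolution operations consume.
#'
#' @param sample_id sample identifier.
#' @param precursor the precursor annotation (a `lipid_annotation` or a
#'   shorthand string, parsed on the fly).
#' @param ms1_area non-negative MS1 precursor peak area.
#' @param fragments data frame with columns `isomer` (shorthand name of the
#'   contributing isomer), `fragment` (fragment label, e.g. a chain token)
#'   and `area` (non-negative).
#' @param rt retention time in seconds (optional).
#' @param mobility ion mobility 1/K0 in V·s/cm² (optional).
#' @return an object of class `peak_group`.
#' @export
peak_group <- function(sample_id, precursor, ms1_area, fragments,
                       rt = NA_real_, mobility = NA_real_) {
  if (is.character(precursor)) precursor <- parse_lipid(precursor)
  stopifnot(inherits(precursor, "lipid_annotation"))
  if (!is.numeric(ms1_area) || length(ms1_area) != 1L || is.na(ms1_area) ||
      ms1_area < 0)
    stop_snlipid("contract", "ms1_area must be a non-negative scalar")
  fragments <- as.data.frame(fragments)
  need <- c("isomer", "fragment", "area")
  if (!all(need %in% names(fragments)))
    stop_snlipid("contract", "fragments need columns %s",
                 paste(need, collapse = ", "))
  if (any(fragments$area < 0, na.rm = TRUE))
    stop_snlipid("contract", "fragment areas must be non-negative")
  structure(list(sample_id = sample_id, precursor = precursor,
                 ms1_area = ms1_area, fragments = fragments,
                 rt = rt, mobility = mobility),
            class = "peak_group")
}

#' @export
print.peak_group <- function(x, ...) {
  cat(sprintf("<peak group: %s | sample %s | MS1 %.4g | %d fragment rows>\n",
              format_lipid(x$precursor), x$sample_id, x$ms1_area,
              nrow(x$fragments)))
  invisible(x)
}

#' Apportion a precursor's MS1 signal among compositional isomers
#'
#' For each isomer in the peak group, sums its diagnostic fragment areas and
#' divides by the MS1 precursor area P to give the raw fraction. Shares are
#' the fragment sums renormalised to 1 and the MS1 area is apportioned by
#' share, so the apportioned areas conserve P.
#'
#' @param group a [peak_group()] with `ms1_area > 0`.
#' @return a `compositional_shares` data frame: one row per isomer with
#'   `fragment_sum`, `raw_fraction`, `share`, `apportioned_ms1`.
#' @export
compositional_fractions <- function(group) {
  stopifnot(inherits(group, "peak_group"))
  if (group$ms1_area <= 0)
    stop_snlipid("contract", "MS1 precursor area must be positive")
  sums <- tapply(group$fragments$area, group$fragments$isomer, sum,
                 na.rm = TRUE)
  sums <- sums[!is.na(sums)]
  if (length(sums) == 0L || sum(sums) <= 0)
    stop_snlipid("no_evidence",
      "all fragment sums are zero for %s in sample %s",
      format_lipid(group$precursor), group$sample_id)
  total <- sum(sums)
  out <- data.frame(sample_id = group$sample_id,
                    precursor = format_lipid(group$precursor),
                    isomer = names(sums),
                    fragment_sum = as.numeric(sums),
                    raw_fraction = as.numeric(sums) / group$ms1_area,
                    share = as.numeric(sums) / total,
                    row.names = NULL)
  out$apportioned_ms1 <- out$share * group$ms1_area
  class(out) <- c("compositional_shares", "data.frame")
  out
}

#' Flag precursor pairs whose quantifier transitions can collide
#'
#' Two scheduled precursors whose quantifier fragment m/z values coincide
#' within a mass tolerance and whose retention-time windows overlap (an
#' isobaric pair sharing a fatty-acyl chain, e.g. a diacyl and an ether
#' species both quantified on a 20:4 carboxylate) yield unreliable
#' transition extraction; such pairs carry a reliability warning downstream.
#'
#' @param transitions data frame with columns `precursor` (name),
#'   `quantifier_mz` (Da), `rt_center` and `rt_window` (seconds; the window
#'   is the total width, applied as center ± width/2).
#' @param mz_tolerance quantifier coincidence tolerance in Da.
#' @return data frame of pairwise conflicts: `precursor_a`, `precursor_b`,
#'   `quantifier_mz_a`, `quantifier_mz_b`, `rt_overlap_s`.
#' @export
shared_fragment_conflicts <- function(transitions, mz_tolerance = 0.005) {
  transitions <- as.data.frame(transitions)
  need <- c("precursor", "quantifier_mz", "rt_center", "rt_window")
  if (!all(need %in% names(transitions)))
    stop_snlipid("contract", "transitions need columns %s",
                 paste(need, collapse = ", "))
  n <- nrow(transitions)
  empty <- data.frame(precursor_a = character(), precursor_b = character(),
                      quantifier_mz_a = numeric(), quantifier_mz_b = numeric(),
                      rt_overlap_s = numeric())
  if (n < 2L) return(empty)
  lo <- transitions$rt_center - transitions$rt_window / 2
  hi <- transitions$rt_center + transitions$rt_window / 2
  rows <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (abs(transitions$quantifier_mz[i] - transitions$quantifier_mz[j]) >
          mz_tolerance) next
      overlap <- min(hi[i], hi[j]) - max(lo[i], lo[j])
      if (overlap <= 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        precursor_a = transitions$precursor[i],
        precursor_b = transitions$precursor[j],
        quantifier_mz_a = transitions$quantifier_mz[i],
        quantifier_mz_b = transitions$quantifier_mz[j],
        rt_overlap_s = overlap)
    }
  }
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}

#' Select the quantifier fragment for a TG/DG under the shared-fragment rule
#'
#' The most intense acyl neutral-loss fragment is the quantifier, unless the
#' same fatty-acyl chain also occurs in a coeluting isomer's fragment set —
#' shared chains are excluded, and only an isomer retaining a dissimilar
#' chain is quantifiable.
#'
#' @param candidates data frame with columns `chain` (chain token), `mz`
#'   and `area` for the isomer's candidate quantifier fragments.
#' @param coeluting list of chain-token character vectors (or candidate
#'   data frames with a `chain` column), one per coeluting isomer.
#' @return a `tg_quantifier` list: `quantifiable` (logical), and when
#'   quantifiable `chain`, `mz`, `area` of the chosen fragment.
#' @export
select_tg_quantifier <- function(candidates, coeluting = list()) {
  candidates <- as.data.frame(candidates)
  if (nrow(candidates) == 0L)
    stop_snlipid("contract", "empty quantifier candidate set")
  if (!all(c("chain", "area") %in% names(candidates)))
    stop_snlipid("contract", "candidates need columns chain, area")
  shared <- unique(unlist(lapply(coeluting, function(x) {
    if (is.data.frame(x)) as.character(x$chain) else as.character(x)
  })))
  ok <- !(candidates$chain %in% shared)
  if (!any(ok)) {
    return(structure(list(quantifiable = FALSE, chain = NA_character_,
                          mz = NA_real_, area = NA_real_),
                     class = "tg_quantifier"))
  }
  pool <- candidates[ok, , drop = FALSE]
  best <- pool[which.max(pool$area), , drop = FALSE]
  structure(list(quantifiable = TRUE, chain = as.character(best$chain),
                 mz = if ("mz" %in% names(best)) best$mz else NA_real_,
                 area = best$area),
            class = "tg_quantifier")
}

#' @export
print.tg_quantifier <- function(x, ...) {
  if (x$quantifiable)
    cat(sprintf("<TG quantifier: loss of %s (area %.4g)>\n", x$chain, x$area))
  else cat("<TG quantifier: not quantifiable (all chains shared)>\n")
  invisible(x)
}
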