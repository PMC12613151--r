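# Monoisotopic masses (CODATA/AME-derived, Da)
.MASS_H <- 1.00782503207
.MASS_D <- 2.01410177785
.MASS_C <- 12.0
.MASS_O <- 15.9949146196
.MASS_N <- 14.0030740048
.MASS_E <- 0.00054857990907
.MASS_NH3 <- .MASS_N + 3 * .MASS_H

#' Monoisotopic m/z of a fatty-acyl carboxylate anion
#'
#' Computes the exact mass of the RCOO- fragment ion of a fatty acyl chain,
#' the diagnostic negative-mode fragment whose intensity depends on the
#' chain's sn position. The ion formula for a chain with `n` carbons and
#' `d` double bonds is C(n)H(2n-1-2d)O2 as an anion; the electron mass is
#' included. Each deuterium label replaces one hydrogen.
#'
#' Note: elemental arithmetic gives 279.2330 Da for the 18:2 carboxylate;
#' a value of 279.2350 sometimes circulates in print but is inconsistent
#' with the monoisotopic masses of C, H and O. This function always
#' computes from elemental masses.
#'
#' @param fa a [fatty_acyl()] object (ether chains are not supported:
#'   an O-/P- linked chain does not yield a carboxylate fragment).
#' @return monoisotopic m/z in Da (numeric scalar).
#' @examples
#' carboxylate_mz(fatty_acyl(18, 1)) # 281.2485
#' carboxylate_mz(fatty_acyl(18, 0)) # 283.2641
#' @export
carboxylate_mz <- function(fa) {
  stopifnot(inherits(fa, "fatty_acyl"))
  if (isTRUE(fa$ether_linkage)) {
    stop_snlipid("unsupported_ion",
      "ether-linked chains do not form carboxylate fragment ions")
  }
  n <- fa$carbons
  d <- fa$double_bonds
  k <- fa$deuterium_count
  n_h <- 2L * n - 1L - 2L * d
  if (k > n_h) stop_snlipid("contract", "more deuterium labels than hydrogens")
  n * .MASS_C + (n_h - k) * .MASS_H + k * .MASS_D + 2 * .MASS_O + .MASS_E
}

#' Neutral monoisotopic mass of a free fatty acid
#'
#' Formula C(n)H(2n-2d)O2, deuterium labels substituting hydrogens.
#'
#' @inheritParams carboxylate_mz
#' @return neutral monoisotopic mass in Da.
#' @export
fatty_acid_mass <- function(fa) {
  stopifnot(inherits(fa, "fatty_acyl"))
  n <- fa$carbons
  d <- fa$double_bonds
  k <- fa$deuterium_count
  n_h <- 2L * n - 2L * d
  if (k > n_h) stop_snlipid("contract", "more deuterium labels than hydrogens")
  n * .MASS_C + (n_h - k) * .MASS_H + k * .MASS_D + 2 * .MASS_O
}

#' m/z of the TG/DG acyl neutral-loss fragment
#'
#' For ammoniated glycerolipid precursors the quantifier fragment is
#' `[M+NH4-(RCOOH+NH3)]+`: the precursor loses one fatty acid as the neutral
#' acid together with ammonia. This fragment can arise from any of the
#' glycerol sn positions carrying that chain.
#'
#' @param precursor_mz m/z of the `[M+NH4]+` precursor (Da).
#' @param fa the lost fatty acyl chain, a [fatty_acyl()].
#' @return fragment m/z in Da.
#' @examples
#' tg_neutral_loss_mz(848.7702, fatty_acyl(16, 0)) # 575.5035
#' @export
tg_neutral_loss_mz <- function(precursor_mz, fa) {
  stopifnot(is.numeric(precursor_mz), length(precursor_mz) == 1L)
  mz <- precursor_mz - fatty_acid_mass(fa) - .MASS_NH3
  if (mz <= 0) {
    stop_snlipid("contract", sprintf(
      "neutral loss of %s from precursor m/z %.4f gives non-positive fragment m/z",
      format_fatty_acyl(fa), precursor_mz))
  }
  mz
}

# Internal condition helper: all package errors carry a subclass so callers
# can trap them precisely.
stop_snlipid <- function(subclass, msg, ..., data = NULL) {
  cond <- structure(
    class = c(paste0("snlipid_", subclass, "_error"), "snlipid_error",
              "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1), data = data))
  stop(cond)
}
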