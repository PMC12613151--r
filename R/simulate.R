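# Seeded simulators generating every input the pipeline consumes. Each
# simulator is the forward partner of exactly one analysis operation, so
# noiseless round trips are exact. Noise is multiplicative lognormal with
# unit mean, applied independently per peak area: positive-valued signals
# with a single CV parameter.

#' Construct a noise model
#'
#' @param kind `"none"` or `"lognormal"`.
#' @param cv coefficient of variation of the multiplicative noise, percent.
#' @param seed optional integer seed; the same configuration and seed
#'   always produce identical simulator output.
#' @return a `noise_model` object.
#' @export
noise_model <- function(kind = c("none", "lognormal"), cv = 0, seed = NULL) {
  kind <- match.arg(kind)
  if (cv < 0) stop_snlipid("contract", "noise CV must be non-negative")
  if (kind == "lognormal" && cv == 0) kind <- "none"
  structure(list(kind = kind, cv = cv, seed = seed), class = "noise_model")
}

# Multiplicative unit-mean lognormal factors; sdlog chosen so the
# multiplicative CV equals cv percent.
.noise_factors <- function(n, noise) {
  if (noise$kind == "none" || n == 0L) return(rep(1, n))
  sdlog <- sqrt(log(1 + (noise$cv / 100)^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

.with_noise_seed <- function(noise, expr) {
  if (!is.null(noise$seed)) set.seed(noise$seed)
  expr
}

# strip the seed so nested per-point simulations inside a seeded series draw
# from the running RNG stream instead of resetting it
.unseeded <- function(noise) { noise$seed <- NULL; noise }

#' Simulate a two-isomer sn-positional mixture
#'
#' Generates the peak group a targeted acquisition would yield for a mixture
#' of an sn-resolved lipid (SNA) and its chain-swapped counterpart (SNB) at
#' SNA fraction `sna_fraction`.
#'
#' Two forward models are available. `"empirical"` draws the observed
#' sn2/sn1 ratio from the exponential calibration, `c1 * exp(c2 * f)`, and
#' splits the fragment signal accordingly. `"mechanistic"` gives each pure
#' isomer a fixed within-isomer sn2:sn1 fragment split of `rho : 1` with
#' `rho = c1 * exp(c2)` (the pure-SNA ratio implied by the calibration) and
#' sums contributions per chain, yielding the two-isomer mixing curve
#' `(f*rho + (1-f)) / (f + (1-f)*rho)`.
#'
#' @param sna_fraction true SNA fraction in `[0, 1]`.
#' @param calibration an `sn_calibration` for the mixture's class.
#' @param mode `"empirical"` or `"mechanistic"`.
#' @param annotation optional sn-resolved `lipid_annotation` (or string) of
#'   the SNA isomer; chain tokens label the fragments. Defaults to generic
#'   `"sn1"`/`"sn2"` labels.
#' @param total_amount total signal (arbitrary area units).
#' @param noise a [noise_model()]; applied independently to each area.
#' @param sample_id sample label for the emitted peak group.
#' @return a [peak_group()] whose two fragment rows are the sn1- and
#'   sn2-chain carboxylate areas.
#' @export
simulate_sn_mixture <- function(sna_fraction, calibration,
                                mode = c("empirical", "mechanistic"),
                                annotation = NULL, total_amount = 1000,
                                noise = noise_model(), sample_id = "sim") {
  mode <- match.arg(mode)
  stopifnot(inherits(calibration, "sn_calibration"))
  if (is.na(sna_fraction) || sna_fraction < 0 || sna_fraction > 1)
    stop_snlipid("contract", "SNA fraction must lie in [0, 1]")
  if (is.character(annotation)) annotation <- parse_lipid(annotation)
  if (!is.null(annotation)) {
    if (annotation$level != "sn_position" || length(annotation$chains) != 2L)
      stop_snlipid("contract", "annotation must be an sn-resolved diacyl")
    labels <- vapply(annotation$chains, format_fatty_acyl, character(1))
    precursor <- annotation
  } else {
    labels <- c("sn1", "sn2")
    precursor <- parse_lipid(paste(calibration$lipid_class, "34:1"))
  }

  f <- sna_fraction
  if (mode == "empirical") {
    r <- calibration$c1 * exp(calibration$c2 * f)
    sn2 <- total_amount * r / (1 + r)
    sn1 <- total_amount / (1 + r)
  } else {
    rho <- calibration$c1 * exp(calibration$c2)
    # per chain: SNA puts rho on its sn2 chain, SNB (chains swapped) puts
    # rho on the SNA sn1 chain
    sn2 <- total_amount * (f * rho + (1 - f)) / (1 + rho)
    sn1 <- total_amount * (f + (1 - f) * rho) / (1 + rho)
  }

  .with_noise_seed(noise, {
    fac <- .noise_factors(3L, noise)
    iso <- if (!is.null(annotation)) format_lipid(annotation) else
      format_lipid(precursor)
    peak_group(sample_id, precursor, ms1_area = total_amount * fac[3],
               fragments = data.frame(
                 isomer = iso,
                 fragment = labels,
                 area = c(sn1 * fac[1], sn2 * fac[2])))
  })
}

#' Observed sn2/sn1 ratio of a simulated mixture
#'
#' @param group a peak group from [simulate_sn_mixture()].
#' @return the sn2/sn1 fragment peak-area ratio.
#' @export
sn_ratio_of <- function(group) {
  stopifnot(inherits(group, "peak_group"), nrow(group$fragments) == 2L)
  compute_sn_ratio(group$fragments$area[2], group$fragments$area[1],
                   transition = paste(group$fragments$fragment, collapse = "/"))
}

#' Simulate a calibration mixture series
#'
#' One simulated two-isomer mixture per design proportion; returns the
#' (fraction, observed ratio) points that [fit_sn_calibration()] consumes.
#'
#' @param calibration generating `sn_calibration`.
#' @param proportions SNA fractions; default the seven-point design of
#'   [calibration_proportions()].
#' @param noise a [noise_model()].
#' @param mode forward model, as in [simulate_sn_mixture()].
#' @return data frame with columns `fraction`, `ratio`.
#' @export
simulate_calibration_series <- function(calibration,
                                        proportions = calibration_proportions(),
                                        noise = noise_model(),
                                        mode = "empirical") {
  if (any(proportions < 0 | proportions > 1))
    stop_snlipid("contract", "proportions must lie in [0, 1]")
  .with_noise_seed(noise, {
    inner <- .unseeded(noise)
    ratios <- vapply(proportions, function(f) {
      sn_ratio_of(simulate_sn_mixture(f, calibration, mode = mode,
                                      noise = inner))
    }, numeric(1))
    data.frame(fraction = proportions, ratio = ratios)
  })
}

#' Simulate a coeluting compositional-isomer mixture
#'
#' Builds the peak group of a precursor whose MS1 signal is shared by
#' fatty-acyl compositional isomers (e.g. PC 36:2 as PC 18:0_18:2 with
#' PC 18:1_18:1). Each isomer's summed diagnostic fragment area is
#' proportional to its amount times its fragment yield; with equal yields
#' and no noise, [compositional_fractions()] recovers the true proportions
#' exactly. Unequal yields reproduce the bias that differing fragmentation
#' efficiencies impose on fragment-based apportionment.
#'
#' @param proportions named numeric vector of true isomer proportions
#'   (names are molecular-species shorthand, chains disjoint between
#'   isomers); must sum to 1.
#' @param precursor sum-composition shorthand of the shared precursor.
#' @param yields named relative fragment yields per isomer (default equal).
#' @param conversion fraction of precursor signal converted to diagnostic
#'   fragments (keeps raw fractions below 1, as fragment yield is below
#'   precursor response).
#' @param total_amount MS1-equivalent total signal.
#' @param noise a [noise_model()].
#' @param sample_id sample label.
#' @return a [peak_group()] with one sn1 and one sn2 fragment row per
#'   isomer.
#' @export
simulate_compositional_mixture <- function(proportions,
                                           precursor = "PC 36:2",
                                           yields = NULL,
                                           conversion = 0.3,
                                           total_amount = 1000,
                                           noise = noise_model(),
                                           sample_id = "sim") {
  stopifnot(is.numeric(proportions), !is.null(names(proportions)))
  if (abs(sum(proportions) - 1) > 1e-9)
    stop_snlipid("contract", "true proportions must sum to 1")
  isomers <- lapply(names(proportions), parse_lipid)
  # symmetric isomers (e.g. 18:1_18:1) produce a single merged fragment
  chains <- lapply(isomers, function(a)
    unique(vapply(a$chains, format_fatty_acyl, character(1))))
  if (length(isomers) > 1L) {
    for (i in seq_along(isomers)[-1]) {
      for (j in seq_len(i - 1L)) {
        if (length(intersect(chains[[i]], chains[[j]])) > 0L)
          stop_snlipid("contract",
            "isomers %s and %s share a chain; fragments are not diagnostic",
            names(proportions)[i], names(proportions)[j])
      }
    }
  }
  if (is.null(yields)) yields <- stats::setNames(
    rep(1, length(proportions)), names(proportions))
  yields <- yields[names(proportions)]
  if (any(is.na(yields)))
    stop_snlipid("contract", "yields must cover every isomer")

  frag <- do.call(rbind, lapply(seq_along(isomers), function(i) {
    tot <- total_amount * proportions[i] * yields[i] * conversion
    data.frame(isomer = names(proportions)[i],
               fragment = chains[[i]],
               area = rep(tot / length(chains[[i]]), length(chains[[i]])))
  }))
  .with_noise_seed(noise, {
    fac <- .noise_factors(nrow(frag) + 1L, noise)
    frag$area <- frag$area * fac[-1]
    peak_group(sample_id, precursor, ms1_area = total_amount * fac[1],
               fragments = frag)
  })
}

#' Simulate a phospholipase A2 digest of an sn-resolved standard
#'
#' The enzyme cleaves the sn2 acyl chain, so a standard of nominal purity
#' `p` percent yields lyso signal carrying the nominal sn1 chain in
#' proportion `p` and the nominal sn2 chain in proportion `100 - p` (the
#' impurity is the chain-swapped isomer, whose sn1 chain is the nominal
#' sn2 chain). Undigested precursor remains in proportion to
#' `100 - efficiency`.
#'
#' @param standard sn-resolved diacyl `lipid_annotation` or shorthand
#'   string.
#' @param purity true isomeric purity of the standard, percent.
#' @param efficiency digestion efficiency, percent.
#' @param total_amount pre-digestion precursor signal.
#' @param noise a [noise_model()].
#' @return list with `lyso_areas` (named by chain token) and
#'   `residual_precursor`.
#' @export
simulate_pla2_digestion <- function(standard, purity, efficiency = 99.5,
                                    total_amount = 1000,
                                    noise = noise_model()) {
  if (is.character(standard)) standard <- parse_lipid(standard)
  stopifnot(inherits(standard, "lipid_annotation"))
  if (standard$level != "sn_position" || length(standard$chains) != 2L)
    stop_snlipid("contract", "standard must be an sn-resolved diacyl")
  if (purity < 0 || purity > 100)
    stop_snlipid("contract", "purity must lie in [0, 100]")
  if (efficiency < 0 || efficiency > 100)
    stop_snlipid("contract", "efficiency must lie in [0, 100]")
  sn1 <- format_fatty_acyl(standard$chains[[1]])
  sn2 <- format_fatty_acyl(standard$chains[[2]])
  eff <- efficiency / 100
  digested <- total_amount * eff
  lyso <- c(purity / 100 * digested, (1 - purity / 100) * digested)
  names(lyso) <- c(sn1, sn2)
  if (sn1 == sn2) lyso <- stats::setNames(sum(lyso), sn1)
  lyso <- lyso[lyso > 0 | seq_along(lyso) == 1L]
  .with_noise_seed(noise, {
    fac <- .noise_factors(length(lyso) + 1L, noise)
    list(lyso_areas = lyso * fac[seq_along(lyso)],
         residual_precursor = total_amount * (1 - eff) * fac[length(fac)])
  })
}

#' Simulate replicate measurements around known true values
#'
#' @param truth named numeric vector of true values (one per analyte).
#' @param n number of replicates (>= 2).
#' @param noise a [noise_model()].
#' @return long data frame `replicate`, `analyte`, `value`.
#' @export
simulate_replicates <- function(truth, n, noise = noise_model()) {
  stopifnot(is.numeric(truth), n >= 2L)
  if (is.null(names(truth)))
    names(truth) <- paste0("analyte_", seq_along(truth))
  .with_noise_seed(noise, {
    fac <- .noise_factors(n * length(truth), noise)
    data.frame(replicate = rep(seq_len(n), each = length(truth)),
               analyte = rep(names(truth), times = n),
               value = rep(unname(truth), times = n) * fac)
  })
}

#' Simulate a serial-dilution calibration series
#'
#' Geometric concentration ladder with a linear detector response plus
#' multiplicative noise; the forward partner of [lod_loq()].
#'
#' @param slope,intercept linear response parameters (area per
#'   concentration unit; area offset).
#' @param levels number of dilution levels (>= 5).
#' @param fold dilution factor between consecutive levels.
#' @param top_concentration concentration of the most concentrated level.
#' @param replicates replicate injections per level.
#' @param noise a [noise_model()].
#' @return a `dilution_series` data frame: `level`, `concentration`,
#'   `replicate`, `area`; concentrations strictly decreasing with level.
#' @export
simulate_dilution_series <- function(slope = 2, intercept = 0, levels = 7,
                                     fold = 2, top_concentration = 100,
                                     replicates = 1,
                                     noise = noise_model()) {
  if (levels < 5L)
    stop_snlipid("contract", "a dilution series needs at least 5 levels")
  if (fold <= 1) stop_snlipid("contract", "dilution factor must exceed 1")
  conc <- top_concentration / fold^(seq_len(levels) - 1L)
  out <- data.frame(level = rep(seq_len(levels), each = replicates),
                    concentration = rep(conc, each = replicates),
                    replicate = rep(seq_len(replicates), times = levels))
  out$area <- intercept + slope * out$concentration
  .with_noise_seed(noise, {
    out$area <- out$area * .noise_factors(nrow(out), noise)
    class(out) <- c("dilution_series", "data.frame")
    out
  })
}
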