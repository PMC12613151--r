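---
title: "Deconvolving coeluting lipid isomers from fragment-ion ratios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolving coeluting lipid isomers from fragment-ion ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snlipid)
```

## The measurement and its observable

In reversed-phase targeted lipidomics, an sn-positional isomer pair —
say PC 16:0/18:1 and PC 16:0/18:1's chain-swapped counterpart
PC 18:1/16:0 — coelutes and shares every fragment m/z. What differs is
intensity: in negative mode the carboxylate fragment (RCOO⁻) released
from the glycerol sn2 position is systematically more abundant than the
one released from sn1. The sn2/sn1 peak-area ratio of these two
transitions is therefore a continuous readout of the mixture's isomeric
composition, and it is the single observable this package models.

Two conventions fix the bookkeeping throughout:

* **SNA/SNB.** The isomer whose chains appear in the stated order of the
  annotation is SNA; its chain-swapped counterpart is SNB. In
  `"/"`-separated names the first chain is sn1.
* **Fractions, not percentages, inside the model.** The calibration
  operates on the SNA fraction `f ∈ [0, 1]`; percentages appear only in
  reported results. At `f = 1` the PC model predicts a pure-isomer ratio
  of `0.40·e^1.91 ≈ 2.70`, consistent with observed pure-PC-standard
  ratios in the low single digits — a percent-scale `f` under the same
  slope would be astronomically wrong, which is how the unit convention
  is pinned down.

## The calibration model

Mixtures of SNA and SNB standards at volume ratios 1:8, 1:4, 1:2, 1:1,
2:1, 4:1 and 8:1 (SNA fractions 1/9 … 8/9, `calibration_proportions()`)
give per-mixture sn2/sn1 ratios; ratios are first averaged across all
standards of a class (`average_sn_ratio()`), which deliberately averages
out the mild dependence of the ratio on chain length and unsaturation.
The averaged points follow an exponential curve

$$r(f) = c_1 e^{c_2 f}$$

fitted as `ln r = ln c1 + c2·f` by ordinary least squares
(`fit_sn_calibration()`). The log-linear route was chosen over an
iterative nonlinear fit because it is deterministic, exactly invertible,
and on noiseless self-generated data reproduces the generating
coefficients to machine precision. The fitted object is a classed model
with the usual verbs:

```{r}
cal <- default_sn_calibrations()$PC
coef(cal)
summary(cal)
```

Inversion is closed-form: `f = ln(r/c1)/c2` (`sn_deconvolve()`). Raw
estimates outside `[0, 1]` are clamped, never errors: a raw estimate
above 1 means the observed ratio exceeds the pure-SNA ratio
`c1·e^{c2}`, and the species is flagged isomerically pure
(`pure_flag`); the symmetric rule below 0 clamps to pure SNB. SNA and
SNB percentages always sum to exactly 100.

The packaged defaults are the published class coefficients — PC
(0.40, 1.91), PE (0.38, 1.66), PS (0.72, 1.33) — shipped in
`inst/extdata/sn_calibrations.yaml`. Classes without a calibration (PA,
PG, PI) raise an error on lookup; a user may borrow a calibration across
classes only by inserting it into the list explicitly. For PS, whose
sn-fragment intensity ordering is inverted relative to PC/PE, the
numerator convention is kept as sn2/sn1 and the coefficients absorb the
ordering.

One enumeration ambiguity was decided here: the calibration-design
description mentions eight concentration points while seven mixing
ratios are enumerated; the package defaults to the seven enumerated
fractions and leaves the design configurable.

### Relation to a mechanistic mixing model

If each pure isomer emitted its two chain fragments in a fixed ratio
`ρ = c1·e^{c2}` (sn2:sn1), a mixture at SNA fraction `f` would show

$$r_{\text{mech}}(f) = \frac{f\rho + (1-f)}{f + (1-f)\rho},$$

which equals the exponential model at both endpoints and within 10%
relative across `f ∈ [0, 1]` for the PC coefficients. Both forward
models are available in `simulate_sn_mixture()` (`"empirical"` draws the
ratio from the exponential curve; `"mechanistic"` mixes fixed pure-isomer
fragment splits per chain); the empirical mode is the default because it
is the exact inverse-partner of the fitted calibration, while the
mechanistic mode exists to probe model mismatch.

### Orthogonal purity by PLA2 digestion

Phospholipase A2 cleaves the sn2 chain, leaving lyso species that carry
the sn1 chain. For a nominally sn-pure standard, the share of total lyso
signal carried by the nominal sn1 chain is an enzymatic purity estimate
independent of the fragment-ratio model (`pla2_purity()`), assuming
equal detector response of the lyso products — an assumption stated, not
tested, here. The paired simulator (`simulate_pla2_digestion()`) models
digestion efficiency (default 99.5%, residual precursor
`1 − efficiency`) and recovers injected purities exactly in the
noiseless limit.

## Compositional isomers and the TG rule

Coeluting fatty-acyl compositional isomers under one precursor are
apportioned by summed diagnostic fragments (`compositional_fractions()`).
The raw fraction of isomer *i* is its fragment sum over the MS1
precursor area `P`, exactly as the method defines it; because fragment
yield differs from precursor response these raw fractions do not sum
to 1, so the package also reports shares renormalised to 1 and uses the
shares to apportion `P`. This keeps the printed definition intact while
conserving the precursor signal. Shares are invariant under uniform
scaling of all fragment areas, and unequal per-isomer fragment yields
bias the shares exactly as the yield ratio predicts — the simulator
exposes a `yields` argument to study this known failure mode.

For TG/DG species the quantifier is the acyl neutral-loss fragment
`[M+NH4−(RCOOH+NH3)]+`. Because one fatty acyl can occur in several
coeluting TGs, the rule implemented in `select_tg_quantifier()` is: take
the most intense candidate fragment whose chain does not occur in any
coeluting isomer's candidate set; if every chain is shared, the species
is reported not-quantifiable rather than quantified on a contaminated
transition. Full sn1/sn2/sn3 positional deconvolution of TGs is out of
scope — the within-TG positional fragment ratios are too variable for a
calibration of the PC kind without dedicated standards.

Pairs of scheduled precursors whose quantifier m/z values coincide
within 0.005 Da (QTOF-scale, configurable) and whose RT windows overlap
are flagged by `shared_fragment_conflicts()` and should be treated as
unreliable downstream.

## Quantification and validation statistics

* **ISTD normalisation** (`normalize_to_istd()`): analyte area / ISTD
  area × spiked amount; a non-positive ISTD area marks the sample failed
  rather than propagating silently. With several ISTDs per class,
  `choose_istd()` picks the one minimising replicate CV.
* **CV** is `100·sd/mean` with the n−1 denominator.
* **IQR outliers** (`iqr_outliers()`): fences at `Q1 − k·IQR`,
  `Q3 + k·IQR` with quartiles by linear interpolation between order
  statistics (type 7, fixed for reproducibility). The default `k = 0.1`
  is read as a fence *multiplier* — an unusually stringent screen meant
  for MS2 replicate sets; the conventional exploratory value 1.5 is one
  argument away. The alternative reading of "0.1" as an absolute offset
  is not implemented as a default precisely because it is
  unit-dependent.
* **LOD/LOQ** (`lod_loq()`): OLS of area on concentration over ≥ 5
  levels; `LOD = 3.3σ/S`, `LOQ = 10σ/S` with σ the residual standard
  deviation. The guideline formula is not uniquely pinned by the cited
  validation guidelines; the ICH-style residual-σ form was fixed here.
* **MS1/MS2 concordance**: the MS2/MS1 normalised-value ratio with the
  closed acceptance interval [0.7, 1.3].

## Acquisition scheduling

`build_target_list()` turns 4D descriptors (m/z, RT, 1/K0, polarity)
into scheduled PRM targets with the validated windows: 1 Da isolation,
60 s total RT window and 0.03 V·s/cm² total mobility window, both
applied as center ± half-width (the window figures are read as total
widths), 45 eV collision energy with per-class overrides for PA/PI/PS
where the precursor survives 45 eV. Descriptors outside the instrument
scan ranges (m/z 100–1350; mobility 0.55–1.87 positive, 0.55–1.86
negative) fail row-by-row with the offending field named.
`schedule_concurrency()` counts window overlap per RT bin against a
brute-force sweep-verified implementation.

## Simulators: what they emulate, and what they do not

Every analysis operation has exactly one forward simulator partner, all
seeded and deterministic (same configuration + seed ⇒ identical output).
Noise is multiplicative lognormal with unit mean, applied independently
per peak area — positive-valued by construction and parameterised by a
single CV. Defaults mirror the study conditions where stated (seven
calibration proportions; 7-level two-fold dilutions; 99.5% PLA2
efficiency; 32-replicate sets at desk scale); noise magnitudes for
standard mixtures are not stated anywhere, so the package uses 5–10% CV
as a realistic QTOF peak-area spread — a package choice, made once.

The simulators deliberately do **not** model: chromatographic peak
shape, RT drift or integration error; correlated noise between the sn1
and sn2 transitions of one spectrum (areas fluctuate independently);
isobaric background interference; detector saturation; or
between-batch effects. Passing round-trip tests therefore demonstrates
the correctness and numerical stability of the deconvolution
arithmetic under the stated noise model — not the field accuracy of the
calibration coefficients on real matrices, which only standards can
establish.

Problem sizes used by the test-suite and the acceptance script — 1,000
mixtures for the noise-robustness quantile, 50 blindfold draws, 28
compositional recoveries, 21-point dilution fits — were chosen as
desk-scale versions of the corresponding experiments that keep sampling
error comfortably inside the tolerances being asserted.

## Numerical choices and degenerate inputs

* Masses are computed from monoisotopic elemental masses (electron mass
  included in ions). Elemental arithmetic gives 279.2330 Da for the
  18:2 carboxylate; a printed value of 279.2350 circulates but is
  inconsistent with the element masses, and this package always
  computes.
* A flat calibration series (all ratios equal) fits as `c2 = 0` with
  `r² = 1` by the zero-variance convention; a `c2 = 0` calibration
  refuses inversion.
* `compute_sn_ratio()` treats a zero or missing fragment area as a
  missing-transition error carrying the transition identity — a ratio
  of 0 or ∞ is never silently produced.
* Ties in `select_tg_quantifier()` resolve to the first maximum in
  candidate order (deterministic).
* Ether (O-/P-) chains parse and schedule but are excluded from
  carboxylate fragment generation; they matter as isobaric-interference
  cases, not as sn-model inputs.
* Deuterium labels (`d5`) attach to the chain they annotate — the last
  chain token — matching ISTD naming such as PC 17:0/14:1 d5.

## Known limitations

The sn model intentionally ignores the residual dependence of the ratio
on chain structure (averaged out at calibration time); classes with
inverted fragment ordering rely on the coefficients to absorb it; TG
positional isomers are not deconvolved; and cohort-scale performance
figures (hundreds of quantified species, replicate CV distributions on
reference plasma) require the original biological data and are outside
what the synthetic suite can or should reproduce.
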