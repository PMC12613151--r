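pc <- default_sn_calibrations()$PC

test_that("seeded simulators are deterministic", {
  nz <- noise_model("lognormal", cv = 10, seed = 77)
  expect_identical(simulate_sn_mixture(0.4, pc, noise = nz),
                   simulate_sn_mixture(0.4, pc, noise = nz))
  expect_identical(simulate_calibration_series(pc, noise = nz),
                   simulate_calibration_series(pc, noise = nz))
  expect_identical(simulate_replicates(c(a = 1, b = 2), 5, nz),
                   simulate_replicates(c(a = 1, b = 2), 5, nz))
  expect_identical(simulate_dilution_series(noise = nz),
                   simulate_dilution_series(noise = nz))
  expect_identical(
    simulate_pla2_digestion("PC 16:0/18:1", 95, noise = nz),
    simulate_pla2_digestion("PC 16:0/18:1", 95, noise = nz))
})

test_that("noiseless empirical mixtures lie exactly on the forward curve", {
  g <- simulate_sn_mixture(0.5, pc)
  expect_equal(sn_ratio_of(g), 0.40 * exp(1.91 * 0.5), tolerance = 1e-12)
  expect_equal(sum(g$fragments$area), 1000, tolerance = 1e-9)
  s <- simulate_calibration_series(pc)
  expect_equal(s$ratio, predict(pc, s$fraction), tolerance = 1e-12)
})

test_that("the mechanistic mixing curve is symmetric at one-to-one", {
  g <- simulate_sn_mixture(0.5, pc, mode = "mechanistic")
  expect_equal(sn_ratio_of(g), 1.0, tolerance = 1e-12)
  # pure isomers hit the calibration endpoints
  g0 <- simulate_sn_mixture(0, pc, mode = "mechanistic")
  g1 <- simulate_sn_mixture(1, pc, mode = "mechanistic")
  rho <- pc$c1 * exp(pc$c2)
  expect_equal(sn_ratio_of(g0), 1 / rho, tolerance = 1e-12)
  expect_equal(sn_ratio_of(g1), rho, tolerance = 1e-12)
})

test_that("refitting a simulated calibration series recovers the generator", {
  s <- simulate_calibration_series(pc)
  fit <- fit_sn_calibration(s$fraction, s$ratio)
  expect_equal(unname(coef(fit)), c(0.40, 1.91), tolerance = 1e-9)
  s5 <- simulate_calibration_series(pc,
    noise = noise_model("lognormal", cv = 5, seed = 101))
  fit5 <- fit_sn_calibration(s5$fraction, s5$ratio)
  expect_lt(abs(fit5$c1 - 0.40) / 0.40, 0.10)
  expect_lt(abs(fit5$c2 - 1.91) / 1.91, 0.10)
})

test_that("annotated sn mixtures label fragments with chain tokens", {
  g <- simulate_sn_mixture(0.3, pc, annotation = "PC 16:0/18:1")
  expect_equal(g$fragments$fragment, c("16:0", "18:1"))
  expect_error(simulate_sn_mixture(0.3, pc, annotation = "PC 34:1"),
               class = "snlipid_contract_error")
  expect_error(simulate_sn_mixture(1.2, pc),
               class = "snlipid_contract_error")
})

test_that("compositional mixtures round-trip through the deconvolution", {
  g <- simulate_compositional_mixture(
    c("PC 18:0_18:2" = 0.6, "PC 18:1_18:1" = 0.4))
  sh <- compositional_fractions(g)
  expect_equal(sh$share[match(c("PC 18:0_18:2", "PC 18:1_18:1"),
                              sh$isomer)],
               c(0.6, 0.4), tolerance = 1e-6)
  expect_equal(sum(sh$apportioned_ms1), g$ms1_area, tolerance = 1e-9)

  g1 <- simulate_compositional_mixture(c("PC 16:0_20:4" = 1),
                                       precursor = "PC 36:4")
  expect_equal(compositional_fractions(g1)$share, 1)
})

test_that("unequal fragment yields bias shares as the yield ratio predicts", {
  g <- simulate_compositional_mixture(
    c("PC 18:0_18:2" = 0.5, "PC 18:1_18:1" = 0.5),
    yields = c("PC 18:0_18:2" = 2, "PC 18:1_18:1" = 1))
  sh <- compositional_fractions(g)
  expect_equal(sort(sh$share, decreasing = TRUE), c(2 / 3, 1 / 3),
               tolerance = 1e-9)
})

test_that("isomers sharing a chain are rejected as non-diagnostic", {
  expect_error(simulate_compositional_mixture(
    c("PC 16:0_20:4" = 0.5, "PC 16:0_18:2" = 0.5)),
    class = "snlipid_contract_error")
  expect_error(simulate_compositional_mixture(
    c("PC 18:0_18:2" = 0.7, "PC 18:1_18:1" = 0.7)),
    class = "snlipid_contract_error")
})

test_that("PLA2 digests recover purity and leave the stated residual", {
  d <- simulate_pla2_digestion("PC 16:0/18:1", purity = 100,
                               efficiency = 100)
  expect_length(d$lyso_areas, 1L)
  expect_named(d$lyso_areas, "16:0")
  expect_equal(d$residual_precursor, 0)

  for (p in c(93, 95, 97, 99)) {
    d <- simulate_pla2_digestion("PC 16:0/18:1", purity = p)
    expect_equal(pla2_purity(d$lyso_areas, parse_lipid("PC 16:0/18:1")),
                 p, tolerance = 0.5)
  }

  d <- simulate_pla2_digestion("PC 16:0/18:1", purity = 95,
                               efficiency = 99.5, total_amount = 1000)
  expect_equal(d$residual_precursor / 1000, 0.005, tolerance = 1e-12)
})

test_that("replicate tables carry the configured noise level", {
  r0 <- simulate_replicates(c(a = 10), 4)
  expect_equal(unique(r0$value), 10)
  expect_equal(compute_cv(r0$value), 0)
  r <- simulate_replicates(c(a = 10), 1000,
    noise = noise_model("lognormal", cv = 10, seed = 55))
  cv <- compute_cv(r$value)
  expect_gt(cv, 9); expect_lt(cv, 11)
})

test_that("dilution series are geometric with a linear response", {
  s <- simulate_dilution_series(slope = 2, intercept = 0, levels = 7,
                                fold = 2)
  conc <- unique(s$concentration)
  expect_equal(max(conc) / min(conc), 64)
  expect_true(all(diff(conc) < 0))
  expect_equal(s$area, 2 * s$concentration, tolerance = 1e-12)
  expect_equal(lod_loq(s)$r_squared, 1, tolerance = 1e-12)
  expect_error(simulate_dilution_series(levels = 4),
               class = "snlipid_contract_error")
})
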