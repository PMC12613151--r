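pc <- default_sn_calibrations()$PC

test_that("sn2/sn1 ratio and class averaging follow their definitions", {
  expect_equal(compute_sn_ratio(200, 100), 2.0)
  expect_equal(compute_sn_ratio(55, 55), 1.0)
  err <- tryCatch(compute_sn_ratio(100, 0, transition = "PC 34:1 sn1"),
                  error = identity)
  expect_s3_class(err, "snlipid_missing_fragment_error")
  expect_match(conditionMessage(err), "PC 34:1 sn1")

  expect_equal(average_sn_ratio(c(2, 3)), 2.5)
  expect_equal(average_sn_ratio(4.2), 4.2)
  set.seed(3)
  x <- stats::rlnorm(9)
  expect_equal(average_sn_ratio(x), average_sn_ratio(sample(x)))
  expect_error(average_sn_ratio(numeric()), class = "snlipid_contract_error")
})

test_that("log-linear fit reproduces generating coefficients exactly on noiseless data", {
  f <- calibration_proportions()
  for (truth in list(c(0.40, 1.91), c(0.38, 1.66), c(0.72, 1.33))) {
    fit <- fit_sn_calibration(f, truth[1] * exp(truth[2] * f))
    expect_equal(unname(coef(fit)), truth, tolerance = 1e-9)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  }
})

test_that("a flat calibration fits as c2 = 0 with c1 the common ratio", {
  fit <- fit_sn_calibration(c(0.2, 0.5, 0.8), c(1.7, 1.7, 1.7))
  expect_equal(fit$c1, 1.7, tolerance = 1e-12)
  expect_equal(fit$c2, 0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1) # degenerate zero-variance response
})

test_that("fit contracts reject degenerate designs", {
  expect_error(fit_sn_calibration(c(0.1, 0.5), c(1, 2)),
               class = "snlipid_fit_error")
  expect_error(fit_sn_calibration(c(0.1, 0.1, 0.1), c(1, 2, 3)),
               class = "snlipid_fit_error")
  expect_error(fit_sn_calibration(c(0.1, 0.5, 0.9), c(1, -2, 3)),
               class = "snlipid_fit_error")
})

test_that("noisy calibration points recover the coefficients within 10%", {
  f <- calibration_proportions()
  s <- simulate_calibration_series(pc,
    noise = noise_model("lognormal", cv = 5, seed = 11))
  fit <- fit_sn_calibration(s$fraction, s$ratio)
  expect_lt(abs(fit$c1 - pc$c1) / pc$c1, 0.10)
  expect_lt(abs(fit$c2 - pc$c2) / pc$c2, 0.10)
})

test_that("forward prediction evaluates c1*exp(c2*f) and respects bounds", {
  expect_equal(predict(pc, 0), 0.40)
  expect_equal(predict(pc, 1), 0.40 * exp(1.91), tolerance = 1e-12)
  expect_equal(predict(pc, 0.5), 0.40 * exp(1.91 * 0.5), tolerance = 1e-12)
  expect_equal(predict(pc, 0.5), 1.03947, tolerance = 1e-5)
  expect_error(predict(pc, 1.2), class = "snlipid_contract_error")
  expect_error(predict(pc, -0.1), class = "snlipid_contract_error")
})

test_that("inversion round-trips the forward model and conserves 100%", {
  set.seed(19)
  for (i in 1:300) {
    cal <- sn_calibration("PC", c1 = stats::runif(1, 0.05, 5),
                          c2 = stats::runif(1, 0.2, 4))
    f <- stats::runif(1)
    dec <- sn_deconvolve(predict(cal, f), cal)
    expect_equal(dec$sna_percent, 100 * f, tolerance = 1e-9)
    expect_identical(dec$sna_percent + dec$snb_percent, 100)
    expect_false(dec$clamped)
  }
})

test_that("sna_percent is non-decreasing in the observed ratio", {
  ratios <- sort(stats::rlnorm(200, 0, 1))
  dec <- sn_deconvolve(ratios, pc)
  expect_true(all(diff(dec$sna_percent) >= 0))
})

test_that("out-of-range ratios clamp with purity flags", {
  dec <- sn_deconvolve(0.40, pc)
  expect_equal(dec$sna_percent, 0)
  expect_equal(dec$snb_percent, 100)
  expect_false(dec$clamped)

  dec <- sn_deconvolve(0.40 * exp(1.91), pc)
  expect_equal(dec$sna_percent, 100, tolerance = 1e-9)
  expect_false(dec$pure_flag)

  # ratio above the pure-SNA ratio: clamp to 100% and flag as pure
  dec <- sn_deconvolve(3.5, pc)
  expect_equal(dec$sna_percent, 100)
  expect_true(dec$pure_flag)
  expect_true(dec$clamped)

  # symmetric rule below the pure-SNB ratio
  dec <- sn_deconvolve(0.2, pc)
  expect_equal(dec$sna_percent, 0)
  expect_true(dec$clamped)
  expect_false(dec$pure_flag)

  expect_error(sn_deconvolve(-1, pc), class = "snlipid_contract_error")
  flat <- sn_calibration("PC", c1 = 1, c2 = 0)
  expect_error(sn_deconvolve(1.5, flat), class = "snlipid_contract_error")
})

test_that("exponential model tracks the mechanistic two-isomer mixing curve", {
  rho <- pc$c1 * exp(pc$c2)
  f <- seq(0, 1, by = 0.02)
  mech <- (f * rho + (1 - f)) / (f + (1 - f) * rho)
  expo <- predict(pc, f)
  expect_true(all(abs(expo - mech) / mech < 0.10))
  # refitting the exponential to mechanistic points recovers c1 within 15%
  fit <- fit_sn_calibration(calibration_proportions(), {
    fd <- calibration_proportions()
    (fd * rho + (1 - fd)) / (fd + (1 - fd) * rho)
  })
  expect_lt(abs(fit$c1 - pc$c1) / pc$c1, 0.15)
})

test_that("PLA2 lyso shares measure isomeric purity", {
  nominal <- parse_lipid("PC 16:0/18:1")
  expect_equal(pla2_purity(c("16:0" = 95, "18:1" = 5), nominal), 95)
  expect_equal(pla2_purity(c("16:0" = 10), nominal), 100)
  expect_warning(p <- pla2_purity(c("18:1" = 10), nominal), "absent")
  expect_equal(p, 0)
  expect_error(pla2_purity(c("16:0" = 1), parse_lipid("PC 34:1")),
               class = "snlipid_contract_error")
})

test_that("calibration accessors, summary and residuals behave", {
  expect_equal(coef(pc), c(c1 = 0.40, c2 = 1.91))
  s <- summary(pc)
  expect_equal(s$pure_sna_ratio, 0.40 * exp(1.91))
  out <- capture.output(print(pc))
  expect_true(any(grepl("PC", out)))

  fit <- fit_sn_calibration(calibration_proportions(),
                            predict(pc, calibration_proportions()))
  expect_equal(max(abs(residuals(fit))), 0, tolerance = 1e-9)
  expect_equal(max(abs(residuals(fit, type = "log"))), 0, tolerance = 1e-9)
})

test_that("class lookup never borrows a calibration silently", {
  cals <- default_sn_calibrations()
  expect_s3_class(sn_calibration_for("PE", cals), "sn_calibration")
  expect_s3_class(sn_calibration_for(parse_lipid("PS 16:0/18:1"), cals),
                  "sn_calibration")
  expect_error(sn_calibration_for("PI", cals),
               class = "snlipid_contract_error")
  # explicit user-provided borrowing is allowed
  cals$PI <- sn_calibration("PI", 0.5, 1.5, source = "borrowed from PC")
  expect_equal(sn_calibration_for("PI", cals)$c2, 1.5)
})
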