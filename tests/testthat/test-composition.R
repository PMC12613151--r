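two_isomer_group <- function(areas_a = c(30, 60), areas_b = c(10, 20),
                             p = 1000) {
  peak_group("s1", "PC 36:2", ms1_area = p, fragments = data.frame(
    isomer = rep(c("PC 18:0_18:2", "PC 18:1_18:1"),
                 c(length(areas_a), length(areas_b))),
    fragment = c("18:0", "18:2", "18:1", "18:1b")[seq_len(length(areas_a) +
                                                            length(areas_b))],
    area = c(areas_a, areas_b)))
}

test_that("summed-fragment apportionment divides by P and renormalises", {
  sh <- compositional_fractions(two_isomer_group())
  sh <- sh[order(sh$isomer), ]
  expect_equal(sh$raw_fraction, c(0.09, 0.03))
  expect_equal(sh$share, c(0.75, 0.25))
  expect_equal(sh$apportioned_ms1, c(750, 250))
})

test_that("a single-isomer group takes the whole precursor signal", {
  g <- peak_group("s1", "PC 34:1", 500, data.frame(
    isomer = "PC 16:0_18:1", fragment = c("16:0", "18:1"), area = c(40, 50)))
  sh <- compositional_fractions(g)
  expect_equal(sh$share, 1)
  expect_equal(sh$apportioned_ms1, 500)
})

test_that("shares are invariant under uniform fragment scaling and conserve P", {
  set.seed(23)
  for (i in 1:25) {
    a <- stats::rlnorm(2, 3, 1); b <- stats::rlnorm(2, 3, 1)
    p <- stats::rlnorm(1, 7, 0.5)
    k <- stats::rlnorm(1, 0, 1)
    s1 <- compositional_fractions(two_isomer_group(a, b, p))
    s2 <- compositional_fractions(two_isomer_group(k * a, k * b, p))
    expect_equal(s1$share, s2$share, tolerance = 1e-12)
    expect_equal(sum(s1$share), 1, tolerance = 1e-9)
    expect_equal(sum(s1$apportioned_ms1), p, tolerance = 1e-6 * p)
  }
})

test_that("groups with no fragment evidence are rejected", {
  expect_error(compositional_fractions(two_isomer_group(c(0, 0), c(0, 0))),
               class = "snlipid_no_evidence_error")
  g <- two_isomer_group()
  g$ms1_area <- 0
  expect_error(compositional_fractions(g),
               class = "snlipid_contract_error")
})

test_that("shared quantifier transitions in overlapping RT windows are flagged", {
  tr <- data.frame(
    precursor = c("PC 17:0/20:4", "PC O-18:0/20:4"),
    quantifier_mz = c(303.2330, 303.2330),
    rt_center = c(600, 620), rt_window = c(60, 60))
  expect_equal(nrow(shared_fragment_conflicts(tr)), 1L)

  tr$rt_center <- c(600, 700) # disjoint windows
  expect_equal(nrow(shared_fragment_conflicts(tr)), 0L)

  tr$rt_center <- c(600, 620)
  tr$quantifier_mz <- c(303.2330, 303.2400) # beyond 0.005 Da
  expect_equal(nrow(shared_fragment_conflicts(tr)), 0L)
})

test_that("three-way overlaps yield all pairwise conflicts, matching brute force", {
  set.seed(5)
  tr <- data.frame(
    precursor = paste0("L", 1:3),
    quantifier_mz = c(303.2330, 303.2332, 303.2329),
    rt_center = c(600, 610, 605), rt_window = 60)
  expect_equal(nrow(shared_fragment_conflicts(tr)), 3L)

  # randomized instance vs exhaustive pair enumeration
  n <- 12
  tr <- data.frame(precursor = paste0("L", seq_len(n)),
                   quantifier_mz = 300 + sample(0:3, n, TRUE) * 0.004,
                   rt_center = stats::runif(n, 0, 300), rt_window = 60)
  got <- nrow(shared_fragment_conflicts(tr))
  want <- 0L
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (abs(tr$quantifier_mz[i] - tr$quantifier_mz[j]) <= 0.005 &&
        min(tr$rt_center[i], tr$rt_center[j]) + 30 >
          max(tr$rt_center[i], tr$rt_center[j]) - 30)
      want <- want + 1L
  }
  expect_equal(got, want)
})

test_that("TG quantifier selection excludes chains shared with coeluters", {
  cand <- data.frame(chain = c("16:0", "18:1", "15:0"),
                     mz = c(575.50, 601.52, 561.49),
                     area = c(900, 700, 300))
  # no coeluters: plain max-area rule
  q <- select_tg_quantifier(cand)
  expect_true(q$quantifiable)
  expect_equal(q$chain, "16:0")

  # the most intense chain is shared: fall back to the best unshared
  q <- select_tg_quantifier(cand, coeluting = list(c("16:0", "14:0")))
  expect_equal(q$chain, "18:1")

  # all chains shared: not quantifiable
  q <- select_tg_quantifier(cand,
    coeluting = list(c("16:0", "18:1"), c("15:0")))
  expect_false(q$quantifiable)

  expect_error(select_tg_quantifier(cand[0, ]),
               class = "snlipid_contract_error")
})

test_that("a chosen TG quantifier never occurs in any coeluter's set", {
  set.seed(13)
  chains <- sprintf("%d:%d", 12:22, rep(0:2, length.out = 11))
  for (i in 1:40) {
    cand <- data.frame(chain = sample(chains, 4),
                       area = stats::rlnorm(4, 5, 1))
    co <- replicate(sample(0:3, 1),
                    sample(chains, sample(1:4, 1)), simplify = FALSE)
    q <- select_tg_quantifier(cand, co)
    if (q$quantifiable) expect_false(q$chain %in% unlist(co))
    else expect_true(all(cand$chain %in% unlist(co)))
  }
})
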