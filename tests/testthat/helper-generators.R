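# Random annotation generator for parse/format property tests, and an
# independent ordinary-least-squares oracle kept separate from the
# stats::lm-based implementation path.

random_annotation <- function() {
  classes1 <- c("LPC", "LPE", "CE", "LPC O-")
  classes2 <- c("PC", "PE", "PS", "PA", "PG", "PI", "SM", "Cer", "DG",
                "PC O-", "PE O-")
  level <- sample(c("sum_composition", "molecular_species", "sn_position"),
                  1)
  rand_chain <- function() {
    n <- sample(12:24, 1)
    fatty_acyl(n, sample(0:min(6, n %/% 2), 1))
  }
  if (level == "sum_composition") {
    cls <- sample(c(classes1, classes2, "TG"), 1)
    n <- sample(28:54, 1)
    chains <- list(fatty_acyl(n, sample(0:6, 1),
                              ether_linkage = endsWith(cls, "O-")))
  } else {
    cls <- sample(classes2, 1)
    k <- snlipid:::.CHAIN_COUNT[[cls]]
    chains <- replicate(k, rand_chain(), simplify = FALSE)
    if (endsWith(cls, "O-")) chains[[1]]$ether_linkage <- TRUE
  }
  if (stats::runif(1) < 0.3)
    chains[[length(chains)]]$deuterium_count <- sample(1:9, 1)
  snlipid:::new_lipid_annotation(cls, chains, level,
                                 iso_tag = stats::runif(1) < 0.2)
}

# OLS of y on x via the normal equations (hand-coded, no lm)
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(crossprod(X), crossprod(X, y))
  resid <- y - X %*% beta
  sigma <- sqrt(sum(resid^2) / (length(y) - 2))
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  list(intercept = beta[1], slope = beta[2], sigma = sigma, r_squared = r2)
}
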