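test_that("default sampler settings match the trial analysis plan", {
  s <- mcmc_settings()
  expect_equal(s$n_chains, 4L)
  expect_equal(s$burn_in, 1000L)
  expect_equal(s$samples_per_chain, 4000L)
  expect_equal(s$n_chains * s$samples_per_chain, 16000L)
})

test_that("split R-hat is near 1 for identical well-mixed chains and large for separated ones", {
  set.seed(1)
  one <- rnorm(1000)
  expect_lt(abs(rhat(cbind(one, one)) - 1), 0.01)

  sep <- cbind(rnorm(1000, 0, 1), rnorm(1000, 5, 1))
  expect_gt(rhat(sep), 1.05)

  expect_error(rhat(matrix(rnorm(100), ncol = 1)), "2 chains")
  expect_error(rhat(matrix(rnorm(4), ncol = 2)), "4 samples")
})

test_that("R-hat matches an independently coded formula oracle", {
  # hand toy: two identical trending chains; splitting exposes the trend
  toy <- list(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(rhat(toy), rhat_oracle(toy), tolerance = 1e-12)
  expect_gt(rhat(toy), 1.05)   # a pure trend must not look converged
  set.seed(2)
  for (i in 1:10) {
    chains <- lapply(1:4, function(j) rnorm(200, mean = 0.2 * j))
    expect_equal(rhat(chains), rhat_oracle(chains), tolerance = 1e-12)
  }
})

test_that("R-hat is invariant to chain permutation", {
  set.seed(3)
  m <- matrix(rnorm(4 * 500, mean = rep(c(0, 0.3, 0, 0.1), each = 500)), ncol = 4)
  expect_equal(rhat(m), rhat(m[, c(3, 1, 4, 2)]), tolerance = 1e-12)
})

test_that("posterior exceedance probability is a draw fraction", {
  expect_equal(posterior_prob_exceeds(rep(1, 50), 0.78), 1)
  # draws 0.1..1.0: strictly above 0.78 are 0.8, 0.9, 1.0
  expect_equal(posterior_prob_exceeds(seq(0.1, 1.0, by = 0.1), 0.78), 0.3)
  set.seed(4)
  sym <- 0.78 + rnorm(20000)
  expect_equal(posterior_prob_exceeds(sym, 0.78), 0.5, tolerance = 0.02)
  expect_error(posterior_prob_exceeds(numeric(0), 1), "empty")
})

test_that("individual fit matches the semi-conjugate posterior oracle", {
  set.seed(5)
  rec <- data.frame(participant_id = "P01",
                    food_code = rep(LETTERS[1:5], each = 3),
                    pbgp = rnorm(15, rep(c(10, 8.5, 9.2, 11, 7.9), each = 3), 1.2))
  fit <- fit_individual(rec, settings = mcmc_settings(seed = 6))
  f <- factor(rec$food_code, levels = LETTERS[1:5])
  X <- model.matrix(~f)
  oracle <- semiconj_oracle(X, rec$pbgp)
  smry <- summary(fit)
  betas <- match(c("beta0", sprintf("beta[%s]", LETTERS[2:5])), smry$parameter)
  for (i in seq_along(betas)) {
    row <- smry[betas[i], ]
    expect_lt(abs(row$mean - oracle$mean[i]), 3 * row$mcse + 0.005)
    expect_lt(abs(row$sd - oracle$sd[i]), 0.03)
  }
})

test_that("sampler is deterministic under its seed", {
  rec <- make_outcomes(n = 1, seed = 10)$outcomes
  f1 <- fit_individual(rec, settings = mcmc_settings_fast(seed = 7))
  f2 <- fit_individual(rec, settings = mcmc_settings_fast(seed = 7))
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_individual(rec, settings = mcmc_settings_fast(seed = 8))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("equal-mean foods give symmetric, sub-coin-flip MCID probabilities", {
  set.seed(9)
  rec <- data.frame(participant_id = "P01",
                    food_code = rep(LETTERS[1:5], each = 3),
                    pbgp = rnorm(15, 10, 1.2))
  fit <- fit_individual(rec, settings = mcmc_settings(seed = 10))
  P <- pairwise_mcid_probs(fit, 0.78)
  # under equal true means no pair should approach certainty, and the
  # average exceedance probability stays well below a coin flip
  expect_true(all(P[!is.na(P)] < 0.9))
  expect_lt(mean(P[!is.na(P)]), 0.45)
  # relabeling foods permutes the matrix identically (symmetry oracle)
  swap <- c(A = "B", B = "A", C = "C", D = "D", E = "E")
  rec2 <- rec; rec2$food_code <- unname(swap[rec$food_code])
  fit2 <- fit_individual(rec2, settings = mcmc_settings(seed = 10))
  P2 <- pairwise_mcid_probs(fit2, 0.78)
  for (j in LETTERS[1:5]) for (k in LETTERS[1:5]) {
    if (j != k) expect_equal(P[j, k], P2[swap[j], swap[k]], tolerance = 0.05)
  }
})

test_that("pairwise contrasts are invariant to the reference food", {
  rec <- make_outcomes(n = 1, seed = 12,
                       offsets = c(A = 2, B = 0, C = 1, D = -1, E = 0))$outcomes
  fa <- fit_individual(rec, reference = "A", settings = mcmc_settings(seed = 13))
  fb <- fit_individual(rec, reference = "B", settings = mcmc_settings(seed = 14))
  for (pair in list(c("C", "D"), c("A", "E"), c("B", "D"))) {
    da <- contrast_draws(fa, pair[1], pair[2])
    db <- contrast_draws(fb, pair[1], pair[2])
    tol <- 3 * sqrt(var(da) / 2000 + var(db) / 2000) + 0.01
    expect_lt(abs(mean(da) - mean(db)), tol)
  }
})

test_that("posterior SD of food effects shrinks with more replicates", {
  plan3 <- randomize_plan("P01", 3, LETTERS[1:5], seed = 15)
  plan12 <- randomize_plan("P01", 12, LETTERS[1:5], seed = 15)
  params <- truth_params(seed = 16, between_sd = 1.77, within_sd = 1.2)
  r3 <- simulate_outcomes(plan3, params)$outcomes
  r12 <- simulate_outcomes(plan12, params)$outcomes
  f3 <- fit_individual(r3, settings = mcmc_settings(seed = 17))
  f12 <- fit_individual(r12, settings = mcmc_settings(seed = 17))
  s3 <- f3$summary; s12 <- f12$summary
  for (fc in LETTERS[2:5]) {
    p <- sprintf("beta[%s]", fc)
    expect_lt(s12$sd[s12$parameter == p], s3$sd[s3$parameter == p])
  }
})

test_that("fit_individual validates its inputs", {
  rec <- make_outcomes(n = 2, seed = 18)$outcomes
  expect_error(fit_individual(rec), "single participant")
  one <- rec[rec$participant_id == "P01", ]
  expect_error(fit_individual(one, food_codes = LETTERS[1:6]), "F")
  thin <- one[!(one$food_code == "B" & one$period > 1), ]
  expect_error(fit_individual(thin, settings = mcmc_settings_fast(seed = 1)),
               "fewer than 2")
})
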