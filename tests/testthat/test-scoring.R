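test_that("MCID derivation uses decimal half-to-even rounding", {
  expect_equal(mcid_from_reference(3.89, 0.20)$value, 0.78)
  expect_equal(mcid_from_reference(1067.85, 0.10)$value, 106.78)
  expect_equal(mcid_from_reference(10, 0.5)$value, 5.00)
  expect_error(mcid_from_reference(0, 0.2), "> 0")
  expect_error(mcid_from_reference(3.89, -0.1), "> 0")
})

test_that("pairwise MCID probabilities count contrast draws", {
  # degenerate: all foods identical -> every probability 0
  eq <- fake_fit(list(B = rep(0, 10), C = rep(0, 10)), reference = "A")
  P <- pairwise_mcid_probs(eq, 0.78)
  expect_true(all(P[!is.na(P)] == 0))
  expect_true(all(is.na(diag(P))))

  # constant separation of 1.0 > MCID: one-sided certainty
  sep <- fake_fit(list(B = rep(1, 10)), reference = "A")
  P2 <- pairwise_mcid_probs(sep, 0.78)
  expect_equal(P2["B", "A"], 1)
  expect_equal(P2["A", "B"], 0)

  # ten listed paired draws against the brute-force counting oracle
  bd <- c(0.1, 0.3, 0.5, 0.7, 0.79, 0.8, 0.9, 1.0, 1.5, 2.0)
  cd <- rep(0.1, 10)
  f <- fake_fit(list(B = bd, C = cd), reference = "A")
  P3 <- pairwise_mcid_probs(f, 0.78)
  count <- function(x, y) sum(x - y > 0.78) / length(x)
  expect_equal(P3["B", "A"], count(bd, 0))
  expect_equal(P3["B", "A"], 0.6)   # strict exceedance: 0.79 counts, 0.7 does not
  expect_equal(P3["B", "C"], count(bd, cd))
  expect_equal(P3["C", "B"], count(cd, bd))
})

test_that("replicate CV is sample SD over mean with a floor", {
  rec <- data.frame(participant_id = "P1",
                    food_code = rep(c("A", "B"), each = 3),
                    pbgp = c(8, 10, 12, 10, 10, 10))
  cv <- replicate_cv(rec)
  expect_equal(cv[["A"]], 2 / 10)       # sample SD (n-1) / mean
  expect_equal(cv[["B"]], 0.01)         # zero variance floored
  single <- data.frame(participant_id = "P1", food_code = c("A", "A", "B"),
                       pbgp = c(9, 10, 10))
  expect_error(replicate_cv(single), "fewer than 2")
  neg <- data.frame(participant_id = "P1",
                    food_code = rep(c("A", "B"), each = 2),
                    pbgp = c(-3, 1, 9, 10))
  expect_error(replicate_cv(neg), "nonpositive mean")
})

test_that("WGRS is the CV-reciprocal weighted mean of exceedance probabilities", {
  # direct evaluation of the published weighting
  expect_equal(wgrs(c(B = 0.9, C = 0.5), c(B = 0.1, C = 0.2)),
               (0.9 * 10 + 0.5 * 5) / 15)
  expect_equal(round(wgrs(c(B = 0.9, C = 0.5), c(B = 0.1, C = 0.2)), 4), 0.7667)
  # constant probabilities are returned untouched whatever the CVs
  set.seed(31)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    p <- runif(1)
    cv <- runif(k, 0.01, 0.6)
    expect_equal(wgrs(rep(p, k), cv), p, tolerance = 1e-12)
  }
  expect_equal(wgrs(c(1, 0), c(0.3, 0.3)), 0.5)
  expect_error(wgrs(numeric(0), numeric(0)), "empty")
})

test_that("WGRS stays in [0, 1] and responds more to low-CV comparators", {
  set.seed(32)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    p <- runif(k); cv <- runif(k, 0.01, 1)
    s <- wgrs(p, cv)
    expect_gte(s, 0); expect_lte(s, 1)
  }
  # raising the probability of the smallest-CV comparator moves the score
  # more than the same raise on the largest-CV comparator
  p <- c(0.2, 0.2, 0.2); cv <- c(0.05, 0.2, 0.5)
  base <- wgrs(p, cv)
  up_small <- wgrs(p + c(0.3, 0, 0), cv)
  up_large <- wgrs(p + c(0, 0, 0.3), cv)
  expect_gt(up_small - base, up_large - base)
})

test_that("wgrs_table scores every food and ranks them", {
  sim <- make_outcomes(n = 1, seed = 33,
                       offsets = c(A = 3, B = 0, C = 0, D = 0, E = -1))
  fit <- fit_individual(sim$outcomes, settings = mcmc_settings(seed = 34))
  tab <- wgrs_table(fit, mcid_from_reference(3.89, 0.20))
  expect_setequal(tab$food_code, LETTERS[1:5])
  expect_true(all(tab$wgrs >= 0 & tab$wgrs <= 1))
  # the food with the large positive offset is the least desirable
  expect_equal(tab$food_code[which.max(tab$wgrs)], "A")
  expect_equal(tab$rank[which.max(tab$wgrs)], 5L)
  P <- attr(tab, "prob_matrix")
  expect_equal(dim(P), c(5, 5))
  cv <- attr(tab, "cv")
  # WGRS row recomputable from the attached matrix and CVs
  for (j in LETTERS[1:5]) {
    comp <- setdiff(LETTERS[1:5], j)
    expect_equal(tab$wgrs[tab$food_code == j], wgrs(P[j, comp], cv[comp]))
  }
})

test_that("relabeling foods permutes the WGRS table identically", {
  sim <- make_outcomes(n = 1, seed = 35,
                       offsets = c(A = 2, B = -1, C = 0, D = 0.5, E = 0))
  fit1 <- fit_individual(sim$outcomes, settings = mcmc_settings(seed = 36))
  tab1 <- wgrs_table(fit1, 0.78)
  swap <- c(A = "D", B = "B", C = "C", D = "A", E = "E")
  rec2 <- sim$outcomes; rec2$food_code <- unname(swap[rec2$food_code])
  fit2 <- fit_individual(rec2, settings = mcmc_settings(seed = 36))
  tab2 <- wgrs_table(fit2, 0.78)
  for (j in LETTERS[1:5]) {
    expect_equal(tab1$wgrs[tab1$food_code == j],
                 tab2$wgrs[tab2$food_code == swap[j]], tolerance = 0.05)
  }
})

test_that("population MCID decisions threshold the pairwise probabilities", {
  null_fit <- fake_fit(list(B = rep(0, 20), C = rep(0, 20)), reference = "A",
                       population = TRUE)
  d <- population_mcid_decision(null_fit, 0.78)
  expect_false(any(d$decision))
  focal <- fake_fit(list(B = rep(2.4, 20)), reference = "A", population = TRUE)
  d2 <- population_mcid_decision(focal, 0.78)
  expect_equal(d2$probability[d2$food_j == "B" & d2$food_k == "A"], 1)
  expect_true(d2$decision[d2$food_j == "B" & d2$food_k == "A"])
  expect_error(population_mcid_decision(focal, 0.78, threshold = 1.2),
               "between 0 and 1")
})
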