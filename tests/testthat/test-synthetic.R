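t0 <- as.POSIXct("2025-01-01 08:00:00", tz = "UTC")

test_that("degenerate variances collapse outcomes onto the population means", {
  offs <- c(A = 2.4, B = 0, C = 0, D = 0, E = -1)
  plan <- randomize_plan(c("P1", "P2"), 3, LETTERS[1:5], seed = 1)
  params <- truth_params(food_offsets = offs, between_sd = 0,
                         within_sd = 1e-9, seed = 2)
  sim <- simulate_outcomes(plan, params)
  expect_equal(sim$outcomes$pbgp, 10 + unname(offs[sim$outcomes$food_code]),
               tolerance = 1e-6)
})

test_that("simulated moments match the generative SDs (moment oracle)", {
  plan <- randomize_plan(sprintf("P%03d", 1:200), 3, LETTERS[1:5], seed = 3)
  params <- truth_params(between_sd = 2.5, within_sd = 1.2, seed = 4)
  sim <- simulate_outcomes(plan, params)
  cellmeans <- aggregate(pbgp ~ participant_id + food_code, sim$outcomes, mean)
  # a participant-level food mean carries between variance plus within/3
  expected_sd <- sqrt(2.5^2 + 1.2^2 / 3)
  n_cells <- nrow(cellmeans)
  se_sd <- expected_sd / sqrt(2 * (n_cells - 1))
  expect_lt(abs(sd(cellmeans$pbgp - ave(cellmeans$pbgp, cellmeans$food_code)) -
                  expected_sd), 3 * se_sd + 0.02)
  # pooled replicate SD around each (participant, food) mean
  resid <- sim$outcomes$pbgp -
    ave(sim$outcomes$pbgp, sim$outcomes$participant_id, sim$outcomes$food_code)
  pooled <- sqrt(sum(resid^2) / (nrow(sim$outcomes) - n_cells))
  expect_lt(abs(pooled - 1.2), 3 * 1.2 / sqrt(2 * (nrow(sim$outcomes) - n_cells)))
})

test_that("between/within SDs are recovered within 5% at n = 500", {
  plan <- randomize_plan(sprintf("P%03d", 1:500), 3, LETTERS[1:5], seed = 5)
  params <- truth_params(between_sd = 2.5, within_sd = 1.2, seed = 6)
  sim <- simulate_outcomes(plan, params)
  cellmeans <- aggregate(pbgp ~ participant_id + food_code, sim$outcomes, mean)
  resid <- sim$outcomes$pbgp -
    ave(sim$outcomes$pbgp, sim$outcomes$participant_id, sim$outcomes$food_code)
  within_hat <- sqrt(sum(resid^2) / (nrow(sim$outcomes) - nrow(cellmeans)))
  centered <- cellmeans$pbgp - ave(cellmeans$pbgp, cellmeans$food_code)
  between_hat <- sqrt(var(centered) - within_hat^2 / 3)
  expect_lt(abs(within_hat - 1.2) / 1.2, 0.05)
  expect_lt(abs(between_hat - 2.5) / 2.5, 0.05)
})

test_that("identical seeds give byte-identical simulated tables", {
  s1 <- make_outcomes(n = 10, seed = 42)
  s2 <- make_outcomes(n = 10, seed = 42)
  expect_identical(s1$outcomes, s2$outcomes)
  expect_identical(s1$truth, s2$truth)
  s3 <- make_outcomes(n = 10, seed = 43)
  expect_false(identical(s1$outcomes$pbgp, s3$outcomes$pbgp))
})

test_that("simulate_trace round-trips its target peak through the extractor", {
  flat <- simulate_trace(7.0, 7.0, t0)
  expect_equal(as.numeric(compute_pbgp(flat, t0)), 7.0)
  expect_equal(as.numeric(compute_iauc3h(flat, t0)), 0)

  tr <- simulate_trace(11.0, 7.0, t0)
  expect_equal(as.numeric(compute_pbgp(tr, t0)), 11.0)
  # decays to within 0.2 mmol/L of baseline by 180 min
  expect_lt(abs(tail(tr$samples$glucose, 1) - 7.0), 0.2 + 1e-9)
  expect_error(simulate_trace(6.0, 7.0, t0), "baseline")
})

test_that("doubling the excursion height doubles the iAUC within 1%", {
  a1 <- as.numeric(compute_iauc3h(simulate_trace(9.0, 7.0, t0), t0))
  a2 <- as.numeric(compute_iauc3h(simulate_trace(11.0, 7.0, t0), t0))
  expect_equal(a2 / a1, 2, tolerance = 0.01)
})

test_that("a batch of synthetic traces round-trips through extract_outcomes", {
  set.seed(9)
  peaks <- round(runif(10, 8, 14), 2)
  traces <- list(); rows <- list()
  for (i in seq_along(peaks)) {
    pid <- sprintf("P%02d", i)
    bite <- t0 + (i - 1) * 86400
    traces[[pid]] <- simulate_trace(peaks[i], 7.0, bite, participant_id = pid)
    rows[[i]] <- data.frame(participant_id = pid, period = 1, day = i,
                            food_code = "A", first_bite = bite)
  }
  out <- extract_outcomes(traces, do.call(rbind, rows))
  expect_equal(out$pbgp[match(sprintf("P%02d", seq_along(peaks)),
                              out$participant_id)], peaks)
  # iAUC within grid tolerance of the trapezoid oracle on the same trace
  for (i in seq_along(peaks)) {
    pid <- sprintf("P%02d", i)
    st <- traces[[pid]]$samples
    rel <- as.numeric(st$time - st$time[1], units = "mins") - 30
    inwin <- rel >= 0
    expect_equal(out$iauc3h[out$participant_id == pid],
                 trapz_oracle(rel[inwin], pmax(st$glucose[inwin] - 7.0, 0)),
                 tolerance = 1e-9)
  }
})

test_that("write_synthetic labels the truth table as analysis-forbidden", {
  sim <- make_outcomes(n = 3, seed = 8)
  dir <- withr::local_tempdir()
  paths <- write_synthetic(sim, dir)
  expect_match(readLines(paths["truth"], n = 1), "DO NOT USE IN ANALYSIS")
  back <- read.csv(paths["outcomes"])
  expect_equal(nrow(back), nrow(sim$outcomes))
})
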