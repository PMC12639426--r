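t0 <- as.POSIXct("2025-01-01 08:00:00", tz = "UTC")

write_cgm_file <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "cgm.csv")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

test_that("read_cgm parses well-formed files and validates pathologies", {
  times <- format(t0 + c(0, 300, 600), "%Y-%m-%dT%H:%M:%S")
  ok <- data.frame(participant_id = "P01", timestamp = times,
                   glucose_mmol_per_L = c(6.5, 7.0, 7.2))
  traces <- read_cgm(write_cgm_file(ok))
  expect_length(traces, 1)
  expect_equal(nrow(traces$P01$samples), 3)

  bad_glucose <- ok; bad_glucose$glucose_mmol_per_L[2] <- -1
  expect_error(read_cgm(write_cgm_file(bad_glucose)), "glucose")

  shuffled <- ok[c(1, 3, 2), ]   # first offender: the 08:05 row after 08:10
  expect_error(read_cgm(write_cgm_file(shuffled)), "08:05")

  dup <- ok; dup$timestamp[2] <- dup$timestamp[1]
  expect_error(read_cgm(write_cgm_file(dup)), "order|duplicated")

  nocol <- ok; names(nocol)[3] <- "glucose"
  expect_error(read_cgm(write_cgm_file(nocol)), "glucose_mmol_per_L")

  badtime <- ok; badtime$timestamp[1] <- "yesterday-ish"
  expect_error(read_cgm(write_cgm_file(badtime)), "yesterday-ish")
})

test_that("PBGP is the in-window maximum on the grid", {
  flat <- make_trace(rep(7, 43))
  expect_equal(as.numeric(compute_pbgp(flat, t0)), 7)

  # rise to 12.3 at +60 min then fall; oracle scans all in-window samples
  rel <- seq(-30, 180, by = 5)
  vals <- 6 + 6.3 * pmax(0, 1 - abs(rel - 60) / 90)
  vals[rel == 60] <- 12.3
  tr <- make_trace(vals)
  inwin <- vals[rel >= 0 & rel <= 180]
  expect_equal(as.numeric(compute_pbgp(tr, t0)), max(inwin))
  expect_equal(as.numeric(compute_pbgp(tr, t0)), 12.3)
  expect_equal(attr(compute_pbgp(tr, t0), "peak_time"), t0 + 3600)

  # a larger excursion outside the 3-h window must be ignored
  rel2 <- seq(-30, 240, by = 5)
  vals2 <- rep(7, length(rel2))
  vals2[rel2 == 120] <- 11.1
  vals2[rel2 == 200] <- 13.0
  tr2 <- make_trace(vals2)
  expect_equal(as.numeric(compute_pbgp(tr2, t0)), 11.1)
})

test_that("PBGP is monotone in the trace", {
  set.seed(42)
  for (i in 1:20) {
    lo <- make_trace(runif(43, 5, 9))
    hi <- make_trace(lo$samples$glucose + runif(43, 0, 2))
    expect_gte(as.numeric(compute_pbgp(hi, t0)), as.numeric(compute_pbgp(lo, t0)))
  }
})

test_that("iAUC matches hand geometry on canonical shapes", {
  rel <- seq(-30, 180, by = 5)
  base <- 6.2
  expect_equal(as.numeric(compute_iauc3h(make_trace(rep(base, 43)), t0)), 0)

  rect <- ifelse(rel < 0, base, base + 2)
  expect_equal(as.numeric(compute_iauc3h(make_trace(rect), t0)), 360)

  tri <- base + ifelse(rel < 0, 0, ifelse(rel <= 90, 3 * rel / 90,
                                          3 * (180 - rel) / 90))
  expect_equal(as.numeric(compute_iauc3h(make_trace(tri), t0)), 270)
  expect_equal(attr(compute_iauc3h(make_trace(tri), t0), "baseline"), base)
})

test_that("iAUC agrees with the trapezoid oracle and clamps negatives", {
  set.seed(11)
  rel <- seq(-30, 180, by = 5)
  for (i in 1:20) {
    vals <- 7 + cumsum(rnorm(length(rel), 0, 0.4))
    vals <- pmax(vals, 0.5)
    tr <- make_trace(vals)
    base <- vals[rel == -30]
    inwin <- rel >= 0
    expected <- trapz_oracle(rel[inwin], pmax(vals[inwin] - base, 0))
    expect_equal(as.numeric(compute_iauc3h(tr, t0)), expected, tolerance = 1e-9)
    net <- trapz_oracle(rel[inwin], vals[inwin] - base)
    expect_equal(as.numeric(compute_iauc3h(tr, t0, net_auc = TRUE)), net,
                 tolerance = 1e-9)
  }
})

test_that("iAUC is invariant to adding a constant to the whole trace", {
  set.seed(3)
  rel <- seq(-30, 180, by = 5)
  vals <- 7 + pmax(0, rnorm(length(rel), 1, 1))
  a0 <- as.numeric(compute_iauc3h(make_trace(vals), t0))
  a1 <- as.numeric(compute_iauc3h(make_trace(vals + 2.5), t0))
  expect_equal(a0, a1, tolerance = 1e-12)
})

test_that("iAUC requires a baseline sample near -30 min", {
  rel <- seq(0, 180, by = 5)    # no pre-meal history at all
  tr <- make_trace(rep(7, length(rel)), start_min = 0)
  expect_error(compute_iauc3h(tr, t0), "baseline")
})

test_that("short interior gaps are interpolated, long gaps fail QC", {
  rel <- seq(-30, 180, by = 5)
  vals <- rep(7, length(rel)); vals[rel == 60] <- 10
  drop2 <- !(rel %in% c(30, 35))          # 2 consecutive missing: recoverable
  tr2 <- cgm_trace("P01", t0 + rel[drop2] * 60, vals[drop2])
  pb <- compute_pbgp(tr2, t0)
  expect_equal(as.numeric(pb), 10)
  expect_match(paste(attr(pb, "qc_flags"), collapse = " "), "interpolated=2")

  drop3 <- !(rel %in% c(30, 35, 40))      # 3 consecutive missing: QC failure
  times3 <- t0 + rel[drop3] * 60
  tr3 <- cgm_trace("P01", times3, vals[drop3])
  expect_error(compute_pbgp(tr3, t0), "gap")

  short <- rel <= 60                      # window covers only 1/3 of 3 h
  trs <- cgm_trace("P01", t0 + rel[short] * 60, vals[short])
  expect_error(compute_pbgp(trs, t0), "cover")
})

test_that("extract_outcomes yields one record per matched meal event", {
  rel <- seq(-30, 180, by = 5)
  mk <- function(day) 7 + 3 * exp(-((rel - 45) / 40)^2) * (rel >= 0)
  traces <- list()
  log_rows <- list()
  for (p in c("P01", "P02", "P03")) {
    day_vals <- do.call(c, lapply(1:5, mk))
    day_times <- do.call(c, lapply(1:5, function(d) t0 + (d - 1) * 86400 + rel * 60))
    traces[[p]] <- cgm_trace(p, day_times, day_vals)
    log_rows[[p]] <- data.frame(
      participant_id = p, period = 1, day = 1:5, food_code = LETTERS[1:5],
      first_bite = t0 + (0:4) * 86400)
  }
  meal_log <- do.call(rbind, log_rows)
  out <- extract_outcomes(traces, meal_log)
  expect_equal(nrow(out), 15)
  expect_true(all(out$iauc3h >= 0))

  orphan <- rbind(meal_log,
                  data.frame(participant_id = "P99", period = 2, day = 1,
                             food_code = "A", first_bite = t0))
  expect_error(extract_outcomes(traces, orphan), "P99")
  expect_warning(out2 <- extract_outcomes(traces, orphan, skip_unmatched = TRUE),
                 "P99")
  expect_equal(nrow(out2), 15)
})
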