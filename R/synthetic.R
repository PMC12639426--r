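# Synthetic trial data with the study's stated variance structure:
# participant-level true food effects (between-individual variation),
# replicate-level observation noise (within-individual variation), and —
# when requested — full CGM traces that round-trip through the endpoint
# extraction.

#' Truth parameters for the synthetic trial
#'
#' Defines the generative model for peak glucose outcomes. Participant `i`'s
#' true PBGP for food `j` is drawn once as
#' `Normal(grand_mean + food_offsets[j], between_sd)`; each replicate
#' observation is then `Normal(true effect, within_sd)`.
#'
#' @param food_codes Food labels (default `LETTERS[1:5]`).
#' @param grand_mean_pbgp Population mean peak, mmol/L (default 10).
#' @param food_offsets Named numeric vector of population mean food effects,
#'   mmol/L; defaults to 0 for every food.
#' @param between_sd Between-individual SD of the per-food true effects,
#'   mmol/L (>= 0).
#' @param within_sd Within-individual (replicate) SD, mmol/L (> 0); the study
#'   value is 1.2.
#' @param baseline_mean,baseline_sd Fasting baseline distribution, mmol/L.
#' @param seed Integer RNG seed.
#' @return An object of class `truth_params`.
#' @export
truth_params <- function(food_codes = LETTERS[1:5], grand_mean_pbgp = 10,
                         food_offsets = NULL, between_sd = 2.5,
                         within_sd = 1.2, baseline_mean = 7.5,
                         baseline_sd = 1.0, seed = NULL) {
  food_codes <- as.character(food_codes)
  if (is.null(food_offsets)) {
    food_offsets <- stats::setNames(numeric(length(food_codes)), food_codes)
  }
  if (!all(food_codes %in% names(food_offsets))) {
    stop_domain("food_offsets must name every food: missing %s",
                paste(setdiff(food_codes, names(food_offsets)), collapse = ", "))
  }
  if (between_sd < 0) stop_domain("between_sd must be >= 0")
  if (within_sd <= 0) stop_domain("within_sd must be > 0")
  structure(
    list(food_codes = food_codes, grand_mean_pbgp = grand_mean_pbgp,
         food_offsets = food_offsets[food_codes], between_sd = between_sd,
         within_sd = within_sd, baseline_mean = baseline_mean,
         baseline_sd = baseline_sd, seed = seed),
    class = "truth_params"
  )
}

#' Simulate trial outcomes under a design plan
#'
#' Draws each participant's true per-food effect once, then one observed
#' outcome per scheduled (participant, period, food) meal. The truth table is
#' returned alongside the observable outcomes for parameter-recovery checks;
#' it must never enter an analysis.
#'
#' @param design A [randomize_plan()] plan; its foods must match `params`.
#' @param params A [truth_params()] object.
#' @return A list with `outcomes` (data frame `participant_id, food_code,
#'   period, pbgp, iauc3h, baseline, qc_flags`; `iauc3h` is `NA` unless traces
#'   are generated) and `truth` (data frame `participant_id, food_code,
#'   true_effect, baseline`).
#' @export
simulate_outcomes <- function(design, params) {
  stopifnot(inherits(design, "design_plan"), inherits(params, "truth_params"))
  if (!setequal(design$food_codes, params$food_codes)) {
    stop_domain("design foods (%s) do not match truth params foods (%s)",
                paste(design$food_codes, collapse = ","),
                paste(params$food_codes, collapse = ","))
  }
  ids <- design$participant_ids
  foods <- params$food_codes
  with_seed(params$seed, {
    truth <- expand.grid(participant_id = ids, food_code = foods,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    truth <- truth[order(truth$participant_id, truth$food_code), ]
    mu <- params$grand_mean_pbgp + params$food_offsets[truth$food_code]
    truth$true_effect <- stats::rnorm(nrow(truth), mu, params$between_sd)
    base <- stats::setNames(
      stats::rnorm(length(ids), params$baseline_mean, params$baseline_sd), ids)
    truth$baseline <- base[truth$participant_id]
    key <- paste(truth$participant_id, truth$food_code)
    eff <- stats::setNames(truth$true_effect, key)

    sched <- design$sequences
    out <- data.frame(participant_id = sched$participant_id,
                      food_code = sched$food_code, period = sched$period,
                      stringsAsFactors = FALSE)
    out <- out[order(out$participant_id, out$period, out$food_code), ]
    out$pbgp <- stats::rnorm(nrow(out),
                             eff[paste(out$participant_id, out$food_code)],
                             params$within_sd)
    out$iauc3h <- NA_real_
    out$baseline <- base[out$participant_id]
    out$qc_flags <- ""
    rownames(out) <- rownames(truth) <- NULL
    list(outcomes = out, truth = truth)
  })
}

#' Synthesize a CGM excursion with a known peak
#'
#' Builds a meal excursion on the nominal grid: 30 min of flat baseline
#' history, a piecewise-linear rise to `target_peak` at `time_to_peak`
#' minutes (a grid point, so the in-window maximum equals `target_peak`
#' exactly), then an exponential decay of fixed shape (2% of the excursion
#' remaining at the horizon, i.e. within 0.2 mmol/L of baseline for
#' excursions up to 10 mmol/L), so the whole trace scales linearly in the
#' excursion height.
#'
#' @param target_peak Peak glucose, mmol/L (>= `baseline`).
#' @param baseline Fasting glucose, mmol/L.
#' @param first_bite `POSIXct` meal time (snapped to the grid).
#' @param participant_id Identifier for the trace.
#' @param time_to_peak Minutes from first bite to peak (default 45; rounded
#'   to the grid).
#' @param horizon_min Trace extent after the first bite (default 180).
#' @param interval Grid interval, minutes (default 5).
#' @return A [cgm_trace()] spanning `[first_bite - 30, first_bite + horizon]`.
#' @export
simulate_trace <- function(target_peak, baseline, first_bite,
                           participant_id = "SYN", time_to_peak = 45,
                           horizon_min = 180, interval = 5) {
  if (target_peak < baseline) {
    stop_domain("target_peak (%g) must be >= baseline (%g)", target_peak, baseline)
  }
  tp <- round_half_up(time_to_peak / interval) * interval
  rel <- seq(-30, horizon_min, by = interval)
  amp <- target_peak - baseline
  g <- numeric(length(rel))
  rise <- rel >= 0 & rel <= tp
  g[rel < 0] <- baseline
  g[rise] <- baseline + amp * rel[rise] / tp
  post <- rel > tp
  # fixed decay shape (2% of the excursion left at the horizon), so the
  # trace scales linearly in the excursion height
  lambda <- log(50) / (horizon_min - tp)
  g[post] <- baseline + amp * exp(-lambda * (rel[post] - tp))
  times <- as.POSIXct(first_bite, tz = "UTC") + rel * 60
  cgm_trace(participant_id, times, g, nominal_interval = interval)
}

#' Write synthetic trial files
#'
#' Emits the same file formats consumed by the analysis side (CGM file, meal
#' log, outcome table) plus the truth table, which carries a "DO NOT USE IN
#' ANALYSIS" header comment.
#'
#' @param sim Result of [simulate_outcomes()].
#' @param dir Output directory (created if needed).
#' @param sep Field separator.
#' @return Invisibly, named vector of written paths.
#' @export
write_synthetic <- function(sim, dir, sep = ",") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out_path <- file.path(dir, "outcomes.csv")
  truth_path <- file.path(dir, "truth.csv")
  write_outcomes(sim$outcomes, out_path, sep = sep)
  con <- file(truth_path, "w")
  writeLines("# TRUTH TABLE - DO NOT USE IN ANALYSIS (parameter-recovery checks only)", con)
  utils::write.table(sim$truth, con, sep = sep, row.names = FALSE, quote = FALSE)
  close(con)
  invisible(c(outcomes = out_path, truth = truth_path))
}
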