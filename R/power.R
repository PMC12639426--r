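# Simulation-based power and type-I-error estimation for the
# series-of-N-of-1 design: simulate a full trial, fit the population
# hierarchical model, and declare success when the posterior probability
# that the focal food contrast exceeds the MCID clears the decision
# threshold.

#' Power-study scenario
#'
#' The study conditions: 3 cycles x 5 foods per participant, one focal food
#' pair whose population mean PBGP differs by `focal_difference`
#' (2.4 mmol/L, white rice vs pasta), a between-individual SD of the
#' pairwise food difference of 2.5 mmol/L, a within-individual (replicate)
#' SD of 1.2 mmol/L, MCID 0.78 mmol/L and a posterior-probability decision
#' threshold of 0.80.
#'
#' `between_sd` is the SD of a participant-specific *difference* between two
#' foods; internally each per-food participant effect is drawn with SD
#' `between_sd / sqrt(2)`, so that every pairwise contrast has
#' between-individual SD `between_sd`.
#'
#' @param n_participants Trial size.
#' @param n_cycles Crossover periods per participant (default 3).
#' @param foods Food codes (default `LETTERS[1:5]`).
#' @param focal_pair Length-2 vector: the pair whose contrast drives the
#'   decision rule; the first food's population mean is the higher one.
#' @param focal_difference Population mean difference of the focal pair,
#'   mmol/L (study value 2.4; set 0 for the null scenario).
#' @param between_sd Between-individual SD of a pairwise food difference,
#'   mmol/L (study value 2.5).
#' @param within_sd Within-individual replicate SD, mmol/L (study value 1.2).
#' @param mcid MCID for the decision rule, mmol/L (study value 0.78).
#' @param decision_threshold Posterior-probability threshold (study 0.80).
#' @param n_replicates Simulated trials per estimate (default 500).
#' @param mcmc [mcmc_settings()] used inside each replicate (default
#'   [mcmc_settings_fast()]).
#' @param food_offsets Optional named vector of population mean offsets
#'   overriding the focal-pair default (non-focal foods at 0).
#' @param seed Master seed; replicate seeds are derived from it.
#' @return An object of class `power_scenario`.
#' @export
power_scenario <- function(n_participants, n_cycles = 3,
                           foods = LETTERS[1:5],
                           focal_pair = c("A", "E"), focal_difference = 2.4,
                           between_sd = 2.5, within_sd = 1.2, mcid = 0.78,
                           decision_threshold = 0.80, n_replicates = 500,
                           mcmc = mcmc_settings_fast(),
                           food_offsets = NULL, seed = 1) {
  foods <- as.character(foods)
  focal_pair <- as.character(focal_pair)
  stopifnot(length(focal_pair) == 2, all(focal_pair %in% foods),
            focal_pair[1] != focal_pair[2])
  if (between_sd < 0 || within_sd < 0) stop_domain("SDs must be >= 0")
  if (decision_threshold <= 0 || decision_threshold >= 1) {
    stop_domain("decision_threshold must lie strictly between 0 and 1")
  }
  if (is.null(food_offsets)) {
    food_offsets <- stats::setNames(numeric(length(foods)), foods)
    food_offsets[focal_pair[1]] <- focal_difference
  }
  structure(
    list(n_participants = n_participants, n_cycles = n_cycles, foods = foods,
         focal_pair = focal_pair, focal_difference = focal_difference,
         between_sd = between_sd, within_sd = within_sd,
         mcid = as_mcid_value(mcid), decision_threshold = decision_threshold,
         n_replicates = n_replicates, mcmc = mcmc,
         food_offsets = food_offsets, seed = seed),
    class = "power_scenario"
  )
}

#' @export
print.power_scenario <- function(x, ...) {
  cat(sprintf(paste0("Power scenario: n=%d, %d cycles x %d foods, focal %s-%s ",
                     "difference %.2f mmol/L\n  between-SD %.2f (difference scale), ",
                     "within-SD %.2f, MCID %.2f, threshold %.2f, %d replicates\n"),
              x$n_participants, x$n_cycles, length(x$foods), x$focal_pair[1],
              x$focal_pair[2], x$focal_difference, x$between_sd, x$within_sd,
              x$mcid, x$decision_threshold, x$n_replicates))
  invisible(x)
}

#' Run one power-simulation replicate
#'
#' Simulates one complete trial under the scenario (independent per-period
#' randomization, participant-level true effects, replicate noise), fits the
#' population hierarchical model with the scenario's MCMC settings, and
#' returns whether the decision rule fires: posterior
#' `P(focal contrast > MCID) > threshold`. A non-convergent fit (core R-hat
#' >= 1.05) is refit once with doubled burn-in; if still non-convergent the
#' replicate counts as a failure and is flagged.
#'
#' @param scenario A [power_scenario()].
#' @param replicate_seed Integer seed for this replicate.
#' @return Logical success flag, with attributes `prob` (the posterior
#'   probability) and `converged`.
#' @export
run_replicate <- function(scenario, replicate_seed) {
  stopifnot(inherits(scenario, "power_scenario"))
  seeds <- with_seed(replicate_seed,
                     sample.int(.Machine$integer.max - 1L, 3))
  design <- randomize_plan(sprintf("P%02d", seq_len(scenario$n_participants)),
                           n_periods = scenario$n_cycles,
                           food_codes = scenario$foods, seed = seeds[1])
  params <- truth_params(food_codes = scenario$foods,
                         food_offsets = scenario$food_offsets,
                         between_sd = scenario$between_sd / sqrt(2),
                         within_sd = scenario$within_sd, seed = seeds[2])
  sim <- simulate_outcomes(design, params)
  mcmc <- scenario$mcmc
  mcmc$seed <- seeds[3]
  fit <- suppressWarnings(
    fit_population(sim$outcomes, outcome = "pbgp", settings = mcmc,
                   keep_participant_effects = FALSE)
  )
  if (!fit$converged) {
    # one retry: double both warm-up and retained draws, which also steadies
    # R-hat for boundary-hugging variance parameters
    mcmc$burn_in <- 2L * mcmc$burn_in
    mcmc$samples_per_chain <- 2L * mcmc$samples_per_chain
    fit <- suppressWarnings(
      fit_population(sim$outcomes, outcome = "pbgp", settings = mcmc,
                     keep_participant_effects = FALSE)
    )
    if (!fit$converged) {
      return(structure(FALSE, prob = NA_real_, converged = FALSE))
    }
  }
  delta <- contrast_draws(fit, scenario$focal_pair[1], scenario$focal_pair[2])
  prob <- posterior_prob_exceeds(delta, scenario$mcid)
  structure(prob > scenario$decision_threshold, prob = prob, converged = TRUE)
}

run_power_loop <- function(scenario, type, warn_only) {
  if (scenario$n_replicates < 50) {
    msg <- sprintf("n_replicates = %d is too small for a reportable estimate (need >= 50)",
                   scenario$n_replicates)
    if (!warn_only) stop_domain("%s", msg)
    warning(msg, call. = FALSE)
  }
  seeds <- derive_seeds(scenario$seed, scenario$n_replicates)
  flags <- logical(scenario$n_replicates)
  nonconv <- 0L
  for (i in seq_len(scenario$n_replicates)) {
    f <- run_replicate(scenario, seeds[i])
    flags[i] <- as.logical(f)
    if (!attr(f, "converged")) nonconv <- nonconv + 1L
  }
  k <- sum(flags)
  p <- k / scenario$n_replicates
  structure(
    list(scenario = scenario, type = type, successes = k,
         estimate = p,
         se = sqrt(p * (1 - p) / scenario$n_replicates),
         n_replicates = scenario$n_replicates,
         n_nonconverged = nonconv, replicate_seeds = seeds,
         flags = flags),
    class = "power_result"
  )
}

#' Estimate statistical power by trial simulation
#'
#' Proportion of simulated trials in which the MCID decision rule fires
#' under the scenario's (non-null) focal difference, with its binomial
#' standard error. Every replicate seed is derived from the scenario seed
#' and logged in the result.
#'
#' @param scenario A [power_scenario()] with `focal_difference > 0`.
#' @param warn_only Report even with fewer than 50 replicates (with a
#'   warning) instead of refusing.
#' @return An object of class `power_result` with `estimate`, `se`,
#'   `successes`, `replicate_seeds`.
#' @export
estimate_power <- function(scenario, warn_only = FALSE) {
  stopifnot(inherits(scenario, "power_scenario"))
  if (scenario$focal_difference <= 0) {
    stop_domain("estimate_power needs focal_difference > 0; use estimate_type1 for the null")
  }
  run_power_loop(scenario, "power", warn_only)
}

#' Estimate the type I error rate under the null
#'
#' Re-runs the scenario with the focal difference forced to zero (all food
#' offsets equal), so the success proportion estimates the false-positive
#' rate of the decision rule.
#'
#' @inheritParams estimate_power
#' @return A `power_result` with `type = "type1"`.
#' @export
estimate_type1 <- function(scenario, warn_only = FALSE) {
  stopifnot(inherits(scenario, "power_scenario"))
  null_sc <- scenario
  null_sc$focal_difference <- 0
  null_sc$food_offsets <- stats::setNames(numeric(length(scenario$foods)),
                                          scenario$foods)
  run_power_loop(null_sc, "type1", warn_only)
}

#' @export
print.power_result <- function(x, ...) {
  lab <- if (x$type == "power") "Power" else "Type I error"
  cat(sprintf("%s at n=%d: %.1f%% (binomial SE %.1f points; %d/%d replicates%s)\n",
              lab, x$scenario$n_participants, 100 * x$estimate, 100 * x$se,
              x$successes, x$n_replicates,
              if (x$n_nonconverged > 0)
                sprintf("; %d non-convergent counted as failures", x$n_nonconverged)
              else ""))
  invisible(x)
}

#' Power across a grid of sample sizes
#'
#' Runs [estimate_power()] at each sample size, re-using the same replicate
#' seed stream per stratum (paired seeds, so power comparisons across n are
#' positively correlated), and reports the smallest n achieving the target
#' power.
#'
#' @param scenario Base [power_scenario()]; its `n_participants` is replaced
#'   by each grid value.
#' @param n_grid Increasing vector of sample sizes.
#' @param target Target power (default 0.80).
#' @param warn_only Passed to [estimate_power()].
#' @return A data frame `n, successes, power, se`, with attribute
#'   `n_at_target` (smallest n with power >= target, or `NA`).
#' @export
sample_size_curve <- function(scenario, n_grid, target = 0.80,
                              warn_only = FALSE) {
  stopifnot(inherits(scenario, "power_scenario"))
  if (length(n_grid) == 0 || is.unsorted(n_grid, strictly = TRUE)) {
    stop_domain("n_grid must be a nonempty strictly increasing vector")
  }
  rows <- lapply(n_grid, function(n) {
    sc <- scenario
    sc$n_participants <- n
    r <- estimate_power(sc, warn_only = warn_only)
    data.frame(n = n, successes = r$successes, power = r$estimate, se = r$se)
  })
  out <- do.call(rbind, rows)
  hit <- out$n[out$power >= target]
  attr(out, "n_at_target") <- if (length(hit)) min(hit) else NA_integer_
  out
}

#' Write a power result to JSON and delimited text
#'
#' JSON carries the scenario, estimate, binomial SE and every replicate
#' seed; the delimited table has one row per replicate (seed, success flag).
#' @param result A `power_result`.
#' @param path Output JSON path; the per-replicate table goes to
#'   `paste0(path, ".replicates.csv")`.
#' @return Invisibly, the paths written.
#' @export
write_power_result <- function(result, path) {
  stopifnot(inherits(result, "power_result"))
  sc <- result$scenario
  jsonlite::write_json(
    list(type = result$type,
         scenario = list(n_participants = sc$n_participants,
                         n_cycles = sc$n_cycles, foods = sc$foods,
                         focal_pair = sc$focal_pair,
                         focal_difference = sc$focal_difference,
                         between_sd = sc$between_sd, within_sd = sc$within_sd,
                         mcid = sc$mcid,
                         decision_threshold = sc$decision_threshold,
                         seed = sc$seed),
         successes = result$successes, n_replicates = result$n_replicates,
         estimate = result$estimate, binomial_se = result$se,
         n_nonconverged = result$n_nonconverged,
         replicate_seeds = result$replicate_seeds),
    path, auto_unbox = TRUE, digits = NA
  )
  rp <- paste0(path, ".replicates.csv")
  utils::write.table(
    data.frame(replicate = seq_along(result$flags),
               seed = result$replicate_seeds, success = result$flags),
    rp, sep = ",", row.names = FALSE, quote = FALSE
  )
  invisible(c(json = path, replicates = rp))
}
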