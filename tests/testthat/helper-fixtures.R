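# Fixture builders shared by the tests. All data are generated in code.

study_comps <- function() {
  read_composition(system.file("extdata", "food_composition.csv",
                               package = "nof1ppgr"))
}

# A complete synthetic outcome table: n participants x 3 periods x 5 foods.
make_outcomes <- function(n = 5, seed = 1, offsets = NULL,
                          between_sd = 1.77, within_sd = 1.2,
                          foods = LETTERS[1:5]) {
  plan <- randomize_plan(sprintf("P%02d", seq_len(n)), n_periods = 3,
                         food_codes = foods, seed = seed)
  params <- truth_params(food_codes = foods, food_offsets = offsets,
                         between_sd = between_sd, within_sd = within_sd,
                         seed = seed + 1)
  simulate_outcomes(plan, params)
}

# A regular CGM trace on the 5-min grid from -30 to +180 min around t0.
make_trace <- function(values, t0 = as.POSIXct("2025-01-01 08:00:00", tz = "UTC"),
                       start_min = -30, id = "P01", interval = 5) {
  times <- t0 + (start_min + interval * (seq_along(values) - 1)) * 60
  cgm_trace(id, times, values, nominal_interval = interval)
}

# Minimal fitted-model stand-in for scoring tests: named list of per-food
# effect draws (reference food omitted; its effect is identically zero).
fake_fit <- function(effect_draws, reference, records = NULL,
                     population = FALSE) {
  foods <- sort(c(reference, names(effect_draws)))
  nd <- length(effect_draws[[1]])
  tag <- if (population) "mu" else "beta"
  pars <- sprintf("%s[%s]", tag, names(effect_draws))
  draws <- array(NA_real_, dim = c(nd, 1, length(pars)),
                 dimnames = list(NULL, NULL, pars))
  for (i in seq_along(pars)) draws[, 1, i] <- effect_draws[[i]]
  structure(
    list(draws = draws, foods = foods, reference = reference,
         records = records, outcome = "pbgp",
         participant_id = if (!population) "P01" else NULL),
    class = c(if (population) "n1fit_population" else "n1fit_individual",
              "n1fit")
  )
}
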