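# Model fitting: the individual-level Bayesian linear model
#   outcome = beta0 + sum_j beta_j * food_j + eps,   eps ~ N(0, sigma^2)
# (reference-cell coding: the reference food's effect is fixed at 0 for
# identifiability), and the population-level hierarchical model that pools
# the per-participant food contrasts through normal random effects.

check_outcome <- function(records, outcome) {
  outcome <- match.arg(outcome, c("pbgp", "iauc3h"))
  if (!outcome %in% names(records)) {
    stop_domain("records lack an '%s' column", outcome)
  }
  y <- records[[outcome]]
  if (any(is.na(y))) stop_domain("missing %s values in records", outcome)
  outcome
}

resolve_foods <- function(records, food_codes, reference) {
  observed <- sort(unique(as.character(records$food_code)))
  foods <- if (is.null(food_codes)) observed else sort(as.character(food_codes))
  absent <- setdiff(foods, observed)
  if (length(absent)) {
    stop_domain("no observations for food(s): %s", paste(absent, collapse = ", "))
  }
  if (is.null(reference)) reference <- foods[1]
  if (!reference %in% foods) {
    stop_domain("reference food '%s' is not among the foods (%s)", reference,
                paste(foods, collapse = ", "))
  }
  list(foods = foods, reference = reference,
       nonref = setdiff(foods, reference))
}

#' Fit the individual-level Bayesian model
#'
#' Blocked Gibbs sampling of the normal linear model for a single
#' participant's outcomes, with food entered through reference-cell coding
#' (the reference food's effect is fixed at 0) and noninformative priors
#' ([prior_control()]). Convergence is checked with the split-chain
#' Gelman-Rubin statistic; any parameter with R-hat >= 1.05 flags the fit.
#'
#' @param records Outcome table for one participant (columns `participant_id,
#'   food_code` and the outcome).
#' @param outcome `"pbgp"` (mmol/L) or `"iauc3h"` (mmol/L.min).
#' @param reference Reference food code (default: alphabetically first).
#' @param food_codes Expected foods; foods listed here but absent from the
#'   data are an error. Default: the foods observed.
#' @param priors A [prior_control()].
#' @param settings An [mcmc_settings()].
#' @param min_replicates Minimum observations required per food (default 2).
#' @return An object of class `c("n1fit_individual", "n1fit")` with elements
#'   `draws` (samples x chains x parameters array), `summary`, `converged`,
#'   `reference`, `foods`, `records`, `outcome`, `settings`, `chain_seeds`.
#' @seealso [fit_population()], [pairwise_mcid_probs()], [wgrs_table()]
#' @export
fit_individual <- function(records, outcome = c("pbgp", "iauc3h"),
                           reference = NULL, food_codes = NULL,
                           priors = prior_control(),
                           settings = mcmc_settings(),
                           min_replicates = 2) {
  outcome <- check_outcome(records, outcome)
  ids <- unique(as.character(records$participant_id))
  if (length(ids) != 1) {
    stop_domain("fit_individual expects records from a single participant (got %d)",
                length(ids))
  }
  ff <- resolve_foods(records, food_codes, reference)
  counts <- table(factor(records$food_code, levels = ff$foods))
  if (any(counts < min_replicates)) {
    stop_domain("fewer than %d observations for food(s): %s", min_replicates,
                paste(names(counts)[counts < min_replicates], collapse = ", "))
  }
  f <- factor(records$food_code, levels = c(ff$reference, ff$nonref))
  X <- stats::model.matrix(~f)
  colnames(X) <- c("beta0", paste0("beta[", ff$nonref, "]"))
  draws <- gibbs_linear(X, records[[outcome]], priors, settings)
  smry <- summarize_draws(draws)
  converged <- all(smry$rhat < 1.05, na.rm = TRUE)
  if (!converged) {
    warning(sprintf("participant %s: MCMC not converged (max R-hat %.3f); fit flagged",
                    ids, max(smry$rhat, na.rm = TRUE)), call. = FALSE)
  }
  structure(
    list(draws = draws, summary = smry, converged = converged,
         participant_id = ids, reference = ff$reference, foods = ff$foods,
         outcome = outcome, records = records, priors = priors,
         settings = settings, chain_seeds = attr(draws, "chain_seeds")),
    class = c("n1fit_individual", "n1fit")
  )
}

#' Fit the population-level hierarchical Bayesian model
#'
#' Aggregates a series of N-of-1 trials: for each non-reference food `j`, the
#' participant-specific contrast `beta[j,i]` (food j minus the reference,
#' within participant i) is modeled as `Normal(mu_j, tau_j^2)`, with
#' participant-specific intercepts, a common residual SD, and noninformative
#' priors (Uniform(0, `tau_upper`) on each `tau_j`). Sampling is by blocked
#' Gibbs; both between-individual (`tau`) and within-individual (`sigma`)
#' variation enter the posterior for the population means `mu_j`.
#'
#' @inheritParams fit_individual
#' @param records Outcome table across participants.
#' @param keep_participant_effects Retain draws of the per-participant
#'   intercepts and contrasts (default `TRUE`; disable to save memory in
#'   simulation loops).
#' @return An object of class `c("n1fit_population", "n1fit")`; population
#'   parameters are named `mu[food]`, `tau[food]` and `sigma`.
#' @export
fit_population <- function(records, outcome = c("pbgp", "iauc3h"),
                           reference = NULL, food_codes = NULL,
                           priors = prior_control(),
                           settings = mcmc_settings(),
                           keep_participant_effects = TRUE) {
  outcome <- check_outcome(records, outcome)
  ids <- sort(unique(as.character(records$participant_id)))
  if (length(ids) < 2) {
    warning("fit_population with a single participant: the hierarchy is degenerate",
            call. = FALSE)
  }
  ff <- resolve_foods(records, food_codes, reference)
  tab <- table(factor(records$participant_id, levels = ids),
               factor(records$food_code, levels = ff$foods))
  if (any(tab == 0)) {
    bad <- which(tab == 0, arr.ind = TRUE)
    stop_domain("participants with no data for a food: %s",
                paste(sprintf("%s/%s", ids[bad[, 1]], ff$foods[bad[, 2]]),
                      collapse = ", "))
  }
  food_lv <- c(ff$reference, ff$nonref)
  participant <- match(as.character(records$participant_id), ids)
  food <- match(as.character(records$food_code), food_lv)
  draws <- gibbs_hierarchical(records[[outcome]], participant, food,
                              n = length(ids), K = length(food_lv),
                              priors = priors, settings = settings,
                              keep_participant_effects = keep_participant_effects)
  # relabel indices with food codes / participant ids
  pn <- dimnames(draws)[[3]]
  for (j in seq_along(ff$nonref)) {
    pn <- sub(sprintf("^mu\\[%d\\]$", j), sprintf("mu[%s]", ff$nonref[j]), pn)
    pn <- sub(sprintf("^tau\\[%d\\]$", j), sprintf("tau[%s]", ff$nonref[j]), pn)
    pn <- sub(sprintf("^beta\\[%d,", j), sprintf("beta[%s,", ff$nonref[j]), pn)
  }
  for (i in seq_along(ids)) {
    pn <- sub(sprintf("^alpha\\[%d\\]$", i), sprintf("alpha[%s]", ids[i]), pn)
    pn <- sub(sprintf(",%d\\]$", i), sprintf(",%s]", ids[i]), pn)
  }
  dimnames(draws)[[3]] <- pn
  smry <- summarize_draws(draws)
  core <- grepl("^(mu|tau)\\[|^sigma$", smry$parameter)
  converged <- all(smry$rhat[core] < 1.05, na.rm = TRUE)
  if (!converged) {
    warning(sprintf("population fit: MCMC not converged (max core R-hat %.3f); fit flagged",
                    max(smry$rhat[core], na.rm = TRUE)), call. = FALSE)
  }
  structure(
    list(draws = draws, summary = smry, converged = converged,
         participant_ids = ids, reference = ff$reference, foods = ff$foods,
         outcome = outcome, records = records, priors = priors,
         settings = settings, chain_seeds = attr(draws, "chain_seeds")),
    class = c("n1fit_population", "n1fit")
  )
}

# ---- accessors --------------------------------------------------------------

#' Flattened posterior draws of one parameter
#' @param fit An `n1fit` object.
#' @param parameter Parameter name as shown in `summary(fit)`.
#' @return Numeric vector of pooled (all chains) retained draws.
#' @export
posterior_draws <- function(fit, parameter) {
  stopifnot(inherits(fit, "n1fit"))
  pars <- dimnames(fit$draws)[[3]]
  if (!parameter %in% pars) {
    stop_domain("unknown parameter '%s' (have: %s ...)", parameter,
                paste(utils::head(pars, 6), collapse = ", "))
  }
  as.vector(fit$draws[, , parameter])
}

#' Posterior draws of a food's effect relative to the reference
#'
#' The reference food's effect is identically 0.
#' @param fit An `n1fit` object.
#' @param food Food code.
#' @return Numeric vector of draws (mmol/L or mmol/L.min).
#' @export
food_effect_draws <- function(fit, food) {
  stopifnot(inherits(fit, "n1fit"))
  if (!food %in% fit$foods) {
    stop_domain("food '%s' not in fit (foods: %s)", food,
                paste(fit$foods, collapse = ", "))
  }
  if (food == fit$reference) {
    return(rep(0, dim(fit$draws)[1] * dim(fit$draws)[2]))
  }
  par <- if (inherits(fit, "n1fit_population")) sprintf("mu[%s]", food)
         else sprintf("beta[%s]", food)
  posterior_draws(fit, par)
}

#' Posterior draws of a pairwise food contrast
#'
#' Draws of `effect(food_j) - effect(food_k)`; invariant (up to Monte-Carlo
#' error) to the choice of reference food.
#' @param fit An `n1fit` object.
#' @param food_j,food_k Food codes.
#' @return Numeric vector of contrast draws.
#' @export
contrast_draws <- function(fit, food_j, food_k) {
  food_effect_draws(fit, food_j) - food_effect_draws(fit, food_k)
}

# ---- methods ----------------------------------------------------------------

#' @export
print.n1fit <- function(x, ...) {
  kind <- if (inherits(x, "n1fit_population")) "Population hierarchical"
          else sprintf("Individual (%s)", x$participant_id)
  cat(sprintf("%s Bayesian model of %s\n", kind, toupper(x$outcome)))
  cat(sprintf("  foods: %s (reference %s)\n", paste(x$foods, collapse = ", "),
              x$reference))
  cat(sprintf("  %d chains x %d retained draws (%d burn-in); converged: %s\n",
              x$settings$n_chains, x$settings$samples_per_chain,
              x$settings$burn_in, x$converged))
  core <- x$summary[grepl("^(beta|mu|tau)\\[|^beta0$|^sigma$", x$summary$parameter) &
                      !grepl("^beta\\[.*,", x$summary$parameter), ]
  print(core, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Posterior summary of a fitted model
#'
#' One row per parameter: posterior mean, posterior SD (reported in trial
#' outputs as the "SE"), Monte-Carlo standard error of the mean, 2.5% and
#' 97.5% credible bounds, and the split-chain R-hat.
#' @param object An `n1fit` object.
#' @param ... Unused.
#' @return A data frame (class `summary.n1fit`).
#' @export
summary.n1fit <- function(object, ...) {
  out <- object$summary
  class(out) <- c("summary.n1fit", "data.frame")
  attr(out, "converged") <- object$converged
  out
}

#' @export
print.summary.n1fit <- function(x, ...) {
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
coef.n1fit <- function(object, ...) {
  core <- object$summary[grepl("^(beta|mu)\\[|^beta0$", object$summary$parameter) &
                           !grepl("^beta\\[.*,", object$summary$parameter), ]
  stats::setNames(core$mean, core$parameter)
}

#' Trace plots of posterior draws
#' @param x An `n1fit` object.
#' @param parameters Parameter names to plot (default: population/individual
#'   core parameters, up to 6).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.n1fit <- function(x, parameters = NULL, ...) {
  pars <- dimnames(x$draws)[[3]]
  if (is.null(parameters)) {
    parameters <- utils::head(pars[grepl("^(beta|mu)\\[|^beta0$|^sigma$", pars) &
                                     !grepl("^beta\\[.*,", pars)], 6)
  }
  old <- graphics::par(mfrow = c(length(parameters), 1),
                       mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(old))
  for (p in parameters) {
    graphics::matplot(x$draws[, , p], type = "l", lty = 1, ylab = p,
                      xlab = "", ...)
    graphics::mtext(sprintf("R-hat %.3f",
                            x$summary$rhat[x$summary$parameter == p]),
                    side = 3, cex = 0.7)
  }
  invisible(x)
}

#' @export
fitted.n1fit_individual <- function(object, ...) {
  eff <- coef(object)
  b0 <- eff["beta0"]
  vals <- vapply(as.character(object$records$food_code), function(fc) {
    if (fc == object$reference) b0
    else b0 + eff[sprintf("beta[%s]", fc)]
  }, 0)
  unname(vals)
}

#' @export
residuals.n1fit_individual <- function(object, ...) {
  object$records[[object$outcome]] - fitted(object)
}

#' Posterior-predictive simulation from an individual fit
#'
#' Draws new replicate outcomes for each record by sampling (coefficients,
#' sigma) from the posterior and adding normal observation noise.
#' @param object An `n1fit_individual`.
#' @param nsim Number of simulated datasets.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return A matrix `nrow(records) x nsim`.
#' @export
simulate.n1fit_individual <- function(object, nsim = 1, seed = NULL, ...) {
  n_draws <- dim(object$draws)[1] * dim(object$draws)[2]
  with_seed(seed, {
    pick <- sample.int(n_draws, nsim, replace = TRUE)
    sig <- posterior_draws(object, "sigma")[pick]
    b0 <- posterior_draws(object, "beta0")[pick]
    eff <- vapply(as.character(object$records$food_code), function(fc) {
      if (fc == object$reference) rep(0, nsim)
      else posterior_draws(object, sprintf("beta[%s]", fc))[pick]
    }, numeric(nsim))
    if (nsim == 1) eff <- matrix(eff, nrow = 1)
    m <- t(eff + b0)   # records x nsim
    m + matrix(stats::rnorm(length(m), 0, rep(sig, each = nrow(m))),
               nrow(m), nsim)
  })
}

#' Export posterior summaries (and optionally draws) to files
#'
#' JSON summaries (parameter, mean, sd, ci2.5, ci97.5, rhat, chain seeds)
#' plus an optional flat delimited draw file, one parameter per column.
#' @param fit An `n1fit` object.
#' @param path Output JSON path; draws go to `paste0(path, ".draws.csv")`.
#' @param draws Also write the flat draw file.
#' @return Invisibly, the paths written.
#' @export
write_posterior <- function(fit, path, draws = FALSE) {
  stopifnot(inherits(fit, "n1fit"))
  jsonlite::write_json(
    list(outcome = fit$outcome, reference = fit$reference,
         converged = fit$converged, chain_seeds = fit$chain_seeds,
         summary = fit$summary),
    path, auto_unbox = TRUE, digits = NA
  )
  paths <- c(summary = path)
  if (draws) {
    flat <- apply(fit$draws, 3, as.vector)
    dp <- paste0(path, ".draws.csv")
    utils::write.table(flat, dp, sep = ",", row.names = FALSE, quote = FALSE)
    paths <- c(paths, draws = dp)
  }
  invisible(paths)
}
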