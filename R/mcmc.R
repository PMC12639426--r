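# MCMC machinery: sampler settings, noninformative prior specifications,
# blocked Gibbs kernels for the conjugate normal linear / hierarchical
# structure, the split-chain Gelman-Rubin diagnostic, and posterior summaries.

#' MCMC sampler settings
#'
#' Defaults follow the trial analysis plan: 4 chains, 1000 burn-in iterations
#' per chain, 4000 retained sampling iterations per chain — 16,000 retained
#' draws in total.
#'
#' @param n_chains Number of chains (>= 2 for convergence diagnostics).
#' @param burn_in Discarded warm-up iterations per chain.
#' @param samples_per_chain Retained iterations per chain.
#' @param thinning Keep every `thinning`-th draw (default 1).
#' @param seed Master seed; per-chain seeds are derived from it and logged.
#' @return An object of class `mcmc_settings`.
#' @examples
#' s <- mcmc_settings()
#' s$n_chains * s$samples_per_chain  # 16000 retained draws
#' @export
mcmc_settings <- function(n_chains = 4, burn_in = 1000,
                          samples_per_chain = 4000, thinning = 1,
                          seed = NULL) {
  stopifnot(n_chains >= 1, burn_in >= 0, samples_per_chain >= 1, thinning >= 1)
  structure(list(n_chains = as.integer(n_chains),
                 burn_in = as.integer(burn_in),
                 samples_per_chain = as.integer(samples_per_chain),
                 thinning = as.integer(thinning), seed = seed),
            class = "mcmc_settings")
}

#' Fast sampler preset for simulation loops
#'
#' 2 chains x 1000 retained draws after 500 burn-in: adequate for the rapidly
#' mixing conjugate Gibbs kernels inside power-simulation replicates, where
#' thousands of fits are run.
#' @param seed Master seed.
#' @return An `mcmc_settings` object.
#' @export
mcmc_settings_fast <- function(seed = NULL) {
  mcmc_settings(n_chains = 2, burn_in = 500, samples_per_chain = 1000,
                seed = seed)
}

#' Noninformative prior specification
#'
#' Concrete "noninformative" priors: Normal(0, `beta_sd`^2) on the intercept
#' and food effects, inverse-gamma(`sigma_shape`, `sigma_rate`) on the
#' residual variance, and Uniform(0, `tau_upper`) on the between-participant
#' SDs of the hierarchical model.
#'
#' @param beta_mean,beta_sd Normal prior on regression coefficients (mmol/L);
#'   default mean 0, SD 100.
#' @param sigma_shape,sigma_rate Inverse-gamma prior on variances (default
#'   0.001, 0.001).
#' @param tau_upper Upper bound (mmol/L) of the uniform prior on
#'   between-participant SDs (default 10).
#' @return An object of class `prior_control`.
#' @export
prior_control <- function(beta_mean = 0, beta_sd = 100, sigma_shape = 0.001,
                          sigma_rate = 0.001, tau_upper = 10) {
  stopifnot(beta_sd > 0, sigma_shape > 0, sigma_rate > 0, tau_upper > 0)
  structure(list(beta_mean = beta_mean, beta_sd = beta_sd,
                 sigma_shape = sigma_shape, sigma_rate = sigma_rate,
                 tau_upper = tau_upper),
            class = "prior_control")
}

#' Split-chain Gelman-Rubin statistic
#'
#' Classic potential-scale-reduction factor, computed after splitting every
#' chain in half (so within-chain trends register as apparent
#' between-chain variance). Values below 1.05 are taken as converged.
#'
#' @param draws A samples x chains matrix (or a vector list of equal-length
#'   chains).
#' @return The R-hat statistic (scalar).
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(4000), ncol = 4)
#' rhat(x)
#' @export
rhat <- function(draws) {
  if (is.list(draws)) draws <- do.call(cbind, draws)
  draws <- as.matrix(draws)
  m <- ncol(draws)
  if (m < 2) stop_domain("rhat needs at least 2 chains (got %d)", m)
  if (nrow(draws) < 4) {
    stop_domain("rhat needs at least 4 samples per chain (2 per split half)")
  }
  n <- floor(nrow(draws) / 2)
  halves <- do.call(cbind, lapply(seq_len(m), function(j) {
    cbind(draws[seq_len(n), j], draws[nrow(draws) - n + seq_len(n), j])
  }))
  W <- mean(apply(halves, 2, stats::var))
  B <- n * stats::var(colMeans(halves))
  if (W < 1e-300) return(if (B < 1e-300) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Posterior probability that draws exceed a threshold
#'
#' Fraction of posterior draws strictly greater than `threshold`; the
#' building block of the MCID decision rules.
#'
#' @param draws Numeric vector (or matrix) of posterior draws.
#' @param threshold Exceedance threshold, in outcome units.
#' @return Probability in `[0, 1]`.
#' @examples
#' posterior_prob_exceeds(c(0.5, 0.9, 1.2), 0.78)
#' @export
posterior_prob_exceeds <- function(draws, threshold) {
  draws <- as.numeric(draws)
  if (length(draws) == 0 || all(is.na(draws))) {
    stop_domain("posterior_prob_exceeds: empty draws")
  }
  mean(draws > threshold)
}

# ---- internal Gibbs kernels -------------------------------------------------

# Draw from inverse-gamma(shape, rate) (i.e. 1/Gamma).
rinvgamma1 <- function(n, shape, rate) 1 / stats::rgamma(n, shape = shape, rate = rate)

# Draw tau (between-participant SD) from its full conditional under a
# Uniform(0, upper) prior: 1/tau^2 ~ Gamma((k-1)/2, S/2) truncated to
# tau <= upper. k = number of effects, S = sum of squared deviations.
# Falls back to a grid inverse-CDF draw when the Gamma shape is <= 0 (k < 2).
draw_tau <- function(k, S, upper) {
  S <- max(S, 1e-12)
  shape <- (k - 1) / 2
  if (shape > 0.05) {
    glo <- 1 / upper^2
    plo <- stats::pgamma(glo, shape = shape, rate = S / 2)
    if (plo >= 1 - 1e-12) return(upper * (1 - 1e-8))
    g <- stats::qgamma(stats::runif(1, plo, 1), shape = shape, rate = S / 2)
    return(1 / sqrt(g))
  }
  # grid sampler on tau in (0, upper): density prop to tau^-k exp(-S/(2 tau^2))
  tg <- seq(upper / 512, upper, length.out = 512)
  lp <- -k * log(tg) - S / (2 * tg^2)
  p <- exp(lp - max(lp))
  tg[sample.int(512, 1, prob = p)]
}

# Blocked Gibbs for the individual-level linear model
#   y = X b + e,  e ~ N(0, sigma^2),  b ~ N(b0, B0), sigma^2 ~ IG(a, r).
# Returns draws array [samples, chains, p + 1] (coefficients then sigma).
gibbs_linear <- function(X, y, priors, settings) {
  p <- ncol(X)
  n <- length(y)
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  prior_prec <- diag(1 / priors$beta_sd^2, p)
  prior_pm <- rep(priors$beta_mean, p) / priors$beta_sd^2
  seeds <- derive_seeds(settings$seed, settings$n_chains)
  n_iter <- settings$burn_in + settings$samples_per_chain * settings$thinning
  ols <- tryCatch(qr.solve(XtX + diag(1e-8, p), Xty), error = function(e) rep(0, p))
  draws <- array(NA_real_,
                 dim = c(settings$samples_per_chain, settings$n_chains, p + 1),
                 dimnames = list(NULL, NULL, c(colnames(X), "sigma")))
  for (ch in seq_len(settings$n_chains)) {
    with_seed(seeds[ch], {
      b <- ols + stats::rnorm(p, 0, 0.5 + 0.5 * ch)  # overdispersed inits
      sig2 <- stats::var(y) + 0.1 * ch
      kept <- 0L
      for (it in seq_len(n_iter)) {
        A <- XtX / sig2 + prior_prec
        U <- chol(A)
        mean_b <- backsolve(U, forwardsolve(t(U), Xty / sig2 + prior_pm))
        b <- mean_b + backsolve(U, stats::rnorm(p))
        r <- y - X %*% b
        sig2 <- rinvgamma1(1, priors$sigma_shape + n / 2,
                           priors$sigma_rate + sum(r^2) / 2)
        if (it > settings$burn_in &&
            (it - settings$burn_in) %% settings$thinning == 0) {
          kept <- kept + 1L
          draws[kept, ch, ] <- c(b, sqrt(sig2))
        }
      }
    })
  }
  attr(draws, "chain_seeds") <- seeds
  draws
}

# Blocked Gibbs for the population hierarchical model with reference-cell
# coding:
#   y_obs = alpha_i + beta[j, i] + e,   e ~ N(0, sigma^2)
#   beta[j, i] ~ N(mu_j, tau_j^2)  (j over non-reference foods)
#   alpha_i ~ N(b0, beta_sd^2), mu_j ~ N(b0, beta_sd^2),
#   tau_j ~ U(0, tau_upper), sigma^2 ~ IG.
# participant: integer index 1..n; food: integer index 1..K with 1 = reference.
gibbs_hierarchical <- function(y, participant, food, n, K, priors, settings,
                               keep_participant_effects = TRUE) {
  J <- K - 1                      # non-reference foods
  N <- length(y)
  # per (participant, food) counts and outcome sums
  cell <- (food - 1) * n + participant
  n_if <- matrix(0, n, K)
  sum_if <- matrix(0, n, K)
  tab <- tabulate(cell, n * K)
  n_if[] <- tab
  s <- rowsum(y, cell)
  sum_if[as.integer(rownames(s))] <- s
  n_i <- rowSums(n_if)
  sum_i <- rowSums(sum_if)
  nonref <- 2:K
  prior_prec <- 1 / priors$beta_sd^2
  prior_pm <- priors$beta_mean / priors$beta_sd^2

  seeds <- derive_seeds(settings$seed, settings$n_chains)
  n_iter <- settings$burn_in + settings$samples_per_chain * settings$thinning
  par_names <- c(paste0("mu[", seq_len(J), "]"),
                 paste0("tau[", seq_len(J), "]"), "sigma")
  if (keep_participant_effects) {
    par_names <- c(par_names, paste0("alpha[", seq_len(n), "]"),
                   as.vector(outer(seq_len(J), seq_len(n),
                                   function(j, i) paste0("beta[", j, ",", i, "]"))))
  }
  draws <- array(NA_real_,
                 dim = c(settings$samples_per_chain, settings$n_chains,
                         length(par_names)),
                 dimnames = list(NULL, NULL, par_names))

  # moment-based starting points
  cellmean <- ifelse(n_if > 0, sum_if / pmax(n_if, 1), NA)
  alpha0 <- ifelse(is.na(cellmean[, 1]), sum_i / n_i, cellmean[, 1])
  beta0 <- cellmean[, nonref, drop = FALSE] - alpha0
  beta0[is.na(beta0)] <- 0

  for (ch in seq_len(settings$n_chains)) {
    with_seed(seeds[ch], {
      alpha <- alpha0 + stats::rnorm(n, 0, 0.5 * ch)
      beta <- beta0 + matrix(stats::rnorm(n * J, 0, 0.5 * ch), n, J)
      mu <- colMeans(beta)
      tau <- pmax(apply(beta, 2, stats::sd), 0.5)
      tau[!is.finite(tau)] <- 1
      sig2 <- stats::var(y)
      kept <- 0L
      Bfull <- matrix(0, n, K)
      for (it in seq_len(n_iter)) {
        Bfull[, nonref] <- beta
        # alpha_i | .
        resid_sum <- sum_i - rowSums(n_if * Bfull)
        prec <- n_i / sig2 + prior_prec
        alpha <- stats::rnorm(n, (resid_sum / sig2 + prior_pm) / prec,
                              1 / sqrt(prec))
        # mu_j | alpha, tau, sigma — collapsed over beta[j, ] (integrating
        # the participant contrasts out keeps the chain mixing when tau -> 0)
        for (j in seq_len(J)) {
          kcol <- nonref[j]
          denom <- sig2 / n_if[, kcol] + tau[j]^2
          prec <- sum(1 / denom) + prior_prec
          mu[j] <- stats::rnorm(
            1, (sum((sum_if[, kcol] / n_if[, kcol] - alpha) / denom) + prior_pm) / prec,
            1 / sqrt(prec))
        }
        # beta[j, i] | mu, .
        for (j in seq_len(J)) {
          kcol <- nonref[j]
          Sij <- sum_if[, kcol] - n_if[, kcol] * alpha
          prec <- n_if[, kcol] / sig2 + 1 / tau[j]^2
          beta[, j] <- stats::rnorm(n, (Sij / sig2 + mu[j] / tau[j]^2) / prec,
                                    1 / sqrt(prec))
        }
        # tau_j | .
        for (j in seq_len(J)) {
          tau[j] <- draw_tau(n, sum((beta[, j] - mu[j])^2), priors$tau_upper)
        }
        # sigma^2 | .
        Bfull[, nonref] <- beta
        r <- y - alpha[participant] - Bfull[cbind(participant, food)]
        sig2 <- rinvgamma1(1, priors$sigma_shape + N / 2,
                           priors$sigma_rate + sum(r^2) / 2)
        if (it > settings$burn_in &&
            (it - settings$burn_in) %% settings$thinning == 0) {
          kept <- kept + 1L
          if (keep_participant_effects) {
            draws[kept, ch, ] <- c(mu, tau, sqrt(sig2), alpha, as.vector(t(beta)))
          } else {
            draws[kept, ch, ] <- c(mu, tau, sqrt(sig2))
          }
        }
      }
    })
  }
  attr(draws, "chain_seeds") <- seeds
  draws
}

# Posterior summary table from a draws array [samples, chains, params].
summarize_draws <- function(draws) {
  pars <- dimnames(draws)[[3]]
  out <- do.call(rbind, lapply(seq_along(pars), function(k) {
    m <- draws[, , k, drop = FALSE]
    dim(m) <- dim(draws)[1:2]
    v <- as.vector(m)
    data.frame(parameter = pars[k], mean = mean(v), sd = stats::sd(v),
               mcse = mcse_batch(v),
               ci2.5 = unname(stats::quantile(v, 0.025)),
               ci97.5 = unname(stats::quantile(v, 0.975)),
               rhat = if (ncol(m) >= 2) rhat(m) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# Monte-Carlo standard error of the mean by non-overlapping batch means.
mcse_batch <- function(x, n_batches = 30) {
  n <- length(x)
  b <- max(2, floor(n / n_batches))
  nb <- floor(n / b)
  bm <- colMeans(matrix(x[seq_len(nb * b)], nrow = b))
  stats::sd(bm) / sqrt(nb)
}
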