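---
title: "Statistical methods of nof1ppgr: Bayesian analysis of a series of N-of-1 glycemic-response trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods of nof1ppgr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(nof1ppgr)
```

# The problem

Postprandial glycemic responses to carbohydrate staples differ markedly
between individuals — two people with type 2 diabetes can rank the same five
staple foods in opposite orders. A randomized multi-crossover (N-of-1) trial
addresses this directly: each participant eats every test food several times
in randomized order under continuous glucose monitoring (CGM), so that
food effects are estimated *within* each person, and a series of such trials
can then be pooled for population inference. `nof1ppgr` implements the full
statistical machinery for such a trial: portion-standardized menu design,
per-period randomization, CGM endpoint extraction, Bayesian individual and
population models, an MCID-based decision rule, the CV-weighted glycemic
response score (WGRS), and a simulation-based power study.

The trial design mirrored throughout the package is 5 staple foods
(letter-coded A–E) x 3 crossover periods per participant, one meal per food
per period, glucose sampled every 5 minutes.

# Design: portions and randomization

Each test meal must deliver the same available-carbohydrate load (50 g by
default), so the served staple weight is
`100 * target / available_carbohydrate` g, with the per-100 g composition
measured on the cooked, ready-to-eat food. Weights are rounded
half-away-from-zero to the nearest gram; this rounding reproduces all five
study menu weights from the packaged composition fixture, including the
two values that sit within 0.2 g of a rounding boundary:

```{r}
comps <- read_composition(system.file("extdata", "food_composition.csv",
                                      package = "nof1ppgr"))
build_menu(comps, 50)[, 1:2]
```

Randomization is an independent uniform permutation of the five foods for
every participant-period, generated from a recorded seed
(`randomize_plan()`), so the allocation is reproducible and per-participant
sequences can be exported separately for concealment. Analyses operate on
the letter codes only; the composition table is the unblinding key.

# CGM endpoints

Two endpoints are extracted per meal event from the 5-minute CGM grid:

* **PBGP** — the postprandial blood glucose peak, the maximum glucose in the
  3 h following the first bite. The first bite is snapped to the nearest
  grid sample (the snap offset is kept as a QC flag), so the 3-h clock and
  the grid coincide.
* **iAUC** — the 3-h incremental area under the curve above the fasting
  baseline, by the trapezoid rule on the grid, in mmol/L·min.

Numerical conventions, chosen where the protocol language is ambiguous:

* the **baseline** is the single sample nearest to 30 min before the first
  bite (within ±2.5 min), not an average — the protocol specifies a
  measurement, not a window;
* **negative increments contribute zero** (the classic incremental-AUC
  convention); `net_auc = TRUE` switches to the signed alternative;
* **gaps** of at most 2 consecutive missing grid points (10 min) are filled
  by linear interpolation and flagged; longer gaps, or a window covering
  less than 75% of its expected samples, fail QC rather than risk hiding a
  peak of the magnitudes at stake (several mmol/L over 30–60 min).

# The individual-level model

For one participant, outcomes are modeled as a normal linear model with
reference-cell coding:

$$y_m = \beta_0 + \sum_{j \ne \mathrm{ref}} \beta_j \,[\mathrm{food}_m = j] + \varepsilon_m,
\qquad \varepsilon_m \sim N(0, \sigma^2).$$

The reference food's effect is fixed at zero for identifiability (an
intercept plus five indicators would be overparameterized); pairwise
contrasts $\beta_j - \beta_k$ are invariant to the choice of reference, which
the test suite checks. "Noninformative" priors are made concrete as
$N(0, 100^2)$ on $\beta_0$ and each $\beta_j$ (mmol/L scale) and
inverse-gamma(0.001, 0.001) on $\sigma^2$; all are exposed through
`prior_control()`.

Sampling is by **blocked Gibbs**: the coefficient vector is conjugate
multivariate normal given $\sigma^2$, and $\sigma^2$ is conjugate
inverse-gamma given the coefficients. No general-purpose HMC machinery is
needed for this conjugate structure, and the sampler mixes essentially like
independent draws. The default configuration is 4 chains x 1000 burn-in +
4000 retained iterations (16,000 retained draws); convergence is assessed
with the split-chain Gelman–Rubin statistic, flagging any parameter with
R-hat ≥ 1.05. The posterior SD is what trial reports label the "SE"; the
Monte-Carlo standard error of each posterior mean is reported separately
(batch means), since the two are easily conflated.

The engine's core correctness test is an analytic one: on a fixed dataset
the Gibbs posterior means and SDs must agree with the exact semi-conjugate
posterior obtained by numerical quadrature over $\sigma^2$ — an independent
oracle that shares no code with the sampler.

# The population-level model

A series of N-of-1 trials is pooled contrast-by-contrast with a hierarchical
(random-effects) model:

$$y_{im} = \alpha_i + \beta_{j[m],i} + \varepsilon_{im}, \qquad
\beta_{j,i} \sim N(\mu_j, \tau_j^2),$$

with participant intercepts $\alpha_i$ given flat normal priors, a common
residual SD $\sigma$, and $\tau_j \sim \mathrm{Uniform}(0, 10)$ mmol/L. The
population parameter $\mu_j$ is the mean contrast of food $j$ against the
reference, so both between-individual ($\tau$) and within-individual
($\sigma$) variation propagate into its posterior. Contrast-level pooling
(rather than pooling absolute per-food means) matches the trial's
hypotheses, which are phrased about differences between foods.

Two numerical choices matter here:

* $\mu_j$ is updated **collapsed** — with the participant contrasts
  $\beta_{j,\cdot}$ integrated out analytically — and the contrasts are then
  redrawn given $\mu_j$. The naive alternating update degenerates into a
  tiny-step random walk as $\tau_j \to 0$ (the contrasts and their mean move
  in lockstep); the collapsed update keeps mixing fast across the whole
  $\tau$ range, including the single-participant limit.
* $\tau_j$ is drawn exactly from its full conditional under the uniform
  prior: $1/\tau_j^2$ is a truncated Gamma, sampled by inverse-CDF; a grid
  sampler handles the one-participant edge case where the Gamma shape
  degenerates.

# Decision rules and the WGRS

The minimum clinically important difference is a fraction of a reference
between-group difference, computed in decimal arithmetic with half-to-even
rounding at two decimals (`mcid_from_reference()`): 20% of 3.89 mmol/L gives
the PBGP MCID of 0.78 mmol/L, and 10% of 1067.85 mmol/L·min gives the iAUC
MCID of 106.78 mmol/L·min. Binary-float rounding of 106.785 would give
106.79; the decimal route is deliberate.

For each ordered food pair the posterior probability
$P_{jk} = P(\beta_j - \beta_k > \mathrm{MCID})$ is a draw fraction
(`pairwise_mcid_probs()`); at the population level the same rule applied to
$\mu$ contrasts with an 80% threshold yields the trial's decision rule
(`population_mcid_decision()`).

The WGRS for participant $i$ and food $j$ aggregates that food's pairwise
evidence, weighting each comparator $k$ by the reciprocal of its replicate
coefficient of variation:

$$\mathrm{WGRS}_{i,j} =
\frac{\sum_{k \ne j} P(\Delta_{j,k} > \mathrm{MCID}) / CV_k}
     {\sum_{k \ne j} 1 / CV_k} \in [0, 1],$$

so foods compared against *stable* comparators (low CV) carry more weight,
and a higher score marks a food as glycemically worse. $CV_k$ is taken from
the observed replicates (SD/mean of the 3 peaks; the most natural reading of
a CV "of each staple food") with a posterior-based alternative behind
`cv_source = "posterior"`; CVs are floored at 0.01 so zero-variance
replicates cannot produce infinite weights. The score is a weighted mean of
probabilities, hence always in $[0,1]$, and equals $p$ exactly when all
pairwise probabilities equal $p$ — both properties are asserted over random
inputs in the tests. The same code path accepts the iAUC MCID, as a
structural extension beyond the PBGP-defined score.

# The synthetic-data generator

No trial data exist at the protocol stage, so a first-class generator
provides the study's stated statistical structure. Participant $i$'s true
peak for food $j$ is drawn once as
$N(\mathrm{grand\ mean} + \mathrm{offset}_j,\ \sigma_b^2)$, and each of the
3 replicate observations as $N(\mathrm{truth},\ \sigma_w^2)$ — i.e. a
per-participant true effect held fixed across cycles, the standard reading
of a subject's "true intervention effect". The generator returns the truth
table alongside the observables (and writes it with a "DO NOT USE IN
ANALYSIS" header) so parameter-recovery tests can score themselves.

Defaults encode the study conditions: grand mean 10 mmol/L, baseline
7.5 ± 1.0 mmol/L, within-individual SD 1.2 mmol/L, and one focal food pair
(A vs E, the white-rice/pasta analogy) separated by 2.4 mmol/L with all
non-focal offsets at 0 — the minimal assumption, since nothing is stated
about the other foods; every offset is overridable.

**The between-individual SD is parameterized on the difference scale.** The
study quotes a between-individual SD of 2.5 mmol/L *for the difference in
PBGP between two foods*. `power_scenario(between_sd = 2.5)` therefore draws
per-food participant effects with SD $2.5/\sqrt{2}$, making every pairwise
contrast have between-individual SD 2.5. Reading the 2.5 instead as a
per-food SD would inflate the contrast SD to 3.5 and change the operating
characteristics of the whole design; the difference-scale reading is also
the one consistent with the study's reported power.

For end-to-end tests of the CGM extractor, `simulate_trace()` synthesizes a
meal excursion on the grid: linear rise to the target peak at 45 min
(a grid point, so peak recovery is exact), then an exponential decay of
fixed shape with 2% of the excursion left at 180 min — fixed so that the
trace, and hence the iAUC, scales linearly in the excursion height. The
generator makes no attempt at physiological realism (no insulin dynamics,
no diurnal noise spectra, no sensor drift or lag): passing tests demonstrate
that the pipeline's statistics behave as designed under the stated variance
structure, not that real CGM data will be this clean.

# The power study

`estimate_power()` simulates complete trials — independent randomization,
truth draws, replicate noise — fits the hierarchical model to each, and
declares success when the posterior probability that the focal contrast
exceeds the MCID clears the 0.80 threshold (the one-sided focal rule the
design specifies; an all-pairs variant would need a multiplicity stance the
protocol does not take). `estimate_type1()` repeats this with all offsets
equal. Results carry binomial standard errors and every replicate seed.

Inside replicates the sampler runs a reduced configuration (2 chains x
1000 retained after 500 burn-in, `mcmc_settings_fast()`): the conjugate
Gibbs kernels mix fast enough that this agrees with the full 4 x 4000
configuration within binomial error, which the test suite checks directly.
A replicate whose fit has not converged is refit once with doubled burn-in
and retained draws, then counted as a failure if still flagged. The default
replicate count is 500 (binomial SE about 1.6 points near 86% power); the
test suite and the acceptance script use 200–300 so the full simulation
study completes in minutes on one CPU.

Problem sizes used by the shipped checks: moment-recovery at 200 and 500
simulated participants; hierarchical CI coverage at 100 replicates of
n = 30; power and type-I reproduction at 200–300 replicates of n = 14.

# Known limitations

* The normal likelihood is assumed for both endpoints; no robust or skewed
  error alternative is implemented.
* Contrast random effects are modeled independently per food
  (diagonal covariance across the $\beta_{j,i}$), although effects sharing
  the reference food are correlated; the marginal posteriors of the
  $\mu_j$, which drive all decisions, are insensitive to this at the
  trial's scale.
* The split-chain R-hat can flag boundary-hugging variance parameters
  (true $\tau \approx 0$) in small simulated trials even when the location
  parameters are well mixed; the refit-then-fail policy makes this a
  conservative bias for the power estimate.
* CGM preprocessing is deliberately minimal: no interstitial-lag
  correction, no sensor recalibration, no imputation beyond 10-minute
  gaps.
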