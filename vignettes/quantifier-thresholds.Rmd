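---
title: "Modelling quantifier-to-number mapping from truth-value judgments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling quantifier-to-number mapping from truth-value judgments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quantmap)
```

## The problem

When a speaker hears "*most* of the gleerbs are fizzda" and then learns that
52% of the gleerbs are fizzda, do they judge the first sentence true? The
proportion at which a quantifier flips from false to true — its *threshold* —
is a core object of quantifier semantics, and speakers demonstrably disagree
about it, especially for the vague quantifiers *few*, *many* and *most*.
quantmap estimates these thresholds, and how sharply defined they are, from
trial-level truth-value judgment data: one row per trial with a participant
id, a quantifier (*few*, *fewer than half*, *many*, *more than half*,
*most*), a presented percentage (an integer 1–99, never 50), a true/false
response and a response time.

## The response model

Let $Y_{ijk} \in \{0, 1\}$ be participant $i$'s judgment of quantifier $j$
on trial $k$, and $c_{ijk} = (\text{percent}_{ijk} - 50)/100$ the centered
proportion. The model is a Bernoulli likelihood with an error-contaminated
inverse-logit response function:

$$Y_{ijk} \sim \text{Bernoulli}(\pi_{ijk}), \qquad
  \pi_{ijk} = \gamma_{ij} + (1 - 2\gamma_{ij})\,
  \text{logit}^{-1}\!\left(\frac{c_{ijk} - \beta_{ij}}{\alpha_{ij}}\right).$$

Each participant–quantifier cell has three parameters:

* **Threshold** $\beta_{ij}$ — the centered proportion at which
  $\pi = 0.5$ exactly, whatever the other two parameters. Reports quote it
  on the percent scale, $50 + 100\beta$.
* **Vagueness** $\alpha_{ij} > 0$ — the logistic scale. As
  $\alpha \to 0$ the curve approaches the bivalent step function
  $\mathbf{1}[c > \beta]$; larger values mean a more gradual
  false-to-true transition.
* **Response error** $\gamma_{ij} \in (0, 0.5)$ — a threshold-independent
  lapse probability that compresses the asymptotes to
  $[\gamma, 1 - \gamma]$: the participant occasionally says true below
  threshold or false above it regardless of the proportion shown.

Negative quantifiers (*few*, *fewer than half*) have decreasing raw
response curves; their responses are sign-flipped before fitting
(`flip_negative()`) so a single increasing model form covers all five.

The hierarchy places quantifier-level populations over the cells:

$$\gamma_{ij} \sim \text{Beta}(2, 20), \quad
  \beta_{ij} \sim \text{Normal}(\delta_j, \sigma^2_j), \quad
  \alpha_{ij} \sim \text{log-normal}(\nu_j, \sigma^2_{\alpha_j}),$$
$$\delta_j, \nu_j \sim \text{Normal}(0, 5^2), \quad
  \sigma^2_j, \sigma^2_{\alpha_j} \sim \text{Inverse-gamma}(2, 0.2).$$

The Beta(2, 20) prior keeps most response-error mass below 20% with mean
$2/22 \approx 0.091$; the log-normal guarantees positive vagueness. The
inverse-gamma is parameterized as shape 2, scale 0.2 (prior mean variance
0.2), the convention of the probabilistic-programming ecosystem this model
family is usually fitted in; `log_prior()` exposes the constants as
arguments.

## Numerical and design choices

* **$\gamma < 0.5$ as a hard bound.** Above one half the flip direction of
  the curve is no longer identifiable, so the bound is enforced in the
  sampler (truncated prior) and in the generator (resampling), not left to
  the prior's negligible tail mass alone.
* **Sampler.** The joint posterior is sampled with JAGS (Gibbs/slice
  updates) through `rjags`, with the model expressed exactly as the
  likelihood and priors above, in the centered parameterization. Defaults
  follow the recipe the model was designed around: 6 chains, 750 warm-up
  iterations, 2500 iterations per chain. We read "iterations per chain" as
  *including* warm-up (so 1750 kept per chain); set
  `iterations_include_warmup = FALSE` in `mcmc_config()` for the other
  reading. Convergence is summarized by split-$\hat{R}$ (computed on
  half-chains) and effective sample size; parameters above the 1.05
  threshold are listed, never silently accepted. JAGS has no divergence
  diagnostic (it is not a Hamiltonian sampler), so the convergence report
  carries only $\hat{R}$/ESS.
* **Point estimates.** All downstream analyses consume posterior means, so
  rerunning them on a saved summary table is bit-identical.
* **Preprocessing order and boundaries.** Participant-level exclusions
  (fast-guessing, non-monotonicity, manual list) precede the trial-level RT
  filter, which precedes flipping. A participant is a fast guesser when
  *at least* half their RTs are under 300 ms (the boundary excludes); the
  trial filter removes RTs *strictly* below 300 ms or above 2500 ms
  (boundary trials are kept, matching the wording "shorter/longer than").
  The monotonicity screen fits a partially pooled logistic regression per
  polarity group (by-participant random intercepts and slopes, via
  `lme4::glmer`, with an independent per-participant `glm` fallback if the
  mixed fit fails) and excludes participants whose conditional slope
  violates the polarity sign. Participants with all-identical responses
  carry no slope information: slope 0, kept, flagged. Near-zero slopes are
  additionally marked borderline, since their sign is noise.
* **Clustering.** Participants' five-dimensional threshold profiles are
  clustered with Euclidean distances and the Ward criterion on squared
  distances (`hclust` method `ward.D2`), whose merge heights are
  non-decreasing; the full tree is always kept and the reported cut
  (default $k = 4$) is a view, not a commitment. Cluster ids are renumbered
  by size for stable reporting.
* **Discriminant validation.** Stepwise selection minimizes overall Wilks'
  $\Lambda = \det(W)/\det(T)$ with a partial-$F$ entry test at $p < 0.05$
  (the conventional default of stepwise discriminant tools; configurable),
  followed by an LDA with pooled covariance and proportional priors,
  validated by leave-one-out cross-validation.
* **Rank tests.** The quantifier-ordering test is a Friedman test on
  within-participant ranks with Kendall's $W = \chi^2 / (n(k-1))$, plus all
  ten pairwise Wilcoxon signed-rank tests, Bonferroni-corrected. Exact
  p-values are used up to $n = 25$ pairs and the continuity-corrected
  normal approximation above, the standard switch point for cohorts of
  this size. Correlations between parameters are plain Pearson $r$ with
  two-sided p-values and no multiplicity correction, with an
  exclude-and-rerun option for outlier sensitivity.

## The synthetic cohort generator

Every stage is testable without human data because `draw_population()` and
`simulate_trials()` generate cohorts with the statistical structure the
model assumes: 5 quantifiers × 50 trials per participant; percentages
uniform on 1–99 excluding 50, balanced 25-below/25-above-50 for *most*,
*more than half* and *fewer than half* (drawn i.i.d. within each half — the
design leaves repetition within a participant open, and i.i.d. is the
minimal assumption); responses drawn from the response model above, with
negative quantifiers emitted on the raw decreasing scale so preprocessing
is exercised exactly as on real data.

Default population values represent a typical cohort: group-mean
thresholds −0.103 (*few*), −0.006 (*fewer than half*), −0.061 (*many*),
0.001 (*more than half*), 0.029 (*most*), with between-participant SDs
0.073/0.027/0.094/0.012/0.056 and small vagueness means (0.001–0.019,
expressed as natural-scale moments and converted to log-normal
parameters). Response errors are Beta(2, 20) draws, resampled above 0.5.

Response times are a three-part mixture invented purely to exercise the
exclusion rules, since the analysis does not model RT: 1% fast guesses
below 300 ms, 5% slow responses above 2500 ms, and an attentive log-normal
component (median 900 ms) truncated to the keep-window. Planted structure
is available for validation: `plant_fast_guessers()` contaminates chosen
participants, and `population_spec(clusters = ...)` plants threshold
subgroups via per-cluster mean offsets, with participants apportioned to
clusters deterministically by largest remainder so planted sizes are exact.

What the generator does **not** emulate: trial-order and learning effects,
any dependence between RT and accuracy, pragmatic or contextual modulation
of thresholds, and cardinal (non-proportional) readings of *many*/*few*.
Passing recovery tests therefore show that the pipeline inverts its own
generative assumptions at realistic sizes — not that those assumptions hold
of any particular human dataset.

## Validation sizes and known limitations

The package validates itself by parameter recovery at the design size of a
typical study — 71 participants × 5 quantifiers × 50 trials — fitting with
4 chains × (750 + 1750) iterations, plus oracle checks (brute-force
Bernoulli products and prior densities to 1e-10; an exhaustive
Lance–Williams recursion reproducing the Ward tree) and planted-structure
recovery run directly on true parameters to decouple clustering from MCMC.

Two limitations are worth knowing. First, with ~50 trials per cell and
near-step response curves, vagueness is weakly identified: trials inform
$\alpha$ only within a band of a few percentage points around the
threshold, and lapses can mimic shallow slopes, so $\alpha$ estimates lean
on the hierarchy and can sit well below the generating values. Second, the
Inverse-gamma(2, 0.2) variance prior places almost no mass below ≈0.015,
while realistic between-participant threshold variances are one to two
orders of magnitude smaller; the quantifier-level variances are therefore
prior-inflated and the hierarchy shrinks cell estimates only mildly. Both
are properties of the model as specified, faithfully reproduced; they chiefly
affect rank recovery for the two near-degenerate quantifiers (*fewer than
half*, *more than half*), whose true between-participant spread sits at the
posterior noise floor.

## A short tour

```{r, eval = FALSE}
library(quantmap)
library(dplyr)

pop <- population_spec()
params <- draw_population(pop, n_participants = 20, seed = 1)
trials <- simulate_trials(experiment_design(), params, seed = 2)

pp <- preprocess_trials(trials)
fit <- fit_quantifier_model(pp$trials,
                            mcmc_config(n_chains = 4, seed = 3))

tidy(fit)                       # posterior summaries per parameter
tm <- threshold_matrix(fit)     # participants x quantifiers
ordering_test(tm)               # Friedman + Kendall W + pairwise Wilcoxon
cl <- cluster_thresholds(tm, k = 4)
wilks_stepwise(tm, cl$labels)
param_correlations(posterior_means(fit))
autoplot(fit)
```

`run_pipeline(pipeline_config(...))` executes the same stages end to end,
writing every intermediate artifact (trial CSVs, preprocessing report,
posterior summaries, convergence report, cluster and correlation tables,
and a markdown report) into a run directory stamped with the resolved
configuration and its hash.
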