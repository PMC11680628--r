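# Shared fixtures. The full-design recovery fit is expensive (~2-3 min), so
# it is computed once per test session and reused by every file that needs
# it.

.fixture_cache <- new.env(parent = emptyenv())

# Full-cohort parameter-recovery fixture: 71 participants x 5 quantifiers x
# 50 trials at the default population values, no RT contamination, fit with
# 4 chains x (750 warmup + 1750 kept). Seeds fixed for reproducibility.
recovery_fixture <- function() {
  if (!is.null(.fixture_cache$recovery)) return(.fixture_cache$recovery)
  pop <- population_spec()
  params <- draw_population(pop, 71, seed = 777)
  design <- experiment_design(rt_fast_rate = 0, rt_slow_rate = 0)
  trials <- flip_negative(simulate_trials(design, params, seed = 778))
  fit <- suppressWarnings(fit_quantifier_model(
    trials, mcmc_config(n_chains = 4, warmup = 750, iterations = 2500, seed = 9)))
  cmp <- function(par) {
    est <- tidy(fit)
    dplyr::inner_join(est[est$parameter == par, ], params,
                      by = c("participant_id", "quantifier"))
  }
  .fixture_cache$recovery <- list(fit = fit, params = params,
                                  beta = cmp("beta"), alpha = cmp("alpha"),
                                  gamma = cmp("gamma"))
  .fixture_cache$recovery
}

# Four planted threshold subgroups (sizes 6/10/25/30 at n = 71, common
# within-cluster SD 0.03) with distinct profiles on the vague quantifiers
# and near-identical ones on *fewer/more than half*.
planted_cluster_spec <- function(sd = 0.03) {
  profiles <- rbind(
    c(-0.16, -0.01, -0.28, -0.004, 0.06),
    c(-0.13, -0.0001, 0.03, -0.002, 0.12),
    c(-0.14, -0.02, -0.11, 0.001, 0.012),
    c(-0.05, -0.01, -0.012, 0.002, 0.006))
  colnames(profiles) <- quantifier_levels()
  hyper <- dplyr::mutate(default_hyper(), delta = 0, sigma2_beta = sd^2)
  population_spec(hyper = hyper,
                  clusters = list(weights = c(6, 10, 25, 30) / 71,
                                  beta_offsets = profiles))
}

planted_cluster_cohort <- function(seed, n = 71, sd = 0.03) {
  params <- draw_population(planted_cluster_spec(sd), n, seed = seed)
  list(
    params = params,
    truth = params[!duplicated(params$participant_id),
                   c("participant_id", "cluster")],
    matrix = tidyr::pivot_wider(
      params[, c("participant_id", "quantifier", "beta")],
      names_from = "quantifier", values_from = "beta")
  )
}
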