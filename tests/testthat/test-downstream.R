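# A hand-built quantfit whose "posterior draws" are exactly specified,
# so downstream propagation can be checked deterministically.
fake_fit <- function(draw_fun, participants, quantifiers, n_draws = 500) {
  cols <- as.vector(outer(seq_along(participants), seq_along(quantifiers),
                          function(i, j) sprintf("beta[%d,%d]", i, j)))
  half <- lapply(1:2, function(ch) {
    m <- sapply(seq_along(cols), function(k) {
      i <- (k - 1) %% length(participants) + 1
      j <- (k - 1) %/% length(participants) + 1
      draw_fun(i, j, n_draws)
    })
    colnames(m) <- cols
    coda::mcmc(m)
  })
  fit <- structure(list(draws = coda::mcmc.list(half),
                        participants = participants,
                        quantifiers = quantifiers,
                        config = mcmc_config(n_chains = 2, warmup = 1,
                                             iterations = n_draws + 1),
                        n_trials = 0L),
                   class = "quantfit")
  fit$summary <- quantmap:::summarize_draws(fit)
  fit
}

test_that("ordering test reproduces the Friedman/Kendall identities", {
  set.seed(301)
  for (rep in 1:5) {
    n <- sample(8:30, 1); k <- sample(3:5, 1)
    m <- matrix(rnorm(n * k), n, k,
                dimnames = list(NULL, paste0("q", 1:k)))
    tbl <- dplyr::bind_cols(participant_id = sprintf("p%02d", 1:n),
                            tibble::as_tibble(m))
    res <- ordering_test(tbl)
    expect_equal(res$friedman$statistic, oracle_friedman_chisq(m),
                 tolerance = 1e-10)
    expect_equal(res$kendall_w,
                 res$friedman$statistic / (n * (k - 1)), tolerance = 1e-12)
    expect_equal(nrow(res$pairwise), choose(k, 2))
    expect_true(all(res$pairwise$p_bonferroni >= res$pairwise$p - 1e-15))
  }
})

test_that("identical columns give a null ordering result", {
  x <- rnorm(10)
  tbl <- tibble::tibble(participant_id = sprintf("p%02d", 1:10),
                        a = x, b = x, c = x)
  res <- suppressWarnings(ordering_test(tbl))
  expect_equal(res$friedman$statistic, 0)
  expect_equal(res$kendall_w, 0)
  expect_equal(length(res$all_tied_participants), 10)
})

test_that("uniformly signed paired differences attain the maximal V", {
  set.seed(302)
  base <- rnorm(71)
  tbl <- tibble::tibble(participant_id = sprintf("p%02d", 1:71),
                        hi = base + abs(rnorm(71)) + 0.01, lo = base)
  res <- ordering_test(tbl)
  # (hi, lo) differences are all positive, so V attains its maximum
  expect_equal(res$pairwise$V[1], 71 * 72 / 2)
  expect_equal(wilcoxon_v_max(71), 2556)
})

test_that("threshold differences propagate the posterior", {
  # most - many difference fixed at 0.05 plus posterior noise
  fit <- fake_fit(function(i, j, n) {
    center <- if (j == 1) -0.06 + i / 100 else -0.01 + i / 100
    center + rnorm(n, sd = 0.01)
  }, participants = sprintf("p%02d", 1:8), quantifiers = c("many", "most"))
  d <- threshold_differences(fit, c("most", "many"), order_by = "many")
  expect_equal(d$difference, rep(0.05, 8), tolerance = 0.02)
  expect_true(all(d$lower < 0.05 & d$upper > 0.05))
  # ordering by the many posterior mean
  expect_equal(d$participant_id, sprintf("p%02d", 1:8))
  # self-difference is exactly zero
  d0 <- threshold_differences(fit, c("many", "many"))
  expect_true(all(d0$difference == 0 & d0$lower == 0 & d0$upper == 0))
})

test_that("ward clustering agrees with the exhaustive Lance-Williams oracle", {
  set.seed(303)
  for (rep in 1:5) {
    n <- sample(6:12, 1)
    x <- matrix(rnorm(n * 5), n, 5,
                dimnames = list(sprintf("p%02d", 1:n), quantifier_levels()))
    tbl <- dplyr::bind_cols(participant_id = rownames(x), tibble::as_tibble(x))
    cl <- cluster_thresholds(tbl, k = 2)
    or <- oracle_ward(x)
    expect_equal(cl$tree$height, or$height, tolerance = 1e-10)
    got <- t(apply(cl$tree$merge, 1, sort))
    storage.mode(got) <- "double"
    expect_equal(got, or$merge, ignore_attr = TRUE)
    # ultrametric monotonicity of merge heights
    expect_true(all(diff(cl$tree$height) >= -1e-12))
  }
})

test_that("cluster solutions are invariant to participant order and degenerate cuts", {
  co <- planted_cluster_cohort(seed = 311, n = 24)
  cl <- cluster_thresholds(co$matrix, k = 4)
  shuffled <- co$matrix[sample(nrow(co$matrix)), ]
  cl2 <- cluster_thresholds(shuffled, k = 4)
  ids <- co$matrix$participant_id
  expect_equal(cl$labels[ids], cl2$labels[ids])
  # k = n: singletons with zero within-cluster variance
  cln <- cluster_thresholds(co$matrix, k = nrow(co$matrix))
  expect_equal(sort(unique(cln$summary$n)), 1)
  expect_true(all(is.na(cln$summary$sd)))
  expect_error(cluster_thresholds(co$matrix, k = 99), "exceed")
})

test_that("well-separated planted subgroups are recovered at the planted cut", {
  skip_if_not_installed("mclust")
  co <- planted_cluster_cohort(seed = 312, sd = 0.012)
  cl <- cluster_thresholds(co$matrix, k = 4)
  ari <- mclust::adjustedRandIndex(cl$labels[co$truth$participant_id],
                                   co$truth$cluster)
  expect_gt(ari, 0.9)
  expect_equal(sort(as.integer(table(cl$labels))), c(6, 10, 25, 30))
  # percent equivalents use the linear threshold map
  expect_equal(cl$summary$percent,
               threshold_to_percent(cl$summary$mean))
})

test_that("stepwise Wilks selection separates signal from noise variables", {
  set.seed(313)
  # labels independent of the variables: nothing may enter
  n <- 40
  m <- tibble::tibble(participant_id = sprintf("p%02d", 1:n),
                      a = rnorm(n), b = rnorm(n), c = rnorm(n))
  labels <- stats::setNames(rep(1:2, each = n / 2), m$participant_id)
  sel <- wilks_stepwise(m, sample(labels))
  expect_equal(nrow(sel), 0)
  # one perfectly separating variable enters first with tiny lambda
  m2 <- dplyr::mutate(m, a = ifelse(labels == 1, 0, 10) + rnorm(n, sd = 0.1))
  sel2 <- wilks_stepwise(m2, labels)
  expect_equal(sel2$variable[1], "a")
  expect_lt(sel2$lambda[1], 0.01)
  # lambda of the first entrant equals the univariate SSW/SST ratio
  av <- stats::aov(m2$a ~ factor(labels))
  ss <- summary(av)[[1]]$`Sum Sq`
  expect_equal(sel2$lambda[1], ss[2] / sum(ss), tolerance = 1e-10)
})

test_that("LDA validation reports resubstitution and leave-one-out accuracy", {
  co <- planted_cluster_cohort(seed = 321, sd = 0.005)
  cl_labels <- co$truth$cluster
  names(cl_labels) <- co$truth$participant_id
  res <- lda_validate(co$matrix, cl_labels,
                      variables = c("many", "most", "few"))
  expect_equal(res$accuracy_resub, 1.0)
  expect_gte(res$accuracy_loo, 0.95)
  expect_equal(dim(res$confusion_resub), c(4, 4))
  # identical points with conflicting labels cannot both be classified right
  dup <- tibble::tibble(participant_id = sprintf("p%02d", 1:8),
                        x = c(0, 0, 0, 0, 5, 6, 7, 8))
  lab <- stats::setNames(c(1, 2, 1, 2, 1, 1, 1, 1), dup$participant_id)
  res2 <- lda_validate(dup, lab)
  expect_lte(res2$accuracy_resub, 0.75)
})

test_that("resubstitution accuracy dominates leave-one-out on average", {
  skip_if_not_installed("mclust")
  accs <- sapply(1:4, function(r) {
    co <- planted_cluster_cohort(seed = 330 + r, n = 40)
    lab <- stats::setNames(co$truth$cluster, co$truth$participant_id)
    res <- lda_validate(co$matrix, lab)
    c(res$accuracy_resub, res$accuracy_loo)
  })
  expect_gte(mean(accs[1, ] - accs[2, ]), 0)
})

test_that("parameter correlations recover planted association and null behavior", {
  set.seed(341)
  # a column against itself
  n <- 71
  means <- tidyr::expand_grid(participant_id = sprintf("p%02d", 1:n),
                              quantifier = "many") |>
    dplyr::mutate(beta = rnorm(n), alpha = beta, gamma = rnorm(n))
  res <- param_correlations(means)
  expect_equal(res$r[res$pair == "beta-alpha"], 1)
  # planted correlation 0.5 between alpha and gamma
  z <- rnorm(500); a <- z; g <- 0.5 * z + sqrt(1 - 0.25) * rnorm(500)
  means2 <- tibble::tibble(participant_id = sprintf("p%03d", 1:500),
                           quantifier = "few", beta = rnorm(500),
                           alpha = a, gamma = g)
  res2 <- param_correlations(means2)
  expect_equal(res2$r[res2$pair == "alpha-gamma"], 0.5, tolerance = 0.12)
  # type-I error calibration at alpha = 0.05
  hits <- replicate(400, {
    d <- tibble::tibble(participant_id = sprintf("p%02d", 1:71),
                        quantifier = "most", beta = rnorm(71),
                        alpha = rnorm(71), gamma = rnorm(71))
    param_correlations(d)$p[1] < 0.05
  })
  expect_gt(mean(hits), 0.015)
  expect_lt(mean(hits), 0.10)
  # outlier-sensitivity rerun drops the named participants
  res3 <- param_correlations(means2, exclude = c("p001", "p002"))
  expect_equal(unique(res3$n), 498)
})
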