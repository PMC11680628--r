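# Independent oracles used to cross-check the implementation.

# Brute-force Bernoulli log-likelihood: per-trial probability computed with
# plain arithmetic (no package functions), then log-multiplied.
oracle_log_likelihood <- function(trials, params) {
  total <- 0
  for (r in seq_len(nrow(trials))) {
    row <- trials[r, ]
    cell <- params[params$participant_id == row$participant_id &
                     params$quantifier == row$quantifier, ]
    cc <- (row$percent - 50) / 100
    mu <- (cc - cell$beta) / cell$alpha
    p <- cell$gamma + (1 - 2 * cell$gamma) / (1 + exp(-mu))
    total <- total + if (row$response == 1) log(p) else log(1 - p)
  }
  total
}

# Textbook density formulas, written out with lgamma/log directly.
oracle_log_prior <- function(params, hyper) {
  lbeta_d <- function(x, a, b) {
    lgamma(a + b) - lgamma(a) - lgamma(b) + (a - 1) * log(x) + (b - 1) * log(1 - x)
  }
  lnorm_d <- function(x, m, v) -0.5 * log(2 * pi * v) - (x - m)^2 / (2 * v)
  llnorm_d <- function(x, m, v) lnorm_d(log(x), m, v) - log(x)
  linvgamma_d <- function(x, shape, scale) {
    shape * log(scale) - lgamma(shape) - (shape + 1) * log(x) - scale / x
  }
  total <- 0
  for (r in seq_len(nrow(params))) {
    row <- params[r, ]
    h <- hyper[hyper$quantifier == row$quantifier, ]
    total <- total + lbeta_d(row$gamma, 2, 20) +
      lnorm_d(row$beta, h$delta, h$sigma2_beta) +
      llnorm_d(row$alpha, h$nu, h$sigma2_alpha)
  }
  for (r in seq_len(nrow(hyper))) {
    h <- hyper[r, ]
    total <- total + lnorm_d(h$delta, 0, 25) + lnorm_d(h$nu, 0, 25) +
      linvgamma_d(h$sigma2_beta, 2, 0.2) + linvgamma_d(h$sigma2_alpha, 2, 0.2)
  }
  total
}

# Exhaustive Lance-Williams agglomeration with the Ward-on-squared-distances
# update; heights reported on the distance scale (ward.D2 convention).
oracle_ward <- function(x) {
  n <- nrow(x)
  d2 <- as.matrix(dist(x))^2
  size <- rep(1, n)
  active <- 1:n
  id <- -(1:n)
  merges <- matrix(0, n - 1, 2)
  heights <- numeric(n - 1)
  for (step in 1:(n - 1)) {
    best <- c(Inf, NA, NA)
    for (ii in seq_along(active)) {
      for (jj in seq_len(ii - 1)) {
        i <- active[ii]; j <- active[jj]
        if (d2[i, j] < best[1]) best <- c(d2[i, j], j, i)
      }
    }
    i <- best[2]; j <- best[3]
    heights[step] <- sqrt(best[1])
    merges[step, ] <- sort(c(id[i], id[j]))
    ni <- size[i]; nj <- size[j]
    for (k in setdiff(active, c(i, j))) {
      nk <- size[k]
      d2[i, k] <- d2[k, i] <-
        ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] - nk * best[1]) /
        (ni + nj + nk)
    }
    size[i] <- ni + nj
    id[i] <- step
    active <- setdiff(active, j)
  }
  list(merge = merges, height = heights)
}

# Friedman chi-squared recomputed from midranks (tie-corrected), following
# the defining formula rather than stats::friedman.test.
oracle_friedman_chisq <- function(m) {
  n <- nrow(m); k <- ncol(m)
  ranks <- t(apply(m, 1, rank))
  rj <- colSums(ranks)
  tie_term <- sum(apply(m, 1, function(row) {
    t <- table(row)
    sum(t^3 - t)
  }))
  num <- 12 * sum((rj - n * (k + 1) / 2)^2)
  den <- n * k * (k + 1) - tie_term / (k - 1)
  num / den
}

random_params <- function(n_participants, quantifiers) {
  tidyr::expand_grid(participant_id = sprintf("p%02d", 1:n_participants),
                     quantifier = quantifiers) |>
    dplyr::mutate(beta = runif(dplyr::n(), -0.3, 0.3),
                  alpha = runif(dplyr::n(), 0.005, 0.1),
                  gamma = runif(dplyr::n(), 0.01, 0.3))
}

random_trials <- function(params, n_per_cell) {
  purrr::pmap_dfr(params, function(participant_id, quantifier, ...) {
    tibble::tibble(participant_id = participant_id, quantifier = quantifier,
                   percent = sample(setdiff(1:99, 50), n_per_cell, replace = TRUE),
                   response = sample(0:1, n_per_cell, replace = TRUE),
                   rt_ms = 800)
  })
}
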