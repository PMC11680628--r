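#' MCMC configuration
#'
#' Defaults follow the fitting recipe the model was designed around: six
#' chains, 750 warm-up iterations and 2500 iterations per chain, with an
#' Rhat acceptance threshold of 1.05. `iterations` is read as the total per
#' chain *including* warm-up by default; set
#' `iterations_include_warmup = FALSE` to treat it as post-warm-up draws.
#'
#' @param n_chains Number of chains (default 6).
#' @param warmup Warm-up (adaptation) iterations per chain (default 750).
#' @param iterations Iterations per chain (default 2500).
#' @param iterations_include_warmup Whether `iterations` counts warm-up
#'   (default TRUE).
#' @param seed Integer seed; chain c uses seed + c.
#' @param rhat_threshold Convergence flag threshold (default 1.05).
#' @return An object of class `quant_mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 6, warmup = 750, iterations = 2500,
                        iterations_include_warmup = TRUE, seed = 1,
                        rhat_threshold = 1.05) {
  keep <- if (iterations_include_warmup) iterations - warmup else iterations
  if (keep <= 0) stop("`iterations` must exceed `warmup`.", call. = FALSE)
  structure(list(n_chains = n_chains, warmup = warmup, iterations = iterations,
                 iterations_include_warmup = iterations_include_warmup,
                 keep = keep, seed = seed, rhat_threshold = rhat_threshold),
            class = "quant_mcmc_config")
}

# JAGS model. The likelihood block is omitted when there are no trials, in
# which case sampling targets the prior (prior predictive contract).
jags_model_string <- function(with_likelihood) {
  lik <- "
  for (n in 1:N) {
    mu[n] <- (c[n] - beta[pid[n], qid[n]]) / alpha[pid[n], qid[n]]
    p[n] <- gamma[pid[n], qid[n]] + (1 - 2 * gamma[pid[n], qid[n]]) * ilogit(mu[n])
    y[n] ~ dbern(p[n])
  }"
  paste0("model {", if (with_likelihood) lik else "", "
  for (i in 1:I) { for (j in 1:J) {
    gamma[i, j] ~ dbeta(gamma_a, gamma_b) T(, 0.4999)
    beta[i, j] ~ dnorm(delta[j], prec_beta[j])
    alpha[i, j] ~ dlnorm(nu[j], prec_alpha[j])
  }}
  for (j in 1:J) {
    delta[j] ~ dnorm(0, 0.04)
    nu[j] ~ dnorm(0, 0.04)
    prec_beta[j] ~ dgamma(2, 0.2)
    prec_alpha[j] ~ dgamma(2, 0.2)
    sigma2_beta[j] <- 1 / prec_beta[j]
    sigma2_alpha[j] <- 1 / prec_alpha[j]
  }
}")
}

# Split-Rhat (potential scale reduction on half-chains). Returns NA for
# constant or too-short sequences rather than erroring.
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    n <- length(x) %/% 2
    if (n < 2) return(NULL)
    list(x[seq_len(n)], x[n + seq_len(n)])
  }), recursive = FALSE)
  if (length(halves) < 2) return(NA_real_)
  n <- min(lengths(halves))
  halves <- lapply(halves, function(x) x[seq_len(n)])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  w <- mean(vars)
  b <- n * var(means)
  if (!is.finite(w) || w <= .Machine$double.eps) return(NA_real_)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Fit the hierarchical quantifier model
#'
#' Samples the joint posterior over all participant-quantifier cells
#' (threshold beta, vagueness alpha, response error gamma) and quantifier
#' hyperparameters (delta, sigma2_beta, nu, sigma2_alpha) by MCMC (Gibbs /
#' slice sampling via JAGS). `trials` should be preprocessed — RT-filtered
#' and response-flipped so every curve is increasing.
#'
#' With an empty trial table the sampler targets the prior; supply
#' `participants` and `quantifiers` explicitly in that case.
#'
#' @param trials Preprocessed trial tibble.
#' @param config A [mcmc_config()].
#' @param participants,quantifiers Optional explicit cell structure (only
#'   needed when `trials` is empty).
#' @param quiet Suppress JAGS progress output (default TRUE).
#' @return An object of class `quantfit` with elements `draws` (a
#'   `coda::mcmc.list`), `summary` (tibble of posterior means, SDs, central
#'   95% credible intervals, split-Rhat and ESS for every parameter),
#'   `convergence` (see [check_convergence()]), `participants`,
#'   `quantifiers` and `config`.
#' @export
fit_quantifier_model <- function(trials, config = mcmc_config(),
                                 participants = NULL, quantifiers = NULL,
                                 quiet = TRUE) {
  stopifnot(inherits(config, "quant_mcmc_config"))
  has_data <- nrow(trials) > 0
  if (has_data) {
    participants <- sort(unique(trials$participant_id))
    quantifiers <- intersect(quantifier_levels(), unique(trials$quantifier))
    if (!length(quantifiers)) quantifiers <- sort(unique(trials$quantifier))
  } else if (is.null(participants) || is.null(quantifiers)) {
    stop("With empty `trials`, supply `participants` and `quantifiers`.", call. = FALSE)
  }
  I <- length(participants); J <- length(quantifiers)
  if (has_data && (I < 2 || J < 1)) {
    stop("Need at least 2 participants and 1 quantifier.", call. = FALSE)
  }
  data <- list(I = I, J = J, gamma_a = 2, gamma_b = 20)
  if (has_data) {
    data$N <- nrow(trials)
    data$y <- as.integer(trials$response)
    data$c <- center_percent(trials$percent)
    data$pid <- match(trials$participant_id, participants)
    data$qid <- match(trials$quantifier, quantifiers)
  }
  inits <- lapply(seq_len(config$n_chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (config$seed * 1009 + ch) %% 2147483647)
  })
  jm <- rjags::jags.model(textConnection(jags_model_string(has_data)),
                          data = data, inits = inits,
                          n.chains = config$n_chains,
                          n.adapt = config$warmup, quiet = quiet)
  monitors <- c("beta", "alpha", "gamma", "delta", "sigma2_beta", "nu", "sigma2_alpha")
  draws <- rjags::coda.samples(jm, monitors, n.iter = config$keep,
                               progress.bar = "none")
  fit <- structure(list(draws = draws, participants = participants,
                        quantifiers = quantifiers, config = config,
                        n_trials = if (has_data) nrow(trials) else 0L),
                   class = "quantfit")
  fit$summary <- summarize_draws(fit)
  fit$convergence <- check_convergence(fit, config$rhat_threshold)
  if (length(fit$convergence$flagged)) {
    warning(length(fit$convergence$flagged),
            " parameter(s) with Rhat above ", config$rhat_threshold,
            " (or undefined); inspect `$convergence`.", call. = FALSE)
  }
  fit
}

# Map a JAGS column name like "beta[3,2]" to participant/quantifier labels.
parse_varnames <- function(vars, participants, quantifiers) {
  base <- sub("\\[.*$", "", vars)
  get_idx <- function(v) {
    m <- regmatches(v, regexpr("(?<=\\[).*(?=\\])", v, perl = TRUE))
    # JAGS drops the index on scalar nodes (single-quantifier fits)
    if (!length(m)) return(c(NA_integer_, 1L))
    parts <- as.integer(strsplit(m, ",")[[1]])
    if (length(parts) == 1) parts <- c(NA_integer_, parts)
    parts
  }
  ij <- t(vapply(vars, get_idx, integer(2)))
  cell <- base %in% c("beta", "alpha", "gamma")
  tibble::tibble(
    variable = vars, parameter = base,
    level = ifelse(cell, "cell", "hyper"),
    participant_id = ifelse(cell, participants[ij[, 1]], NA_character_),
    quantifier = quantifiers[ij[, 2]]
  )
}

summarize_draws <- function(fit) {
  draws <- fit$draws
  pooled <- as.matrix(draws)
  chains <- lapply(draws, as.matrix)
  vars <- colnames(pooled)
  ess <- tryCatch(coda::effectiveSize(draws), error = function(e) rep(NA_real_, length(vars)))
  info <- parse_varnames(vars, fit$participants, fit$quantifiers)
  info |>
    dplyr::mutate(
      mean = colMeans(pooled),
      sd = apply(pooled, 2, sd),
      lower = apply(pooled, 2, quantile, 0.025),
      upper = apply(pooled, 2, quantile, 0.975),
      rhat = vapply(vars, function(v) split_rhat(lapply(chains, function(m) m[, v])),
                    numeric(1)),
      ess = as.numeric(ess[vars])
    )
}

#' Convergence diagnostics for a fitted model
#'
#' Computes split-Rhat and effective sample size for every monitored
#' parameter and lists those exceeding the threshold (or with undefined
#' Rhat, e.g. constant chains). Runs with fewer than 4 retained draws per
#' half-chain are flagged as insufficient rather than trusted.
#'
#' @param fit A `quantfit` (or a `coda::mcmc.list`).
#' @param threshold Rhat flag threshold (default 1.05).
#' @return List of class `quant_convergence`: `summary` (parameter, rhat,
#'   ess), `flagged` (parameter names with Rhat > threshold or NA),
#'   `sufficient` (logical), `n_kept` draws per chain.
#' @export
check_convergence <- function(fit, threshold = 1.05) {
  if (inherits(fit, "quantfit")) {
    smry <- fit$summary
    if (is.null(smry)) smry <- summarize_draws(fit)
    n_kept <- nrow(as.matrix(fit$draws[[1]]))
  } else {
    draws <- fit
    if (length(draws) < 2) stop("Need at least 2 chains.", call. = FALSE)
    chains <- lapply(draws, as.matrix)
    vars <- colnames(chains[[1]])
    ess <- tryCatch(coda::effectiveSize(draws),
                    error = function(e) setNames(rep(NA_real_, length(vars)), vars))
    smry <- tibble::tibble(
      variable = vars, parameter = sub("\\[.*$", "", vars),
      rhat = vapply(vars, function(v) split_rhat(lapply(chains, function(m) m[, v])),
                    numeric(1)),
      ess = as.numeric(ess[vars]))
    n_kept <- nrow(chains[[1]])
  }
  flagged <- smry$variable[is.na(smry$rhat) | smry$rhat > threshold]
  structure(list(summary = dplyr::select(smry, dplyr::any_of(
    c("variable", "parameter", "participant_id", "quantifier", "rhat", "ess"))),
    flagged = flagged, sufficient = n_kept >= 8, n_kept = n_kept,
    threshold = threshold), class = "quant_convergence")
}

#' @export
print.quant_convergence <- function(x, ...) {
  cat("Convergence report:", nrow(x$summary), "parameters,",
      x$n_kept, "kept draws per chain\n")
  if (!x$sufficient) cat("  WARNING: too few draws for reliable diagnostics\n")
  if (length(x$flagged)) {
    cat("  Rhat >", x$threshold, "or undefined for:",
        paste(utils::head(x$flagged, 10), collapse = ", "),
        if (length(x$flagged) > 10) "..." else "", "\n")
  } else {
    cat("  all Rhat <=", x$threshold, "\n")
  }
  invisible(x)
}

#' Posterior means of cell parameters, long format
#'
#' @param fit A `quantfit`.
#' @return Tibble with `participant_id`, `quantifier`, `beta`, `alpha`,
#'   `gamma` (posterior means).
#' @export
posterior_means <- function(fit) {
  fit$summary |>
    dplyr::filter(.data$level == "cell") |>
    dplyr::select("participant_id", "quantifier", "parameter", "mean") |>
    tidyr::pivot_wider(names_from = "parameter", values_from = "mean")
}

#' Participants-by-quantifiers matrix of posterior means
#'
#' The input to the clustering and ordering analyses: one row per
#' participant, one column per quantifier, entries the posterior mean of
#' `parameter`.
#'
#' @param fit A `quantfit`.
#' @param parameter One of "beta", "alpha", "gamma".
#' @return Wide tibble (`participant_id` + one column per quantifier).
#' @export
threshold_matrix <- function(fit, parameter = "beta") {
  parameter <- match.arg(parameter, c("beta", "alpha", "gamma"))
  fit$summary |>
    dplyr::filter(.data$level == "cell", .data$parameter == !!parameter) |>
    dplyr::select("participant_id", "quantifier", "mean") |>
    tidyr::pivot_wider(names_from = "quantifier", values_from = "mean")
}

# Draws matrix for one cell parameter: iterations x (participant,quantifier),
# with a map describing the columns.
cell_draws <- function(fit, parameter = "beta") {
  pooled <- as.matrix(fit$draws)
  keep <- grepl(paste0("^", parameter, "\\["), colnames(pooled))
  m <- pooled[, keep, drop = FALSE]
  map <- parse_varnames(colnames(m), fit$participants, fit$quantifiers)
  list(draws = m, map = map)
}

#' @export
print.quantfit <- function(x, ...) {
  cat("Hierarchical quantifier model fit\n")
  cat("  participants:", length(x$participants),
      " quantifiers:", length(x$quantifiers),
      " trials:", x$n_trials, "\n")
  cat("  chains:", x$config$n_chains, " kept draws/chain:", x$config$keep, "\n")
  rh <- x$summary$rhat
  cat(sprintf("  max Rhat: %.3f  (%d flagged)\n",
              suppressWarnings(max(rh, na.rm = TRUE)),
              length(x$convergence$flagged)))
  invisible(x)
}

#' @rdname quantfit-tidiers
#' @export
tidy.quantfit <- function(x, level = c("cell", "hyper", "all"), ...) {
  level <- match.arg(level)
  s <- x$summary
  if (level != "all") s <- dplyr::filter(s, .data$level == !!level)
  dplyr::select(s, "level", "participant_id", "quantifier", "parameter",
                "mean", "sd", "lower", "upper", "rhat", "ess")
}

#' Tidiers for fitted quantifier models
#'
#' `tidy()` returns one row per parameter with posterior mean, SD, 95%
#' credible interval and diagnostics; `glance()` a one-row model overview.
#'
#' @param x A `quantfit`.
#' @param level Which parameters: cell-level ("cell"), quantifier-level
#'   hyperparameters ("hyper"), or both ("all").
#' @param ... Unused.
#' @name quantfit-tidiers
#' @export
glance.quantfit <- function(x, ...) {
  tibble::tibble(
    n_participants = length(x$participants),
    n_quantifiers = length(x$quantifiers),
    n_trials = x$n_trials,
    n_chains = x$config$n_chains,
    draws_per_chain = x$config$keep,
    max_rhat = suppressWarnings(max(x$summary$rhat, na.rm = TRUE)),
    n_flagged = length(x$convergence$flagged)
  )
}

#' Write posterior outputs
#'
#' `write_posterior_summary()` writes the tidy parameter summary as CSV;
#' `write_draws()` one CSV per chain; `write_convergence()` the convergence
#' report as JSON.
#'
#' @param fit A `quantfit`.
#' @param path,dir Output locations.
#' @return The path(s), invisibly.
#' @export
write_posterior_summary <- function(fit, path) {
  utils::write.csv(tidy(fit, "all"), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_posterior_summary
#' @export
write_draws <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- purrr::imap_chr(fit$draws, function(ch, i) {
    p <- file.path(dir, sprintf("chain-%02d.csv", i))
    utils::write.csv(as.data.frame(as.matrix(ch)), p, row.names = FALSE)
    p
  })
  invisible(paths)
}

#' @rdname write_posterior_summary
#' @export
write_convergence <- function(fit, path) {
  cv <- fit$convergence
  jsonlite::write_json(list(flagged = cv$flagged, sufficient = cv$sufficient,
                            n_kept = cv$n_kept, threshold = cv$threshold,
                            summary = cv$summary),
                       path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}
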