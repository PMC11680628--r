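#' Describe the trial design of a truth-value judgment experiment
#'
#' The default design mirrors the task the model targets: five quantifiers,
#' 50 trials each, presented percentages on the integer grid 1..99 excluding
#' 50. For *most*, *more than half* and *fewer than half* — whose thresholds
#' sit near 50% — percentages are balanced, 25 below and 25 above 50; for
#' *few* and *many* they are drawn uniformly over the whole grid.
#'
#' Response times are generated from a three-component mixture so the
#' RT-based exclusion rules have something to bite on: a fast-guess
#' component below `rt_floor`, a log-normal "attentive" component truncated
#' to `[rt_floor, rt_ceiling]`, and a slow tail above `rt_ceiling`. The
#' default contamination rates (1% fast, 5% slow) match the trial fractions
#' such experiments typically discard.
#'
#' @param quantifiers Ordered character vector of quantifier labels.
#' @param trials_per_quantifier Trials per participant-quantifier cell
#'   (default 50); must be even for balanced quantifiers.
#' @param balanced Labels whose percentages are drawn half below, half
#'   above 50.
#' @param rt_fast_rate,rt_slow_rate Mixture weights of the fast-guess and
#'   slow-tail RT components.
#' @param rt_meanlog,rt_sdlog Log-scale parameters of the nominal RT
#'   component (milliseconds).
#' @param rt_floor,rt_ceiling Bounds (ms) separating the contamination
#'   components from the nominal one.
#' @return An object of class `quant_design`.
#' @examples
#' experiment_design(trials_per_quantifier = 10)
#' @export
experiment_design <- function(quantifiers = quantifier_levels(),
                              trials_per_quantifier = 50,
                              balanced = c("most", "more than half", "fewer than half"),
                              rt_fast_rate = 0.01,
                              rt_slow_rate = 0.05,
                              rt_meanlog = log(900),
                              rt_sdlog = 0.35,
                              rt_floor = 300,
                              rt_ceiling = 2500) {
  balanced <- intersect(balanced, quantifiers)
  if (length(balanced) && trials_per_quantifier %% 2 != 0) {
    stop("`trials_per_quantifier` must be even when any quantifier is balanced.",
         call. = FALSE)
  }
  if (rt_fast_rate < 0 || rt_slow_rate < 0 || rt_fast_rate + rt_slow_rate >= 1) {
    stop("RT contamination rates must be non-negative and sum below 1.", call. = FALSE)
  }
  structure(
    list(quantifiers = quantifiers, trials_per_quantifier = trials_per_quantifier,
         balanced = balanced, rt_fast_rate = rt_fast_rate, rt_slow_rate = rt_slow_rate,
         rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog,
         rt_floor = rt_floor, rt_ceiling = rt_ceiling,
         percent_domain = setdiff(1:99, 50)),
    class = "quant_design"
  )
}

#' Default population hyperparameters
#'
#' Quantifier-level means and variances of a typical cohort: group-mean
#' thresholds of -0.103 (*few*), -0.006 (*fewer than half*), -0.061
#' (*many*), 0.001 (*more than half*) and 0.029 (*most*) with the matching
#' between-participant SDs, and vagueness distributions expressed on the
#' natural scale (mean, SD) and converted to log-normal parameters.
#'
#' @return Tibble with one row per quantifier: `delta`, `sigma2_beta`,
#'   `nu`, `sigma2_alpha`.
#' @export
default_hyper <- function() {
  beta_mean <- c(-0.103, -0.006, -0.061, 0.001, 0.029)
  beta_sd   <- c(0.073, 0.027, 0.094, 0.012, 0.056)
  alpha_mean <- c(0.016, 0.002, 0.019, 0.001, 0.009)
  alpha_sd   <- c(0.001, 0.00004, 0.003, 0.00003, 0.001)
  ln <- purrr::map2(alpha_mean, alpha_sd, lognormal_from_moments)
  tibble::tibble(
    quantifier = quantifier_levels(),
    delta = beta_mean,
    sigma2_beta = beta_sd^2,
    nu = purrr::map_dbl(ln, "meanlog"),
    sigma2_alpha = purrr::map_dbl(ln, "sdlog2")
  )
}

#' Specify the population a synthetic cohort is drawn from
#'
#' @param hyper Tibble of quantifier-level hyperparameters as returned by
#'   [default_hyper()]: columns `quantifier`, `delta` (threshold mean),
#'   `sigma2_beta` (threshold variance), `nu`, `sigma2_alpha` (log-scale
#'   vagueness mean and variance).
#' @param gamma_shape Beta shape parameters of the response-error law
#'   (default `c(2, 20)`, mean 1/11); draws at or above 0.5 are resampled.
#' @param clusters Optional planted subgroup structure: a list with
#'   `weights` (positive, summing to 1) and `beta_offsets`, a matrix of
#'   per-cluster, per-quantifier offsets added to `delta` (rows = clusters,
#'   columns named by quantifier; missing quantifiers get offset 0).
#'   Participants are apportioned to clusters deterministically by largest
#'   remainder, so `weights = sizes / n` reproduces exact planted sizes.
#' @return An object of class `quant_population`.
#' @export
population_spec <- function(hyper = default_hyper(), gamma_shape = c(2, 20),
                            clusters = NULL) {
  bad <- hyper$quantifier[hyper$sigma2_beta <= 0 | hyper$sigma2_alpha <= 0]
  if (length(bad)) {
    stop("Variances must be strictly positive; offending quantifier(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(clusters)) {
    stopifnot(is.list(clusters), !is.null(clusters$weights), !is.null(clusters$beta_offsets))
    if (abs(sum(clusters$weights) - 1) > 1e-8) {
      stop("Cluster weights must sum to 1.", call. = FALSE)
    }
    if (nrow(clusters$beta_offsets) != length(clusters$weights)) {
      stop("`beta_offsets` needs one row per cluster weight.", call. = FALSE)
    }
  }
  structure(list(hyper = hyper, gamma_shape = gamma_shape, clusters = clusters),
            class = "quant_population")
}

# Largest-remainder apportionment of n into round(w*n) with exact total.
apportion <- function(weights, n) {
  raw <- weights * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Draw participant-level parameters from a population
#'
#' For each participant and quantifier: beta ~ Normal(delta_j + cluster
#' offset, sigma2_beta_j), alpha ~ log-normal(nu_j, sigma2_alpha_j) (so
#' vagueness is always positive), gamma ~ Beta(shape) resampled until below
#' 0.5. With zero variances the draw degenerates to the mean, which makes
#' exact planting possible.
#'
#' @param spec A [population_spec()].
#' @param n_participants Number of participants (>= 1).
#' @param seed Optional integer seed; identical seed + spec gives an
#'   identical table.
#' @return Tibble with columns `participant_id`, `cluster`, `quantifier`,
#'   `beta`, `alpha`, `gamma`.
#' @export
draw_population <- function(spec, n_participants, seed = NULL) {
  stopifnot(inherits(spec, "quant_population"), n_participants >= 1)
  if (!is.null(seed)) set.seed(seed)
  hyper <- spec$hyper
  qs <- hyper$quantifier
  if (is.null(spec$clusters)) {
    cluster <- rep(1L, n_participants)
    offsets <- matrix(0, 1, length(qs), dimnames = list(NULL, qs))
  } else {
    sizes <- apportion(spec$clusters$weights, n_participants)
    cluster <- rep(seq_along(sizes), sizes)
    offsets <- matrix(0, length(sizes), length(qs), dimnames = list(NULL, qs))
    given <- spec$clusters$beta_offsets
    offsets[, colnames(given)] <- given
  }
  ids <- sprintf("p%03d", seq_len(n_participants))
  grid <- tidyr::expand_grid(participant_id = ids, quantifier = qs) |>
    dplyr::left_join(hyper, by = "quantifier") |>
    dplyr::mutate(cluster = cluster[match(.data$participant_id, ids)])
  grid$beta <- rnorm(nrow(grid),
                     grid$delta + offsets[cbind(grid$cluster, match(grid$quantifier, qs))],
                     sqrt(grid$sigma2_beta))
  grid$alpha <- rlnorm(nrow(grid), grid$nu, sqrt(grid$sigma2_alpha))
  g <- rbeta(nrow(grid), spec$gamma_shape[1], spec$gamma_shape[2])
  while (any(g >= 0.5)) {
    i <- which(g >= 0.5)
    g[i] <- rbeta(length(i), spec$gamma_shape[1], spec$gamma_shape[2])
  }
  grid$gamma <- g
  dplyr::select(grid, "participant_id", "cluster", "quantifier",
                "beta", "alpha", "gamma")
}

# RT mixture draw: fast guesses below the floor, slow lapses above the
# ceiling, otherwise a log-normal truncated to [floor, ceiling] by
# inverse-CDF so contamination fractions are exact in expectation.
draw_rt <- function(n, design) {
  u <- runif(n)
  rt <- numeric(n)
  fast <- u < design$rt_fast_rate
  slow <- u >= design$rt_fast_rate & u < design$rt_fast_rate + design$rt_slow_rate
  nominal <- !fast & !slow
  rt[fast] <- runif(sum(fast), 50, design$rt_floor - 1)
  rt[slow] <- design$rt_ceiling + 1 + rexp(sum(slow), rate = 1 / 400)
  if (any(nominal)) {
    lo <- stats::plnorm(design$rt_floor, design$rt_meanlog, design$rt_sdlog)
    hi <- stats::plnorm(design$rt_ceiling, design$rt_meanlog, design$rt_sdlog)
    rt[nominal] <- qlnorm(lo + runif(sum(nominal)) * (hi - lo),
                          design$rt_meanlog, design$rt_sdlog)
  }
  round(rt, 1)
}

draw_percents <- function(design, quantifier) {
  k <- design$trials_per_quantifier
  if (quantifier %in% design$balanced) {
    below <- sample(design$percent_domain[design$percent_domain < 50], k / 2, replace = TRUE)
    above <- sample(design$percent_domain[design$percent_domain > 50], k / 2, replace = TRUE)
    sample(c(below, above))
  } else {
    sample(design$percent_domain, k, replace = TRUE)
  }
}

#' Simulate a trial table from known parameters
#'
#' Each trial's "true" probability comes from [response_probability()]
#' applied on the increasing (flipped) convention; for negative quantifiers
#' the emitted response is then un-flipped, so the output table looks like
#' raw data and exercises the full preprocessing path.
#'
#' @param design A [experiment_design()].
#' @param params Parameter table as from [draw_population()]; must contain a
#'   row for every participant x quantifier in the design.
#' @param seed Optional integer seed.
#' @return Tibble with columns `participant_id`, `quantifier`, `percent`,
#'   `response` (1 = judged true), `rt_ms` — one row per trial,
#'   `participants x quantifiers x trials_per_quantifier` rows in total.
#' @export
simulate_trials <- function(design, params, seed = NULL) {
  stopifnot(inherits(design, "quant_design"))
  if (!is.null(seed)) set.seed(seed)
  cells <- tidyr::expand_grid(participant_id = unique(params$participant_id),
                              quantifier = design$quantifiers)
  missing <- dplyr::anti_join(cells, params, by = c("participant_id", "quantifier"))
  if (nrow(missing)) {
    stop("Missing parameter cell(s): ",
         paste(paste(missing$participant_id, missing$quantifier, sep = " / "),
               collapse = "; "), call. = FALSE)
  }
  cells <- dplyr::inner_join(cells, params, by = c("participant_id", "quantifier"))
  trials <- purrr::pmap_dfr(cells, function(participant_id, quantifier, beta,
                                            alpha, gamma, ...) {
    percent <- draw_percents(design, quantifier)
    cc <- center_percent(percent)
    p <- response_probability(cc, beta, alpha, gamma)
    y <- rbinom(length(p), 1, p)
    if (quantifier %in% negative_quantifiers()) y <- 1L - y
    tibble::tibble(participant_id = participant_id, quantifier = quantifier,
                   percent = as.integer(percent), response = as.integer(y))
  })
  trials$rt_ms <- draw_rt(nrow(trials), design)
  trials
}

#' Plant fast-guessing participants in a trial table
#'
#' Replaces a fraction of the listed participants' RTs with sub-floor fast
#' guesses (and random responses on those trials), so participant-level
#' exclusion rules can be exercised against known ground truth.
#'
#' @param trials A trial tibble.
#' @param participants Ids to contaminate.
#' @param rate Fraction of each contaminated participant's trials turned
#'   into fast guesses.
#' @param rt_floor Floor (ms) below which the planted RTs fall.
#' @param seed Optional seed.
#' @return The modified trial tibble.
#' @export
plant_fast_guessers <- function(trials, participants, rate = 0.6,
                                rt_floor = 300, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  for (p in participants) {
    rows <- which(trials$participant_id == p)
    n_fast <- ceiling(rate * length(rows))
    pick <- sample(rows, n_fast)
    trials$rt_ms[pick] <- round(runif(n_fast, 50, rt_floor - 1), 1)
    trials$response[pick] <- rbinom(n_fast, 1, 0.5)
  }
  trials
}

#' Read and write the canonical trial CSV
#'
#' Columns `participant_id`, `quantifier`, `percent`, `response` (0/1
#' integer), `rt_ms`; one header row, UTF-8. `read_trials()` validates every
#' row and reports the line number of the first malformed one.
#'
#' @param trials A trial tibble.
#' @param path File path.
#' @return `read_trials()` returns the validated tibble; `write_trials()`
#'   returns `path` invisibly.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials[, c("participant_id", "quantifier", "percent",
                              "response", "rt_ms")],
                   path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("participant_id", "quantifier", "percent", "response", "rt_ms")
  if (!all(need %in% names(raw))) {
    stop("Trial CSV must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  bad_q <- which(!raw$quantifier %in% quantifier_levels())
  if (length(bad_q)) {
    stop("Unknown quantifier ", shQuote(raw$quantifier[bad_q[1]]), " at line ",
         bad_q[1] + 1L, "; canonical labels are: ",
         paste(quantifier_levels(), collapse = ", "), call. = FALSE)
  }
  bad_p <- which(is.na(raw$percent) | raw$percent < 1 | raw$percent > 99 |
                   raw$percent == 50 | raw$percent != round(raw$percent))
  if (length(bad_p)) {
    stop("Invalid percent at line ", bad_p[1] + 1L,
         ": must be an integer in 1..99 excluding 50.", call. = FALSE)
  }
  bad_r <- which(!raw$response %in% c(0L, 1L))
  if (length(bad_r)) {
    stop("Invalid response at line ", bad_r[1] + 1L, ": must be 0 or 1.", call. = FALSE)
  }
  tibble::as_tibble(raw) |>
    dplyr::mutate(percent = as.integer(.data$percent),
                  response = as.integer(.data$response))
}

#' Write the generator's ground truth sidecar
#'
#' Serializes the drawn participant parameters and the population
#' hyperparameters to JSON so recovery analyses can compare estimates to
#' truth.
#'
#' @param params Parameter table from [draw_population()].
#' @param spec The [population_spec()] used.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(params, spec, path) {
  jsonlite::write_json(
    list(params = params, hyper = spec$hyper, gamma_shape = spec$gamma_shape),
    path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}
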