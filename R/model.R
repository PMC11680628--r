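#' quantmap: hierarchical Bayesian modelling of quantifier thresholds
#'
#' Estimates, from trial-level truth-value judgments, how individual speakers
#' map quantifiers such as *few*, *many* and *most* onto proportions. Each
#' participant-quantifier response curve is decomposed into a threshold (the
#' centered proportion at which "true" becomes the majority response), a
#' vagueness scale (how gradual the false-to-true transition is) and a
#' response-error probability (a threshold-independent lapse rate that
#' compresses the curve's asymptotes).
#'
#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
#' @importFrom generics tidy glance
#' @importFrom stats dbeta dnorm dlnorm plogis qlnorm rbeta rbinom rexp rlnorm
#'   rnorm runif sd quantile cor.test friedman.test wilcox.test pf predict
#'   as.formula var median setNames
#' @importFrom utils head
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# Canonical quantifier labels, in threshold order used for display.
QUANTIFIERS <- c("few", "fewer than half", "many", "more than half", "most")
NEGATIVE_QUANTIFIERS <- c("few", "fewer than half")

#' Canonical quantifier label sets
#'
#' `quantifier_levels()` returns the five canonical quantifier labels;
#' `negative_quantifiers()` the subset whose truth probability decreases in
#' the presented proportion (their responses are sign-flipped before
#' fitting so all curves are increasing).
#'
#' @return A character vector of lower-case labels.
#' @export
quantifier_levels <- function() QUANTIFIERS

#' @rdname quantifier_levels
#' @export
negative_quantifiers <- function() NEGATIVE_QUANTIFIERS

#' Center a presented percentage at 50
#'
#' The model's predictor is the centered proportion c = (percent - 50)/100,
#' so c = 0 corresponds to exactly half. Valid percentages are the integers
#' 1..99 excluding 50 (50 is ambiguous for *more/fewer than half* and is
#' never presented).
#'
#' @param percent Integer vector in 1..99, never 50.
#' @return Numeric vector of centered proportions in (-0.49, 0.49) \ {0}.
#' @examples
#' center_percent(c(1, 44, 99))
#' @export
center_percent <- function(percent) {
  if (any(percent != round(percent) | percent < 1 | percent > 99 | percent == 50)) {
    bad <- percent[percent != round(percent) | percent < 1 | percent > 99 | percent == 50]
    stop("`percent` must be an integer in 1..99 excluding 50; got: ",
         paste(utils::head(unique(bad), 5), collapse = ", "), call. = FALSE)
  }
  (percent - 50) / 100
}

#' @rdname center_percent
#' @param c Centered proportion as produced by `center_percent()`.
#' @export
uncenter_percent <- function(c) {
  p <- 50 + 100 * c
  as.integer(round(p))
}

#' Map a threshold to the percent scale
#'
#' Thresholds live on the centered-proportion scale; reports quote them as
#' percentages via percent = 50 + 100 * beta. A group-mean threshold of
#' -0.103 for *few*, for example, corresponds to 39.7%.
#'
#' @param beta Numeric vector of thresholds (centered-proportion scale).
#' @param digits Decimal places for reporting (default 1, as in headline
#'   tables).
#' @return Numeric vector on the percent scale.
#' @examples
#' threshold_to_percent(c(-0.103, 0.029))
#' @export
threshold_to_percent <- function(beta, digits = 1) {
  round(50 + 100 * beta, digits)
}

#' Linear predictor of the three-parameter logistic model
#'
#' mu = (c - beta) / alpha: the signed distance of the presented centered
#' proportion from the participant's threshold, in units of the vagueness
#' scale. Strictly increasing in `c`; zero exactly at threshold.
#'
#' @param c Centered proportion(s).
#' @param beta Threshold(s).
#' @param alpha Vagueness scale(s), strictly positive.
#' @return Numeric vector mu.
#' @export
linear_predictor <- function(c, beta, alpha) {
  if (any(alpha <= 0)) stop("`alpha` must be strictly positive.", call. = FALSE)
  (c - beta) / alpha
}

#' Probability of a "true" judgment
#'
#' The error-contaminated inverse-logit response function
#' pi = gamma + (1 - 2 gamma) * logistic((c - beta)/alpha).
#' The response error gamma bounds the curve in (gamma, 1 - gamma): with
#' probability gamma the participant lapses on either side of the threshold,
#' erroneously saying true below it or false above it. pi = 0.5 exactly at
#' c = beta regardless of alpha and gamma, and the curve is point-symmetric
#' about the threshold. gamma must be below 0.5 or the curve's direction is
#' not identifiable.
#'
#' @inheritParams linear_predictor
#' @param gamma Response-error probability(ies) in [0, 0.5).
#' @return Probabilities in (gamma, 1 - gamma).
#' @examples
#' response_probability(0, beta = -0.061, alpha = 0.019, gamma = 0.048)
#' @export
response_probability <- function(c, beta, alpha, gamma) {
  if (any(gamma < 0 | gamma >= 0.5)) {
    stop("`gamma` must lie in [0, 0.5): at 0.5 and above the curve's direction is not identifiable.",
         call. = FALSE)
  }
  gamma + (1 - 2 * gamma) * plogis(linear_predictor(c, beta, alpha))
}

#' Bernoulli log-likelihood of a trial table
#'
#' Sums y * log(pi) + (1 - y) * log(1 - pi) over trials, with pi from
#' [response_probability()] at each trial's centered percentage and the
#' matching participant-quantifier parameter cell. Trials are expected on
#' the increasing (flipped) response convention, i.e. after
#' [flip_negative()].
#'
#' @param trials Tibble with columns `participant_id`, `quantifier`,
#'   `percent`, `response` (0/1).
#' @param params Tibble with columns `participant_id`, `quantifier`,
#'   `beta`, `alpha`, `gamma` — one row per cell.
#' @return A single finite number (finite whenever gamma > 0).
#' @export
log_likelihood <- function(trials, params) {
  joined <- dplyr::inner_join(
    trials, params,
    by = c("participant_id", "quantifier")
  )
  if (nrow(joined) != nrow(trials)) {
    missing <- dplyr::anti_join(trials, params, by = c("participant_id", "quantifier"))
    stop("No parameter cell for: ",
         paste(unique(paste(missing$participant_id, missing$quantifier, sep = " / ")),
               collapse = "; "), call. = FALSE)
  }
  p <- response_probability(center_percent(joined$percent),
                            joined$beta, joined$alpha, joined$gamma)
  sum(ifelse(joined$response == 1, log(p), log1p(-p)))
}

# Inverse-gamma log density, shape/scale convention:
# f(x) = scale^shape / Gamma(shape) * x^(-shape-1) * exp(-scale/x), x > 0.
dinvgamma_log <- function(x, shape, scale) {
  ifelse(x > 0,
         shape * log(scale) - lgamma(shape) - (shape + 1) * log(x) - scale / x,
         -Inf)
}

#' Joint log prior density of the hierarchy
#'
#' Evaluates the model's prior at a full parameter configuration:
#' gamma_ij ~ Beta(2, 20); beta_ij ~ Normal(delta_j, sigma2_beta_j);
#' alpha_ij ~ log-normal(nu_j, sigma2_alpha_j); delta_j, nu_j ~ Normal(0, 5^2);
#' both variances ~ Inverse-gamma(shape 2, scale 0.2). The Beta(2, 20)
#' response-error prior puts most of its mass below a 20% lapse rate.
#' Any out-of-support value yields -Inf.
#'
#' @param params Tibble with columns `participant_id`, `quantifier`, `beta`,
#'   `alpha`, `gamma`.
#' @param hyper Tibble with columns `quantifier`, `delta`, `sigma2_beta`,
#'   `nu`, `sigma2_alpha`.
#' @param gamma_shape Length-2 Beta shape parameters for the response-error
#'   prior (default `c(2, 20)`).
#' @param hyper_sd Prior standard deviation of the quantifier-level means
#'   delta_j and nu_j (default 5).
#' @param invgamma Length-2 (shape, scale) of the inverse-gamma variance
#'   prior (default `c(2, 0.2)`).
#' @return A single number; `-Inf` if any parameter is outside its support.
#' @export
log_prior <- function(params, hyper, gamma_shape = c(2, 20), hyper_sd = 5,
                      invgamma = c(2, 0.2)) {
  if (any(params$gamma <= 0 | params$gamma >= 0.5) || any(params$alpha <= 0) ||
      any(hyper$sigma2_beta <= 0) || any(hyper$sigma2_alpha <= 0)) {
    return(-Inf)
  }
  joined <- dplyr::inner_join(params, hyper, by = "quantifier")
  if (nrow(joined) != nrow(params)) {
    stop("`hyper` must contain a row for every quantifier in `params`.", call. = FALSE)
  }
  cell <- sum(dbeta(joined$gamma, gamma_shape[1], gamma_shape[2], log = TRUE)) +
    sum(dnorm(joined$beta, joined$delta, sqrt(joined$sigma2_beta), log = TRUE)) +
    sum(dlnorm(joined$alpha, joined$nu, sqrt(joined$sigma2_alpha), log = TRUE))
  top <- sum(dnorm(hyper$delta, 0, hyper_sd, log = TRUE)) +
    sum(dnorm(hyper$nu, 0, hyper_sd, log = TRUE)) +
    sum(dinvgamma_log(hyper$sigma2_beta, invgamma[1], invgamma[2])) +
    sum(dinvgamma_log(hyper$sigma2_alpha, invgamma[1], invgamma[2]))
  cell + top
}

# Solve log-normal (meanlog, sdlog) from a target mean and sd on the
# natural scale; used to express vagueness hyperparameters in interpretable
# units.
lognormal_from_moments <- function(mean, sd) {
  stopifnot(mean > 0, sd > 0)
  s2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog2 = s2)
}
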