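#' Exclude participants dominated by fast guesses
#'
#' Removes, all-or-nothing, every participant for whom the fraction of
#' trials with RT below `rt_floor` is at least `fraction` (the boundary
#' counts: exactly half fast-guessed trials excludes).
#'
#' @param trials Trial tibble.
#' @param rt_floor Fast-guess boundary in ms (default 300).
#' @param fraction Exclusion fraction (default 0.5).
#' @return List with `trials` (kept rows) and `excluded` (character ids).
#' @export
exclude_fast_participants <- function(trials, rt_floor = 300, fraction = 0.5) {
  if (nrow(trials) == 0) stop("`trials` is empty.", call. = FALSE)
  frac <- trials |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(fast = mean(.data$rt_ms < rt_floor), .groups = "drop")
  excluded <- frac$participant_id[frac$fast >= fraction]
  list(trials = dplyr::filter(trials, !.data$participant_id %in% excluded),
       excluded = excluded)
}

# Per-polarity-group slope estimates: partially pooled logistic regression
# of response on the centered percentage with by-participant intercepts and
# slopes (lme4::glmer); participant slope = fixed effect + conditional mode.
# Falls back to independent per-participant glm fits if glmer fails.
polarity_slopes <- function(sub) {
  slopes <- tryCatch({
    fit <- suppressMessages(suppressWarnings(
      lme4::glmer(response ~ c + (1 + c | participant_id),
                  data = sub, family = stats::binomial,
                  control = lme4::glmerControl(calc.derivs = FALSE,
                                               check.conv.singular = "ignore"))
    ))
    re <- lme4::ranef(fit)$participant_id
    stats::setNames(lme4::fixef(fit)[["c"]] + re[, "c"], rownames(re))
  }, error = function(e) {
    by_p <- split(sub, sub$participant_id)
    vapply(by_p, function(d) {
      g <- suppressWarnings(stats::glm(response ~ c, data = d, family = stats::binomial))
      stats::coef(g)[["c"]]
    }, numeric(1))
  })
  slopes
}

#' Exclude participants violating quantifier monotonicity
#'
#' For positive quantifiers (*many*, *most*, *more than half*) the
#' probability of a "true" response must increase with the presented
#' proportion; for negative ones (*few*, *fewer than half*) it must
#' decrease. Slopes are estimated per polarity group by a partially pooled
#' logistic regression (by-participant random intercept and slope); a
#' participant is excluded when the estimated slope violates the polarity
#' sign by more than `slope_tolerance`. Participants whose responses are
#' all identical within a group carry no slope information: their slope is
#' treated as 0, they are kept and flagged.
#'
#' @param trials Trial tibble (run after fast-participant exclusion, on raw
#'   un-flipped responses).
#' @param slope_tolerance Violation must exceed this magnitude (default 0).
#' @param negative Labels treated as negative polarity.
#' @param borderline_below Slope magnitudes under this value (on the
#'   centered-proportion logit scale, where attentive responders produce
#'   slopes in the tens) are marked borderline: the sign — and hence the
#'   exclusion decision — is then essentially noise, as for a fully random
#'   responder. Default 1.
#' @return List with `trials`, `excluded` (ids), `flagged` (ids with a
#'   degenerate all-identical response pattern), `borderline` (ids whose
#'   decisive slope was near zero) and `slopes` (tibble of estimated slopes
#'   per participant and polarity group, with `borderline` and `violates`
#'   flags).
#' @export
exclude_nonmonotonic <- function(trials, slope_tolerance = 0,
                                 negative = negative_quantifiers(),
                                 borderline_below = 1) {
  groups <- list(positive = setdiff(unique(trials$quantifier), negative),
                 negative = intersect(unique(trials$quantifier), negative))
  groups <- groups[lengths(groups) > 0]
  out <- purrr::imap_dfr(groups, function(qs, pol) {
    sub <- dplyr::filter(trials, .data$quantifier %in% qs) |>
      dplyr::mutate(c = center_percent(.data$percent))
    const <- sub |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::summarise(const = dplyr::n_distinct(.data$response) == 1L,
                       .groups = "drop")
    slopes <- polarity_slopes(sub)
    tibble::tibble(participant_id = names(slopes), polarity = pol,
                   slope = unname(slopes)) |>
      dplyr::left_join(const, by = "participant_id") |>
      dplyr::mutate(slope = ifelse(.data$const, 0, .data$slope))
  })
  out <- dplyr::mutate(out,
    violates = !.data$const & dplyr::if_else(
      .data$polarity == "positive",
      .data$slope < -abs(slope_tolerance),
      .data$slope > abs(slope_tolerance)),
    borderline = !.data$const & abs(.data$slope) < borderline_below)
  excluded <- unique(out$participant_id[out$violates])
  flagged <- unique(out$participant_id[out$const])
  list(trials = dplyr::filter(trials, !.data$participant_id %in% excluded),
       excluded = excluded, flagged = flagged,
       borderline = unique(out$participant_id[out$borderline]), slopes = out)
}

#' Trial-level response-time filter
#'
#' Drops trials with RT strictly below `rt_floor` (fast guesses) or
#' strictly above `rt_ceiling` (attention drift); trials exactly at either
#' boundary are kept.
#'
#' @param trials Trial tibble.
#' @param rt_floor,rt_ceiling Bounds in ms (defaults 300 and 2500).
#' @return List with `trials` and `fractions` — named numeric
#'   (`fast`, `slow`, `total`) removed fractions.
#' @export
filter_trials <- function(trials, rt_floor = 300, rt_ceiling = 2500) {
  if (nrow(trials) == 0) {
    return(list(trials = trials, fractions = c(fast = 0, slow = 0, total = 0)))
  }
  fast <- trials$rt_ms < rt_floor
  slow <- trials$rt_ms > rt_ceiling
  list(trials = trials[!fast & !slow, , drop = FALSE],
       fractions = c(fast = mean(fast), slow = mean(slow), total = mean(fast | slow)))
}

#' Flip responses of negative quantifiers
#'
#' Negates `response` for rows whose quantifier is in `negative`, putting
#' all curves on a common increasing scale before fitting, and adds/updates
#' a logical `flipped` column. Applying the function twice restores the
#' input (an involution).
#'
#' @param trials Trial tibble.
#' @param negative Labels to flip (default *few*, *fewer than half*).
#' @return The tibble with flipped responses and a `flipped` flag.
#' @export
flip_negative <- function(trials, negative = negative_quantifiers()) {
  hit <- trials$quantifier %in% negative
  trials$response <- ifelse(hit, 1L - trials$response, trials$response)
  if (is.null(trials[["flipped"]])) trials$flipped <- FALSE
  trials$flipped <- xor(trials$flipped, hit)
  trials
}

#' Full preprocessing pipeline
#'
#' Applies, in fixed order: (1) fast-guessing participant exclusion, (2)
#' monotonicity-based participant exclusion, (3) manual participant
#' exclusion, (4) trial RT filter, (5) response flipping for negative
#' quantifiers. Returns the cleaned table plus a report of what was removed
#' at every stage.
#'
#' @param trials Raw trial tibble.
#' @param rt_floor,rt_ceiling Trial RT window in ms.
#' @param fast_fraction Participant-level fast-guess exclusion fraction.
#' @param slope_tolerance Monotonicity tolerance.
#' @param manual_exclude Character ids excluded by hand (e.g., prior
#'   participation).
#' @param negative Negative-polarity labels.
#' @return List with `trials` (clean, flipped) and `report` (class
#'   `quant_preprocess_report`).
#' @export
preprocess_trials <- function(trials, rt_floor = 300, rt_ceiling = 2500,
                              fast_fraction = 0.5, slope_tolerance = 0,
                              manual_exclude = character(),
                              negative = negative_quantifiers()) {
  n0 <- nrow(trials)
  s1 <- exclude_fast_participants(trials, rt_floor, fast_fraction)
  s2 <- exclude_nonmonotonic(s1$trials, slope_tolerance, negative)
  manual <- setdiff(intersect(manual_exclude, unique(s2$trials$participant_id)),
                    c(s1$excluded, s2$excluded))
  kept <- dplyr::filter(s2$trials, !.data$participant_id %in% manual)
  s3 <- filter_trials(kept, rt_floor, rt_ceiling)
  clean <- flip_negative(s3$trials, negative)
  report <- structure(list(
    excluded_fast_participants = s1$excluded,
    excluded_nonmonotonic_participants = s2$excluded,
    excluded_manual_participants = manual,
    flagged_participants = s2$flagged,
    trial_exclusion_fractions = as.list(s3$fractions),
    flipped_quantifiers = intersect(negative, unique(trials$quantifier)),
    rows = list(input = n0, after_participant_exclusions = nrow(kept),
                after_trial_filter = nrow(s3$trials)),
    thresholds = list(rt_floor = rt_floor, rt_ceiling = rt_ceiling,
                      fast_fraction = fast_fraction,
                      slope_tolerance = slope_tolerance)
  ), class = "quant_preprocess_report")
  list(trials = clean, report = report)
}

#' Serialize a preprocessing report to JSON
#'
#' @param report A `quant_preprocess_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_preprocess_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "list")
  invisible(path)
}

#' @export
print.quant_preprocess_report <- function(x, ...) {
  cat("Preprocessing report\n")
  cat("  fast-guess participants excluded:  ",
      length(x$excluded_fast_participants), "\n")
  cat("  non-monotone participants excluded:",
      length(x$excluded_nonmonotonic_participants), "\n")
  cat("  manually excluded participants:    ",
      length(x$excluded_manual_participants), "\n")
  fr <- x$trial_exclusion_fractions
  cat(sprintf("  trials removed: %.1f%% fast, %.1f%% slow (%.1f%% total)\n",
              100 * fr$fast, 100 * fr$slow, 100 * fr$total))
  cat("  flipped quantifiers:", paste(x$flipped_quantifiers, collapse = ", "), "\n")
  invisible(x)
}
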