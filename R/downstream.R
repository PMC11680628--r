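#' Effect-size and statistic identities for rank tests
#'
#' `kendall_w_from_chisq()` converts a Friedman chi-squared statistic into
#' Kendall's coefficient of concordance, W = chi^2 / (n (k - 1)) for n
#' participants ranking k conditions. `wilcoxon_v_max()` gives the maximal
#' value of the Wilcoxon signed-rank statistic for n pairs, n (n + 1) / 2 —
#' attained when every paired difference has the same sign.
#'
#' @param chisq Friedman chi-squared statistic.
#' @param n Number of participants (rows).
#' @param k Number of conditions (columns).
#' @return A single number.
#' @export
kendall_w_from_chisq <- function(chisq, n, k) chisq / (n * (k - 1))

#' @rdname kendall_w_from_chisq
#' @export
wilcoxon_v_max <- function(n) n * (n + 1) / 2

# Helper: wide threshold tibble -> numeric matrix with participant rownames.
as_threshold_matrix <- function(matrix) {
  stopifnot("participant_id" %in% names(matrix))
  m <- as.matrix(matrix[, setdiff(names(matrix), "participant_id"), drop = FALSE])
  rownames(m) <- matrix$participant_id
  m
}

#' Test the group-level ordering of quantifier thresholds
#'
#' A Friedman test on the within-participant ranks of the per-quantifier
#' posterior-mean thresholds, with Kendall's W = chi^2 / (n (k - 1)) as the
#' effect size, followed by all pairwise Wilcoxon signed-rank tests with
#' Bonferroni correction. The signed-rank statistic V is the sum of
#' positive ranks, so with n paired differences all of one sign V attains
#' its maximum n(n+1)/2. Exact p-values are used for n <= 25, the normal
#' approximation with continuity correction above.
#'
#' @param matrix Wide tibble from [threshold_matrix()] (`participant_id`
#'   plus one numeric column per quantifier).
#' @return List of class `quant_ordering`: `friedman` (statistic, df, p),
#'   `kendall_w`, `pairwise` (tibble: pair, V, p, p_bonferroni), `n`, `k`.
#' @export
ordering_test <- function(matrix) {
  m <- as_threshold_matrix(matrix)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("Need at least 2 participants and 2 quantifiers.", call. = FALSE)
  all_tied <- apply(m, 1, function(r) length(unique(r)) == 1)
  if (all(all_tied)) {
    # every participant ranks all quantifiers equal: no concordance signal
    fr <- list(statistic = c(`Friedman chi-squared` = 0),
               parameter = c(df = k - 1), p.value = 1)
  } else {
    fr <- friedman.test(m)
  }
  w <- unname(fr$statistic / (n * (k - 1)))
  pairs <- utils::combn(colnames(m), 2)
  pairwise <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    wt <- suppressWarnings(wilcox.test(m[, a], m[, b], paired = TRUE,
                                       exact = n <= 25, correct = TRUE))
    tibble::tibble(quantifier_1 = a, quantifier_2 = b,
                   V = unname(wt$statistic), p = wt$p.value)
  })
  pairwise$p_bonferroni <- pmin(1, pairwise$p * nrow(pairwise))
  structure(list(
    friedman = tibble::tibble(statistic = unname(fr$statistic),
                              df = unname(fr$parameter), p = fr$p.value),
    kendall_w = w, pairwise = pairwise, n = n, k = k,
    all_tied_participants = rownames(m)[all_tied]
  ), class = "quant_ordering")
}

#' @export
print.quant_ordering <- function(x, ...) {
  cat(sprintf("Friedman chi^2(%d) = %.1f, p = %.3g; Kendall's W = %.2f (n = %d)\n",
              x$friedman$df, x$friedman$statistic, x$friedman$p, x$kendall_w, x$n))
  cat("Pairwise Wilcoxon signed-rank (Bonferroni over",
      nrow(x$pairwise), "pairs):\n")
  print(x$pairwise)
  invisible(x)
}

#' @export
tidy.quant_ordering <- function(x, ...) x$pairwise

#' @export
glance.quant_ordering <- function(x, ...) {
  tibble::tibble(statistic = x$friedman$statistic, df = x$friedman$df,
                 p.value = x$friedman$p, kendall_w = x$kendall_w, n = x$n, k = x$k)
}

#' Per-participant threshold differences with credible intervals
#'
#' Propagates the posterior: for each participant, the difference of
#' threshold draws between two quantifiers is summarized by its mean and
#' central 95% credible interval. Participants are ordered by their
#' posterior-mean threshold for `order_by` (by convention, *many*).
#'
#' @param fit A `quantfit`.
#' @param pair Length-2 character vector of quantifier labels (difference =
#'   first minus second).
#' @param order_by Quantifier whose posterior-mean threshold orders the
#'   output (default "many", falling back to the first of `pair`).
#' @return Tibble: `participant_id`, `difference`, `lower`, `upper`,
#'   `order_value`, sorted by `order_value`.
#' @export
threshold_differences <- function(fit, pair, order_by = "many") {
  stopifnot(length(pair) == 2)
  if (!all(pair %in% fit$quantifiers)) {
    stop("Both quantifiers in `pair` must be in the fit.", call. = FALSE)
  }
  if (!order_by %in% fit$quantifiers) order_by <- pair[1]
  cd <- cell_draws(fit, "beta")
  get_col <- function(p, q) {
    cd$draws[, cd$map$variable[cd$map$participant_id == p & cd$map$quantifier == q]]
  }
  ord_means <- threshold_matrix(fit)[, c("participant_id", order_by)]
  purrr::map_dfr(fit$participants, function(p) {
    d <- get_col(p, pair[1]) - get_col(p, pair[2])
    tibble::tibble(participant_id = p, difference = mean(d),
                   lower = quantile(d, 0.025), upper = quantile(d, 0.975))
  }) |>
    dplyr::left_join(stats::setNames(ord_means, c("participant_id", "order_value")),
                     by = "participant_id") |>
    dplyr::arrange(.data$order_value)
}

#' Cluster participants by their threshold profiles
#'
#' Agglomerative hierarchical clustering of the participants-by-quantifiers
#' threshold matrix, using Euclidean distances and the Ward criterion on
#' squared distances (`hclust` method `ward.D2`: each merge minimizes the
#' increase in total within-cluster sum of squares, heights reported on the
#' distance scale, hence non-decreasing). The full tree is kept so cuts
#' other than `k` remain inspectable.
#'
#' @param matrix Wide threshold tibble ([threshold_matrix()]).
#' @param k Number of clusters at the reported cut (default 4).
#' @return Object of class `quant_clusters`: `tree` (hclust), `labels`
#'   (named integer vector; clusters renumbered by size, largest last),
#'   `assignments` (tibble), `summary` (cluster x quantifier mean, SD and
#'   percent equivalent), `k`.
#' @export
cluster_thresholds <- function(matrix, k = 4) {
  m <- as_threshold_matrix(matrix)
  if (k > nrow(m)) stop("`k` cannot exceed the number of participants.", call. = FALSE)
  tree <- stats::hclust(stats::dist(m, method = "euclidean"), method = "ward.D2")
  labels <- stats::cutree(tree, k = k)
  # stable renumbering: clusters ordered by size (ties by first appearance)
  sizes <- table(labels)
  new_id <- rank(sizes, ties.method = "first")
  labels <- stats::setNames(as.integer(new_id[as.character(labels)]), names(labels))
  assignments <- tibble::tibble(participant_id = names(labels),
                                cluster = unname(labels))
  summary <- tibble::as_tibble(m, rownames = "participant_id") |>
    dplyr::left_join(assignments, by = "participant_id") |>
    tidyr::pivot_longer(-c("participant_id", "cluster"),
                        names_to = "quantifier", values_to = "beta") |>
    dplyr::group_by(.data$cluster, .data$quantifier) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$beta),
                     sd = sd(.data$beta), .groups = "drop") |>
    dplyr::mutate(percent = threshold_to_percent(.data$mean))
  structure(list(tree = tree, labels = labels, assignments = assignments,
                 summary = summary, k = k),
            class = "quant_clusters")
}

#' @export
print.quant_clusters <- function(x, ...) {
  cat("Ward (ward.D2) clustering of thresholds:",
      length(x$labels), "participants, cut at k =", x$k, "\n")
  cat("Cluster sizes:", paste(table(x$labels), collapse = " / "), "\n")
  invisible(x)
}

#' @export
tidy.quant_clusters <- function(x, ...) x$summary

#' @export
glance.quant_clusters <- function(x, ...) {
  tibble::tibble(k = x$k, n = length(x$labels),
                 height_max = max(x$tree$height),
                 sizes = paste(table(x$labels), collapse = "/"))
}

# Wilks' lambda for a variable subset: det(W)/det(T) of within-group and
# total scatter matrices.
wilks_lambda <- function(m, labels, vars) {
  x <- m[, vars, drop = FALSE]
  tot <- scale(x, scale = FALSE)
  t_mat <- crossprod(tot)
  w_mat <- Reduce(`+`, lapply(split.data.frame(x, labels), function(g) {
    crossprod(scale(g, scale = FALSE))
  }))
  det(w_mat) / det(t_mat)
}

#' Stepwise variable selection by Wilks' lambda
#'
#' Greedy forward selection of the quantifier-threshold variables that
#' separate the clusters: at each step the candidate minimizing the overall
#' Wilks' lambda enters, provided its partial F-statistic is significant at
#' `alpha_enter`; selection stops when no candidate qualifies. The partial
#' F for adding a variable to p already-selected ones with g groups and n
#' observations is F = ((n - g - p) / (g - 1)) (lambda_p / lambda_{p+1} - 1)
#' on (g - 1, n - g - p) degrees of freedom.
#'
#' @param matrix Wide threshold tibble.
#' @param labels Cluster labels (named vector or tibble from
#'   [cluster_thresholds()] `$assignments`).
#' @param alpha_enter Entry significance level (default 0.05).
#' @return Tibble: `step`, `variable`, `lambda`, `F`, `p` — in entry order.
#' @export
wilks_stepwise <- function(matrix, labels, alpha_enter = 0.05) {
  m <- as_threshold_matrix(matrix)
  labels <- resolve_labels(labels, rownames(m))
  g <- length(unique(labels)); n <- nrow(m)
  if (g < 2 || any(table(labels) < 2)) {
    stop("Need >= 2 clusters with >= 2 members each.", call. = FALSE)
  }
  selected <- character(); lambda_prev <- 1
  out <- tibble::tibble(step = integer(), variable = character(),
                        lambda = numeric(), F = numeric(), p = numeric())
  repeat {
    candidates <- setdiff(colnames(m), selected)
    if (!length(candidates)) break
    p_sel <- length(selected)
    trial <- purrr::map_dfr(candidates, function(v) {
      lam <- wilks_lambda(m, labels, c(selected, v))
      df2 <- n - g - p_sel
      f <- if (df2 > 0 && lam > 0) (df2 / (g - 1)) * (lambda_prev / lam - 1) else Inf
      tibble::tibble(variable = v, lambda = lam, F = f,
                     p = if (is.finite(f)) pf(f, g - 1, df2, lower.tail = FALSE) else 0)
    })
    best <- trial[which.min(trial$lambda), ]
    if (best$p >= alpha_enter) break
    selected <- c(selected, best$variable)
    lambda_prev <- best$lambda
    out <- dplyr::bind_rows(out, dplyr::mutate(best, step = length(selected),
                                               .before = 1))
  }
  out
}

resolve_labels <- function(labels, ids) {
  if (is.data.frame(labels)) {
    labels <- stats::setNames(labels$cluster, labels$participant_id)
  }
  if (!is.null(names(labels))) labels <- labels[ids]
  as.integer(labels)
}

#' Validate cluster separability with linear discriminant analysis
#'
#' Fits an LDA (per-class means, pooled covariance, proportional priors) of
#' cluster labels on the selected threshold variables, reporting
#' resubstitution accuracy and leave-one-out cross-validated accuracy with
#' their confusion tables.
#'
#' @param matrix Wide threshold tibble.
#' @param labels Cluster labels (vector or assignments tibble).
#' @param variables Columns to use (default: all quantifier columns).
#' @return List of class `quant_lda`: `accuracy_resub`, `accuracy_loo`,
#'   `confusion_resub`, `confusion_loo`, `variables`.
#' @export
lda_validate <- function(matrix, labels, variables = NULL) {
  m <- as_threshold_matrix(matrix)
  labels <- factor(resolve_labels(labels, rownames(m)))
  if (is.null(variables)) variables <- colnames(m)
  if (!length(variables)) stop("`variables` must be non-empty.", call. = FALSE)
  x <- as.data.frame(m[, variables, drop = FALSE])
  fit <- suppressWarnings(MASS::lda(x, grouping = labels))
  pred <- predict(fit, x)$class
  loo <- suppressWarnings(MASS::lda(x, grouping = labels, CV = TRUE))$class
  structure(list(
    accuracy_resub = mean(pred == labels),
    accuracy_loo = mean(loo == labels, na.rm = TRUE),
    confusion_resub = table(truth = labels, predicted = pred),
    confusion_loo = table(truth = labels, predicted = loo),
    variables = variables
  ), class = "quant_lda")
}

#' @export
print.quant_lda <- function(x, ...) {
  cat("LDA on", paste(x$variables, collapse = ", "), "\n")
  cat(sprintf("  resubstitution accuracy: %.1f%%\n", 100 * x$accuracy_resub))
  cat(sprintf("  leave-one-out accuracy:  %.1f%%\n", 100 * x$accuracy_loo))
  invisible(x)
}

#' Correlations between model parameters within quantifiers
#'
#' Pearson correlations (with two-sided p-values, no multiplicity
#' correction) between each pair of the three cell parameters, separately
#' per quantifier — e.g., a negative threshold-vagueness correlation means
#' vaguer participants set lower thresholds. An optional robustness rerun
#' drops the ids in `exclude` first.
#'
#' @param means Long tibble of posterior means ([posterior_means()]):
#'   `participant_id`, `quantifier`, `beta`, `alpha`, `gamma`.
#' @param exclude Optional participant ids to drop (outlier sensitivity).
#' @return Tibble: `quantifier`, `pair`, `r`, `p`, `n`.
#' @export
param_correlations <- function(means, exclude = character()) {
  means <- dplyr::filter(means, !.data$participant_id %in% exclude)
  pairs <- list(c("beta", "alpha"), c("beta", "gamma"), c("alpha", "gamma"))
  purrr::map_dfr(split(means, means$quantifier), function(d) {
    if (nrow(d) < 3) stop("Need at least 3 participants per quantifier.", call. = FALSE)
    purrr::map_dfr(pairs, function(pr) {
      ct <- cor.test(d[[pr[1]]], d[[pr[2]]], method = "pearson")
      tibble::tibble(quantifier = d$quantifier[1],
                     pair = paste(pr, collapse = "-"),
                     r = unname(ct$estimate), p = ct$p.value, n = nrow(d))
    })
  })
}

#' Write downstream outputs
#'
#' `write_cluster_table()` writes the cluster x quantifier summary (mean,
#' SD, percent) as CSV; `write_test_report()` the ordering/LDA results as
#' JSON; `write_correlations()` the correlation table as CSV.
#'
#' @param clusters,ordering,lda,correlations Downstream result objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(clusters, path) {
  utils::write.csv(clusters$summary, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cluster_table
#' @param wilks Optional stepwise-selection tibble to include.
#' @export
write_test_report <- function(ordering, lda = NULL, wilks = NULL, path) {
  report <- list(
    friedman = as.list(ordering$friedman),
    kendall_w = ordering$kendall_w,
    pairwise = ordering$pairwise
  )
  if (!is.null(wilks)) report$wilks_stepwise <- wilks
  if (!is.null(lda)) {
    report$lda <- list(variables = lda$variables,
                       accuracy_resub = lda$accuracy_resub,
                       accuracy_loo = lda$accuracy_loo)
  }
  jsonlite::write_json(report, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_cluster_table
#' @export
write_correlations <- function(correlations, path) {
  utils::write.csv(correlations, path, row.names = FALSE)
  invisible(path)
}
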