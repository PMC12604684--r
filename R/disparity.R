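disparity_metric <- function(X, metric) {
  switch(metric,
    sum_of_variances = sum(apply(X, 2, var)),
    median_pairwise_distance = median(dist(X))
  )
}

#' Kinematic disparity per group, with bootstrap and Wilcoxon tests
#'
#' Measures the spread of each group in the (jointly standardised) kinematic
#' variable space — or in PCA score space — with one of the two common
#' disparity metrics, and compares groups via bootstrap: rows are resampled
#' within each group `n_boot` times, and each pair of groups is compared
#' with a two-sided Wilcoxon rank-sum test between their bootstrap
#' distributions, Bonferroni-corrected across pairs.
#'
#' @param data Data frame with the variables and the grouping column.
#' @param group Name of the grouping column (e.g. `"medium"`).
#' @param responses Variable names (default the 25 common strike variables).
#' @param metric `"sum_of_variances"` (default) or
#'   `"median_pairwise_distance"`.
#' @param n_boot Bootstrap draws per group (default 1000).
#' @param seed Integer seed.
#' @param space `"standardized"` (default) or `"pca"` (scores of
#'   [pca_kinematic()]).
#' @return A `disparity_result` list: `estimates` (per-group point
#'   estimates), `boot` (named list of bootstrap vectors), `tests`
#'   (pairwise Wilcoxon p-values, raw and Bonferroni-corrected), `metric`.
#' @export
disparity_groups <- function(data, group, responses = kin_vars_common,
                             metric = c("sum_of_variances",
                                        "median_pairwise_distance"),
                             n_boot = 1000, seed = NULL,
                             space = c("standardized", "pca")) {
  metric <- match.arg(metric)
  space <- match.arg(space)
  data <- as.data.frame(data)
  g <- base::factor(data[[group]])
  if (nlevels(g) < 2) stop_strikekin("Need at least 2 groups.", "input_error")
  tab <- table(g)
  if (any(tab < 3)) {
    stop_strikekin(sprintf("Group(s) with fewer than 3 rows: %s.",
                           paste(names(tab)[tab < 3], collapse = ", ")),
                   "insufficient_data_error")
  }
  X <- if (space == "pca") {
    pca_kinematic(data, responses)$scores
  } else {
    scale(as.matrix(data[responses]))
  }
  est <- vapply(levels(g), function(l) {
    disparity_metric(X[g == l, , drop = FALSE], metric)
  }, numeric(1))

  boot_run <- function() {
    lapply(setNames(levels(g), levels(g)), function(l) {
      Xi <- X[g == l, , drop = FALSE]
      vapply(seq_len(n_boot), function(i) {
        disparity_metric(Xi[sample.int(nrow(Xi), replace = TRUE), , drop = FALSE],
                         metric)
      }, numeric(1))
    })
  }
  boot <- if (is.null(seed)) boot_run() else withr::with_seed(seed, boot_run())

  pairs <- utils::combn(levels(g), 2, simplify = FALSE)
  tests <- do.call(rbind, lapply(pairs, function(pr) {
    p <- suppressWarnings(
      wilcox.test(boot[[pr[1]]], boot[[pr[2]]], exact = FALSE)$p.value
    )
    tibble::tibble(group_1 = pr[1], group_2 = pr[2], p_value = p)
  }))
  tests$p_adjusted <- pmin(1, tests$p_value * length(pairs))
  structure(
    list(estimates = tibble::tibble(group = levels(g), disparity = unname(est)),
         boot = boot, tests = tests, metric = metric, space = space,
         n_boot = n_boot),
    class = "disparity_result"
  )
}

#' @export
print.disparity_result <- function(x, ...) {
  cat(sprintf("<disparity_result> metric = %s (%s space)\n", x$metric, x$space))
  for (i in seq_len(nrow(x$estimates))) {
    cat(sprintf("  %s: %.3f\n", x$estimates$group[i], x$estimates$disparity[i]))
  }
  invisible(x)
}
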