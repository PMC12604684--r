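#' Correlation-matrix PCA of the kinematic space
#'
#' Standardises the selected variables to zero mean and unit variance
#' (equivalently, eigendecomposition of their correlation matrix) and
#' returns eigenvalues, percent variance, loadings, per-variable
#' contributions to each axis (squared loading as a percentage of the axis
#' total, so each axis' contributions sum to 100), and scores. Variables
#' with zero variance are dropped with a warning.
#'
#' @param data Data frame holding the variables.
#' @param responses Character vector of variable names (default: the 25
#'   common strike variables).
#' @return A `kin_pca` list: `eigenvalues`, `percent`, `loadings`,
#'   `contributions`, `scores`, `contrib_threshold` (the expected average
#'   contribution, `100 / k`), `dropped`.
#' @export
pca_kinematic <- function(data, responses = kin_vars_common) {
  data <- as.data.frame(data)
  X <- as.matrix(data[responses])
  if (nrow(X) < 3) stop_strikekin("PCA needs at least 3 rows.", "input_error")
  if (any(!is.finite(X))) {
    stop_strikekin("Missing values in the PCA block.", "input_error")
  }
  sds <- apply(X, 2, sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped)) {
    rlang::warn(sprintf("Dropping constant variable(s): %s.",
                        paste(dropped, collapse = ", ")))
    X <- X[, sds > 0, drop = FALSE]
  }
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  k <- ncol(X)
  contrib <- 100 * sweep(pc$rotation^2, 2, colSums(pc$rotation^2), "/")
  structure(
    list(eigenvalues = ev,
         percent = 100 * ev / sum(ev),
         loadings = pc$rotation,
         contributions = contrib,
         scores = pc$x,
         contrib_threshold = 100 / k,
         dropped = dropped),
    class = "kin_pca"
  )
}

#' @export
print.kin_pca <- function(x, ...) {
  cat(sprintf("<kin_pca> %d axes; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              length(x$eigenvalues), x$percent[1], x$percent[2]))
  invisible(x)
}

#' Type II ANOVA of PC1 scores on presentation and medium
#'
#' Tests the impact of the prey presentation method, the medium, and their
#' interaction on the first axis of the kinematic PCA, with type II sums of
#' squares against the full-model residual.
#'
#' @param scores Numeric vector of PC1 scores.
#' @param presentation,medium Two-level factors (or coercible).
#' @return Tibble with one row per term: `term`, `sum_sq`, `df`,
#'   `F_value`, `p_value`.
#' @export
anova_on_pc1 <- function(scores, presentation, medium) {
  presentation <- base::factor(presentation)
  medium <- base::factor(medium)
  if (nlevels(presentation) != 2 || nlevels(medium) != 2) {
    stop_strikekin("Both factors must have exactly 2 levels.", "design_error")
  }
  if (any(table(presentation, medium) == 0)) {
    stop_strikekin("Empty design cell: interaction is not estimable.",
                   "design_error")
  }
  dat <- data.frame(pc1 = scores, presentation = presentation, medium = medium)
  fit <- lm(pc1 ~ presentation * medium, data = dat)
  aov2 <- car::Anova(fit, type = 2)
  out <- tibble::tibble(
    term = rownames(aov2),
    sum_sq = aov2[["Sum Sq"]],
    df = aov2[["Df"]],
    F_value = aov2[["F value"]],
    p_value = aov2[["Pr(>F)"]]
  )
  out[out$term != "Residuals", ]
}

#' Mahalanobis-distance QQ diagnostic for multivariate normality
#'
#' Squared Mahalanobis distances of the rows (about the column means, using
#' the sample covariance) are plotted against chi-square quantiles with `k`
#' df; under multivariate normality the points fall on the identity. The
#' Pearson correlation of the point pairs is returned as a scalar summary.
#'
#' @param residuals Numeric matrix (N x k) of model residuals.
#' @param ridge If `TRUE`, regularise a singular covariance
#'   (`S + 1e-8 tr(S)/k I`); otherwise singular covariance is an error.
#' @return A list with `qq` (tibble of `theoretical`, `observed`) and
#'   `correlation`.
#' @export
multinormality_qq <- function(residuals, ridge = FALSE) {
  R <- as.matrix(residuals)
  N <- nrow(R); k <- ncol(R)
  if (N <= k && !ridge) {
    stop_strikekin("Need N > k (or ridge = TRUE) for a stable covariance.",
                   "numeric_error")
  }
  S <- cov(R)
  if (!is_spd(S)) {
    if (!ridge) {
      stop_strikekin("Singular covariance; rerun with ridge = TRUE.",
                     "numeric_error")
    }
    S <- S + 1e-8 * sum(diag(S)) / k * diag(k)
  }
  d2 <- mahalanobis(R, colMeans(R), S)
  qq <- tibble::tibble(
    theoretical = qchisq(ppoints(N), df = k),
    observed = sort(d2)
  )
  list(qq = qq, correlation = cor(qq$theoretical, qq$observed))
}
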