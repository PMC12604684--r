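# GLS machinery for a random-intercept model with known variance ratio.
# V_i = s2 (I + rho * 11') per individual block; Woodbury gives the block
# inverse in closed form, so the permutation loop is a handful of sums.
gls_t <- function(y, x, blocks, rho) {
  XtVX <- matrix(0, 2, 2)
  XtVy <- numeric(2)
  rss <- 0
  for (b in blocks) {
    yb <- y[b]; xb <- x[b]; ni <- length(b)
    w <- rho / (1 + ni * rho)
    Xb <- cbind(1, xb)
    XtVX <- XtVX + crossprod(Xb) - w * tcrossprod(colSums(Xb))
    XtVy <- XtVy + crossprod(Xb, yb) - w * colSums(Xb) * sum(yb)
  }
  beta <- solve(XtVX, XtVy)
  # scale-free t: the residual variance cancels in the permutation ranking,
  # but compute it for a proper standard error
  se2_unit <- solve(XtVX)[2, 2]
  list(beta = beta, t_unit = beta[2] / sqrt(se2_unit))
}

#' Mixed-model contrast between two conditions
#'
#' Per-variable test of a two-level condition with individuals as random
#' intercepts: `y = b0 + b1 * condition + u_individual + e`. The model is fit
#' by REML ([lme4::lmer()]); the primary p-value comes from permuting
#' condition labels within individuals (respecting the grouping structure
#' under which labels are exchangeable when the condition has no effect),
#' ranking a GLS t statistic whose variance ratio is estimated once from the
#' null model. A Wald t with `N - m - 1` residual df is also reported and is
#' approximate.
#'
#' @param y Numeric response (one kinematic variable).
#' @param condition Two-level factor (or coercible).
#' @param individual Grouping factor.
#' @param B Number of permutations (default 5000).
#' @param seed Integer seed.
#' @return One-row tibble: `estimate` (level 2 minus level 1), `se`,
#'   `t_wald`, `df_approx`, `p_wald`, `p_perm`, `B`, `sd_individual`,
#'   `sd_residual`.
#' @export
lmm_contrast <- function(y, condition, individual, B = 5000, seed = NULL) {
  condition <- base::factor(condition)
  individual <- base::factor(individual)
  if (nlevels(condition) != 2) {
    stop_strikekin("`condition` must have exactly 2 levels present.", "design_error")
  }
  if (nlevels(individual) < 2) {
    stop_strikekin("Need at least 2 individuals.", "design_error")
  }
  if (length(y) != length(condition) || length(y) != length(individual)) {
    stop_strikekin("Input lengths differ.", "input_error")
  }
  within_var <- tapply(as.integer(condition), individual,
                       function(z) length(unique(z)) > 1)
  if (!any(within_var)) {
    stop_strikekin(
      "Condition is constant within every individual: contrast inestimable
       separately from the individual effects.", "inestimable_error")
  }

  dat <- data.frame(y = y, condition = condition, individual = individual)
  fit <- suppressMessages(lme4::lmer(
    y ~ condition + (1 | individual), data = dat, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore")
  ))
  b <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))[2]
  est <- unname(b[2])
  t_wald <- est / se
  df_approx <- length(y) - nlevels(individual) - 1
  p_wald <- 2 * pt(abs(t_wald), df_approx, lower.tail = FALSE)

  # variance ratio from the null model (no condition term)
  fit0 <- suppressMessages(lme4::lmer(
    y ~ 1 + (1 | individual), data = dat, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore")
  ))
  vc <- as.data.frame(lme4::VarCorr(fit0))
  s2_b <- vc$vcov[vc$grp == "individual"]
  s2_e <- vc$vcov[vc$grp == "Residual"]
  rho <- if (s2_e > 0) s2_b / s2_e else 0

  blocks <- split(seq_along(y), individual)
  x01 <- as.numeric(condition) - 1
  obs <- gls_t(y, x01, blocks, rho)
  perm <- function() {
    exceed <- 0L
    for (i in seq_len(B)) {
      xp <- x01
      for (b in blocks) xp[b] <- x01[b][sample.int(length(b))]
      tp <- gls_t(y, xp, blocks, rho)$t_unit
      if (abs(tp) >= abs(obs$t_unit) - 1e-12) exceed <- exceed + 1L
    }
    (exceed + 1) / (B + 1)
  }
  p_perm <- if (is.null(seed)) perm() else withr::with_seed(seed, perm())

  vc1 <- as.data.frame(lme4::VarCorr(fit))
  tibble::tibble(
    estimate = est, se = unname(se), t_wald = unname(t_wald),
    df_approx = df_approx, p_wald = unname(p_wald), p_perm = p_perm,
    B = as.integer(B),
    sd_individual = sqrt(vc1$vcov[vc1$grp == "individual"]),
    sd_residual = sqrt(vc1$vcov[vc1$grp == "Residual"])
  )
}
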