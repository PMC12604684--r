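rand_design <- function(n = 36, k = 1, m_ind = 3, seed = 1) {
  withr::with_seed(seed, {
    d <- data.frame(
      presentation = sample(c("substrate", "tweezers"), n, replace = TRUE),
      individual_id = sample(paste0("I", seq_len(m_ind)), n, replace = TRUE)
    )
    for (j in seq_len(k)) d[[paste0("y", j)]] <- rnorm(n)
    d
  })
}

test_that("univariate Pillai tests reduce to type II ANOVA F tests", {
  for (seed in 1:3) {
    d <- rand_design(seed = seed)
    res <- manova_typeII(d, "y1", c("presentation", "individual_id"),
                         mode = "parametric")
    fit <- lm(y1 ~ presentation * individual_id, d)
    oracle <- car::Anova(fit, type = 2)
    expect_equal(res$p_value, oracle[["Pr(>F)"]][1:3], tolerance = 1e-8)
  }
})

test_that("permutation p-values are bounded, seeded and rank-robust", {
  d <- rand_design(k = 4, seed = 7)
  ys <- paste0("y", 1:4)
  r1 <- manova_typeII(d, ys, c("presentation", "individual_id"),
                      B = 99, seed = 101)
  r2 <- manova_typeII(d, ys, c("presentation", "individual_id"),
                      B = 99, seed = 101)
  expect_identical(r1$p_value, r2$p_value)
  expect_true(all(r1$p_value >= 1 / 100 & r1$p_value <= 1))

  # duplicating the response block (rank-deficient E -> ridge) barely moves p
  d2 <- d
  for (y in ys) d2[[paste0(y, "_dup")]] <- d[[y]]
  r3 <- manova_typeII(d2, c(ys, paste0(ys, "_dup")),
                      c("presentation", "individual_id"), B = 199, seed = 101)
  r4 <- manova_typeII(d, ys, c("presentation", "individual_id"),
                      B = 199, seed = 101)
  expect_gt(r3$ridge_delta[1], 0)
  expect_lt(max(abs(r3$p_value - r4$p_value)), 0.12)
})

test_that("Pillai is invariant under invertible response reparameterisation", {
  d <- rand_design(k = 3, seed = 5)
  ys <- paste0("y", 1:3)
  withr::with_seed(6, T_ <- matrix(rnorm(9), 3, 3) + diag(3))
  Yt <- as.matrix(d[ys]) %*% T_
  d2 <- d
  d2[ys] <- Yt
  r1 <- manova_typeII(d, ys, c("presentation", "individual_id"), mode = "parametric")
  r2 <- manova_typeII(d2, ys, c("presentation", "individual_id"), mode = "parametric")
  expect_equal(r1$pillai, r2$pillai, tolerance = 1e-8)
})

test_that("aliased factors are rejected", {
  d <- rand_design(seed = 2)
  d$copy <- d$presentation
  expect_error(manova_typeII(d, "y1", c("presentation", "copy")),
               class = "strikekin_design_error")
})

test_that("pairwise post-hoc tests enumerate pairs and find the odd individual out", {
  withr::with_seed(13, {
    n_per <- 8; m <- 5
    d <- data.frame(
      individual_id = rep(paste0("I", 1:m), each = n_per),
      presentation = rep(c("substrate", "tweezers"), m * n_per / 2)
    )
    for (j in 1:3) d[[paste0("y", j)]] <- rnorm(nrow(d))
    sel <- d$individual_id == "I3"
    d[sel, paste0("y", 1:3)] <- d[sel, paste0("y", 1:3)] + 3
  })
  res <- pairwise_glh(d, paste0("y", 1:3), "individual_id", "presentation",
                      mode = "parametric")
  expect_equal(nrow(res), 10)
  involved <- res$level_1 == "I3" | res$level_2 == "I3"
  expect_equal(sort(res$p_value)[1:4], sort(res$p_value[involved])[1:4])
  expect_true(all(res$p_adjusted >= res$p_value))

  # a two-level factor gives the single pair, matching the one-factor test
  d2 <- rand_design(k = 2, seed = 3)
  pw <- pairwise_glh(d2, c("y1", "y2"), "presentation", "individual_id",
                     mode = "parametric")
  mv <- manova_typeII(d2, c("y1", "y2"), c("presentation", "individual_id"),
                      interaction = FALSE, mode = "parametric")
  expect_equal(nrow(pw), 1)
  expect_equal(pw$pillai, mv$pillai[mv$term == "presentation"], tolerance = 1e-10)

  d2$individual_id[1] <- "lonely"
  expect_error(pairwise_glh(d2, c("y1", "y2"), "individual_id", "presentation"),
               class = "strikekin_insufficient_data_error")
})

test_that("lmm_contrast reduces to the mean difference without individual effects", {
  withr::with_seed(17, {
    n <- 60
    cond <- rep(c("substrate", "tweezers"), each = n / 2)
    ind <- rep(paste0("I", 1:5), times = n / 5)
    y <- 0.4 * (cond == "tweezers") + rnorm(n)  # no individual effect
    res <- lmm_contrast(y, cond, ind, B = 199, seed = 23)
    diff_means <- mean(y[cond == "tweezers"]) - mean(y[cond == "substrate"])
    expect_equal(res$estimate, diff_means, tolerance = 0.05)
    # location shift moves nothing but the intercept
    res2 <- lmm_contrast(y + 100, cond, ind, B = 199, seed = 23)
    expect_equal(res2$estimate, res$estimate, tolerance = 1e-6)
    expect_equal(res2$p_perm, res$p_perm)
    expect_equal(sign(res$estimate), sign(res$t_wald))
  })
})

test_that("lmm_contrast validates its design", {
  y <- rnorm(12)
  ind <- rep(c("a", "b"), each = 6)
  cond_between <- rep(c("substrate", "tweezers"), each = 6) # aliased with ind
  expect_error(lmm_contrast(y, cond_between, ind, B = 19),
               class = "strikekin_inestimable_error")
  expect_error(lmm_contrast(y, rep("substrate", 12), ind, B = 19),
               class = "strikekin_design_error")
})

test_that("correlation-matrix PCA reports variance shares and contributions", {
  withr::with_seed(29, {
    n <- 80
    z <- rnorm(n)
    d <- data.frame(a = z, b = z, c = rnorm(n), d = rnorm(n), e = rnorm(n))
  })
  pc <- pca_kinematic(d, c("a", "b", "c", "d", "e"))
  expect_equal(sum(pc$percent), 100)
  expect_true(all(diff(pc$eigenvalues) <= 1e-12))
  expect_equal(colSums(pc$contributions), rep(100, 5),
               ignore_attr = TRUE, tolerance = 1e-9)
  # the duplicated pair shares PC1 equally
  expect_equal(pc$contributions["a", 1], pc$contributions["b", 1], tolerance = 1e-6)
  expect_gt(pc$contributions["a", 1] + pc$contributions["b", 1], 90)
  expect_equal(pc$contrib_threshold, 20)

  d$const <- 1
  expect_warning(pca_kinematic(d, c("a", "b", "const")), "constant")
  expect_error(pca_kinematic(d[1:2, ], c("a", "b")), class = "strikekin_input_error")
})

test_that("the PC1 ANOVA isolates a constructed medium signal", {
  withr::with_seed(31, {
    n <- 60
    medium <- sample(c("aquatic", "terrestrial"), n, replace = TRUE)
    pres <- sample(c("substrate", "tweezers"), n, replace = TRUE)
    scores <- as.numeric(medium == "aquatic") + rnorm(n, 0, 1e-3)
  })
  res <- anova_on_pc1(scores, pres, medium)
  expect_lt(res$p_value[res$term == "medium"], 1e-10)
  expect_gt(res$p_value[res$term == "presentation"], 0.1)
  # F is scale-free
  res3 <- anova_on_pc1(scores * 3, pres, medium)
  expect_equal(res$F_value, res3$F_value, tolerance = 1e-9)
})

test_that("disparity metrics scale as expected and identical groups collapse to zero", {
  sum_var <- function(X) sum(apply(X, 2, var))
  withr::with_seed(37, A <- matrix(rnorm(60), 20, 3))
  B <- sweep(sweep(A, 2, colMeans(A)), 2, colMeans(A), function(d, m) 2 * d)
  B <- sweep(B, 2, colMeans(A), "+")
  mA <- median(dist(A)); mB <- median(dist(B))
  expect_equal(mB, 2 * mA, tolerance = 1e-9)

  d <- as.data.frame(rbind(A, A[rep(1, 5), ]))
  names(d) <- c("v1", "v2", "v3")
  d$grp <- rep(c("spread", "point"), c(20, 5))
  res <- disparity_groups(d, "grp", c("v1", "v2", "v3"), n_boot = 50, seed = 2)
  expect_equal(res$estimates$disparity[res$estimates$group == "point"], 0)
  expect_gt(res$estimates$disparity[res$estimates$group == "spread"], 0)
  expect_true(all(res$tests$p_adjusted >= res$tests$p_value))
  d$grp[1:23] <- "spread"
  expect_error(disparity_groups(d, "grp", c("v1", "v2", "v3")),
               class = "strikekin_insufficient_data_error")
})

test_that("the Mahalanobis QQ diagnostic separates normal from heavy tails", {
  withr::with_seed(41, {
    R_norm <- matrix(rnorm(2000 * 3), ncol = 3)
    R_t <- matrix(rt(2000 * 3, df = 2), ncol = 3)
  })
  qn <- multinormality_qq(R_norm)
  qt <- multinormality_qq(R_t)
  expect_gt(qn$correlation, 0.99)
  expect_lt(qt$correlation, qn$correlation)
  # k = 1 reduces to a chi-square(1) plot of squared z-scores
  q1 <- multinormality_qq(R_norm[, 1, drop = FALSE])
  z2 <- sort(scale(R_norm[, 1])[, 1]^2)
  expect_equal(q1$qq$observed, z2, tolerance = 1e-9)
  expect_error(multinormality_qq(matrix(rnorm(6), 2, 3)),
               class = "strikekin_numeric_error")
})
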