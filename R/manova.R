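# Residual SSCP machinery -----------------------------------------------------
#
# For a design matrix X and response block Y, the residual SSCP is
# Y'Y - (Q'Y)'(Q'Y) with Q an orthonormal basis of col(X). Bases are
# precomputed once so that permutation loops cost only two matrix products.

qr_basis <- function(X) {
  qrd <- qr(X)
  list(Q = qr.Q(qrd)[, seq_len(qrd$rank), drop = FALSE], rank = qrd$rank)
}

resid_sscp <- function(Y, basis) {
  QtY <- crossprod(basis$Q, Y)
  crossprod(Y) - crossprod(QtY)
}

# minimal ridge (as a fraction of mean eigenvalue) making E well-conditioned
ridge_delta <- function(E, k, df_res) {
  needed <- k >= df_res || !is_spd(E)
  if (!needed) return(0)
  for (delta in 10^seq(-8, 0)) {
    Er <- E + delta * sum(diag(E)) / k * diag(k)
    if (is_spd(Er)) return(delta)
  }
  1
}

is_spd <- function(M) {
  ev <- tryCatch(eigen(M, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) NA)
  all(is.finite(ev)) && min(ev) > max(ev) * 1e-10 && min(ev) > 0
}

pillai_trace <- function(H, E, delta, k) {
  Er <- if (delta > 0) E + delta * sum(diag(E)) / k * diag(k) else E
  sum(diag(solve(H + Er, H)))
}

pillai_F <- function(V, k, q, df_res) {
  s <- min(k, q)
  m <- (abs(k - q) - 1) / 2
  nn <- (df_res - k - 1) / 2
  df1 <- s * (2 * m + s + 1)
  df2 <- s * (2 * nn + s + 1)
  if (df2 <= 0) return(c(F = NA_real_, df1 = df1, df2 = df2, p = NA_real_))
  Fv <- (df2 / df1) * (V / (s - V))
  c(F = Fv, df1 = df1, df2 = df2, p = pf(Fv, df1, df2, lower.tail = FALSE))
}

#' Type II MANOVA with Pillai's trace, parametric or permutation-based
#'
#' Tests each term of a two-factor design (two main effects and optionally
#' their interaction) against a multivariate response block. Hypothesis SSCP
#' matrices follow type II marginality: a main effect is the SSCP gained by
#' adding it to the other main effect, the interaction the SSCP gained over
#' both main effects. The error SSCP comes from the full model and is
#' ridge-regularised (`E + delta * tr(E)/k * I`, with the smallest power of
#' ten making `E` positive definite) whenever the response dimension reaches
#' the residual df or `E` is singular — which is how near-high-dimensional
#' kinematic blocks (25-32 variables on 50-odd strikes) stay testable.
#'
#' Parametric p-values use the standard Pillai-to-F approximation.
#' Permutation p-values use Freedman-Lane residual permutation: for each
#' term, residuals of the reduced model (without that term) are row-permuted
#' and added back to the reduced-model fit, and Pillai's trace is recomputed
#' identically; `p = (#{V* >= V} + 1) / (B + 1)`.
#'
#' @param data Data frame with the response variables and factor columns.
#' @param responses Character vector of response column names.
#' @param factors Character vector of exactly two factor column names.
#' @param interaction Include the interaction term (default TRUE).
#' @param mode `"permutation"` (default) or `"parametric"`.
#' @param B Number of permutations (default 5000).
#' @param seed Integer seed for the permutation draw.
#' @return A tibble with one row per term: `term`, `df`, `pillai`,
#'   `p_value`, `mode`, `ridge_delta`, `B`.
#' @export
manova_typeII <- function(data, responses, factors, interaction = TRUE,
                          mode = c("permutation", "parametric"), B = 5000,
                          seed = NULL) {
  mode <- match.arg(mode)
  data <- as.data.frame(data)
  if (length(factors) != 2) {
    stop_strikekin("Exactly two factors are required.", "design_error")
  }
  Y <- as.matrix(data[responses])
  if (any(!is.finite(Y))) {
    stop_strikekin("Missing or non-finite responses: validate the table first.",
                   "design_error")
  }
  fA <- factor(data[[factors[1]]]); fB <- factor(data[[factors[2]]])
  k <- ncol(Y); N <- nrow(Y)

  d <- data.frame(A = fA, B = fB)
  X1 <- model.matrix(~ 1, d)
  XA <- model.matrix(~ A, d)
  XB <- model.matrix(~ B, d)
  XAB <- model.matrix(~ A + B, d)
  Xfull <- if (interaction) model.matrix(~ A * B, d) else XAB
  bases <- lapply(list(X1 = X1, XA = XA, XB = XB, XAB = XAB, Xfull = Xfull),
                  qr_basis)
  if (bases$Xfull$rank < ncol(Xfull)) {
    stop_strikekin("Aliased design: a factor is confounded with the other.",
                   "design_error")
  }
  df_res <- N - bases$Xfull$rank
  if (mode == "parametric" && df_res <= 0) {
    stop_strikekin("No residual df for parametric tests.", "design_error")
  }

  terms <- list(
    list(term = factors[1], red = "XB", aug = "XAB"),
    list(term = factors[2], red = "XA", aug = "XAB")
  )
  if (interaction) {
    terms <- c(terms, list(list(term = paste(factors, collapse = ":"),
                                red = "XAB", aug = "Xfull")))
  }

  E <- resid_sscp(Y, bases$Xfull)
  delta <- ridge_delta(E, k, df_res)

  stat_for <- function(Yx, tm) {
    H <- resid_sscp(Yx, bases[[tm$red]]) - resid_sscp(Yx, bases[[tm$aug]])
    Ex <- resid_sscp(Yx, bases$Xfull)
    pillai_trace(H, Ex, delta, k)
  }

  run <- function() {
    rows <- lapply(terms, function(tm) {
      q <- bases[[tm$aug]]$rank - bases[[tm$red]]$rank
      V <- stat_for(Y, tm)
      if (mode == "parametric") {
        pf_ <- pillai_F(V, k, q, df_res)
        tibble::tibble(term = tm$term, df = q, pillai = V,
                       p_value = pf_[["p"]], mode = mode,
                       ridge_delta = delta, B = NA_integer_)
      } else {
        fit_red <- bases[[tm$red]]$Q %*% crossprod(bases[[tm$red]]$Q, Y)
        R_red <- Y - fit_red
        exceed <- 0L
        for (b in seq_len(B)) {
          Yb <- fit_red + R_red[sample.int(N), , drop = FALSE]
          if (stat_for(Yb, tm) >= V - 1e-12) exceed <- exceed + 1L
        }
        tibble::tibble(term = tm$term, df = q, pillai = V,
                       p_value = (exceed + 1) / (B + 1), mode = mode,
                       ridge_delta = delta, B = as.integer(B))
      }
    })
    do.call(rbind, rows)
  }
  out <- if (is.null(seed) || mode == "parametric") run() else withr::with_seed(seed, run())
  structure(out, class = c("manova_typeII", class(out)),
            df_res = df_res, k = k, N = N)
}

#' Pairwise post-hoc Pillai tests on one factor
#'
#' One type II Pillai test per pair of levels of `factor`, restricted to the
#' rows of that pair (the other factor is retained as a main effect where it
#' still varies), with multiplicity correction across pairs.
#'
#' @inheritParams manova_typeII
#' @param factor Name of the factor whose levels are compared.
#' @param other Name of the retained factor.
#' @param correction `"none"`, `"holm"` or `"bonferroni"` (default).
#' @return A tibble with one row per level pair.
#' @export
pairwise_glh <- function(data, responses, factor, other,
                         mode = c("permutation", "parametric"), B = 5000,
                         seed = NULL, correction = c("bonferroni", "holm", "none")) {
  mode <- match.arg(mode)
  correction <- match.arg(correction)
  data <- as.data.frame(data)
  f <- base::factor(data[[factor]])
  levs <- levels(f)
  if (length(levs) < 2) {
    stop_strikekin("`factor` needs at least 2 levels.", "design_error")
  }
  tab <- table(f)
  if (any(tab < 2)) {
    stop_strikekin(
      sprintf("Level(s) with fewer than 2 observations: %s.",
              paste(names(tab)[tab < 2], collapse = ", ")),
      "insufficient_data_error"
    )
  }
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  rows <- lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    sub <- data[f %in% pr, , drop = FALSE]
    sub[[factor]] <- droplevels(base::factor(sub[[factor]]))
    keep_other <- length(unique(sub[[other]])) > 1
    res <- if (keep_other) {
      manova_typeII(sub, responses, c(factor, other), interaction = FALSE,
                    mode = mode, B = B,
                    seed = if (is.null(seed)) NULL else seed + i)
    } else {
      one_factor_pillai(sub, responses, factor, mode, B,
                        if (is.null(seed)) NULL else seed + i)
    }
    row <- res[res$term == factor, ]
    tibble::tibble(level_1 = pr[1], level_2 = pr[2], df = row$df,
                   pillai = row$pillai, p_value = row$p_value)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- p.adjust(out$p_value, method = correction)
  out
}

# single-factor Pillai (used by pairwise_glh when the retained factor
# degenerates to one level inside a pair's rows)
one_factor_pillai <- function(data, responses, factor, mode, B, seed) {
  Y <- as.matrix(data[responses])
  f <- base::factor(data[[factor]])
  k <- ncol(Y); N <- nrow(Y)
  b1 <- qr_basis(model.matrix(~ 1, data.frame(A = f)))
  bf <- qr_basis(model.matrix(~ A, data.frame(A = f)))
  df_res <- N - bf$rank
  q <- bf$rank - b1$rank
  E <- resid_sscp(Y, bf)
  delta <- ridge_delta(E, k, df_res)
  stat <- function(Yx) {
    H <- resid_sscp(Yx, b1) - resid_sscp(Yx, bf)
    pillai_trace(H, resid_sscp(Yx, bf), delta, k)
  }
  V <- stat(Y)
  if (mode == "parametric") {
    p <- pillai_F(V, k, q, df_res)[["p"]]
    return(tibble::tibble(term = factor, df = q, pillai = V, p_value = p))
  }
  fit1 <- b1$Q %*% crossprod(b1$Q, Y)
  R1 <- Y - fit1
  run <- function() {
    exceed <- 0L
    for (b in seq_len(B)) {
      if (stat(fit1 + R1[sample.int(N), , drop = FALSE]) >= V - 1e-12) {
        exceed <- exceed + 1L
      }
    }
    (exceed + 1) / (B + 1)
  }
  p <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  tibble::tibble(term = factor, df = q, pillai = V, p_value = p)
}
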