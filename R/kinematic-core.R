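#' Cubic smoothing spline with a target effective df
#'
#' Fits the cubic smoothing spline minimising `RSS + lambda * integral(f'')^2`
#' with the penalty chosen so that the trace of the linear smoother matrix
#' (the effective degrees of freedom) matches `target_df` to within 0.1.
#' All data points are used as knots so that the full df range `(2, n)` is
#' reachable. For short clips the target is capped at `n - 4` with a warning:
#' the smoother trace cannot usefully approach the basis size.
#'
#' @param x Numeric signal (one coordinate series).
#' @param t Strictly increasing, equispaced time vector, same length as `x`.
#' @param target_df Target effective degrees of freedom, in `[2, n - 1]`.
#'   Default 80, the conventional value for 1000 fps feeding sequences.
#'
#' @return A `smoothed_track`: list with `t`, `x_s` (fitted values),
#'   `effective_df`, `target_df`, `lambda`.
#' @export
smooth_track <- function(x, t, target_df = 80) {
  n <- length(x)
  if (n < 4) stop_strikekin("Need at least 4 samples to smooth.", "input_error")
  if (length(t) != n) stop_strikekin("`x` and `t` lengths differ.", "input_error")
  if (!is_equispaced(t)) {
    stop_strikekin("`t` must be strictly increasing and equispaced.", "input_error")
  }
  if (target_df < 2 || target_df > n - 1) {
    stop_strikekin(sprintf("`target_df` must be in [2, n - 1] = [2, %d].", n - 1),
                   "input_error")
  }
  if (target_df > n - 4) {
    rlang::warn(sprintf(
      "target_df = %g exceeds n - 4 = %d; capping at %d.", target_df, n - 4, n - 4
    ), class = "strikekin_df_capped")
    target_df <- n - 4
  }
  fit <- smooth.spline(t, x, df = target_df, all.knots = TRUE,
                       keep.data = FALSE)
  if (abs(fit$df - target_df) > 0.1) {
    stop_strikekin(
      sprintf("Smoother df %.3f did not converge to target %.3f (lambda = %.3g).",
              fit$df, target_df, fit$lambda),
      "numeric_error"
    )
  }
  structure(
    list(t = t, x_s = predict(fit, t)$y, effective_df = fit$df,
         target_df = target_df, lambda = fit$lambda),
    class = "smoothed_track"
  )
}

#' Euclidean distance between two point series
#'
#' `d = sqrt((x_A - x_B)^2 + (y_A - y_B)^2)`, frame by frame.
#'
#' @param a,b Data frames or matrices with `x` and `y` columns, equal length.
#' @return Numeric vector of non-negative distances.
#' @export
euclidean_distance <- function(a, b) {
  a <- as.data.frame(a); b <- as.data.frame(b)
  if (nrow(a) != nrow(b)) {
    stop_strikekin("Point series lengths differ.", "input_error")
  }
  sqrt((a$x - b$x)^2 + (a$y - b$y)^2)
}

#' Three-point angle at a vertex (law of cosines)
#'
#' The angle at `vertex` subtended by `a` and `c`, via
#' `acos((d_vc^2 + d_va^2 - d_ac^2) / (2 d_vc d_va))`, reported in degrees in
#' `[0, 180]`. The acos argument is clamped to `[-1, 1]` to absorb rounding.
#'
#' @param a,vertex,c Point series (`x`, `y` columns), equal length.
#' @param eps Degeneracy floor (cm): the vertex must be at least this far
#'   from both arm endpoints at every frame.
#' @return Numeric vector of angles in degrees.
#' @export
alkashi_angle <- function(a, vertex, c, eps = 1e-9) {
  d_va <- euclidean_distance(vertex, a)
  d_vc <- euclidean_distance(vertex, c)
  d_ac <- euclidean_distance(a, c)
  degen <- which(d_va <= eps | d_vc <= eps)
  if (length(degen)) {
    stop_strikekin(
      sprintf("Degenerate triangle: vertex coincides with an arm endpoint at frame %d.",
              degen[1] - 1),
      "geometry_error"
    )
  }
  arg <- (d_vc^2 + d_va^2 - d_ac^2) / (2 * d_vc * d_va)
  deg(acos(pmin(1, pmax(-1, arg))))
}

#' Forward-difference derivative
#'
#' First forward difference divided by the sampling interval. The output has
#' `n - 1` samples, timestamped at the left endpoint of each interval; apply
#' twice for a second derivative.
#'
#' @param signal Numeric vector, length `n >= 2`.
#' @param t Equispaced time vector matching `signal`.
#' @return A list with `t` (left endpoints) and `value` (derivative).
#' @export
differentiate <- function(signal, t) {
  n <- length(signal)
  if (n < 2) stop_strikekin("Need at least 2 samples to differentiate.", "input_error")
  if (length(t) != n) stop_strikekin("`signal` and `t` lengths differ.", "input_error")
  if (!is_equispaced(t)) {
    stop_strikekin("`t` must be strictly increasing and equispaced.", "input_error")
  }
  list(t = t[-n], value = diff(signal) / diff(t))
}

profile_landmarks <- function(medium) {
  base <- c("e", "uj", "lj", "jj", "hd1", "hd2", "sh")
  if (medium == "terrestrial") c(base, "tg") else base
}

#' Build the kinematic profile of a strike
#'
#' Smooths the calibrated landmark coordinates (each coordinate separately,
#' cubic smoothing spline at `target_df`), then computes the primary signals
#' frame by frame from the smoothed coordinates, then their forward-difference
#' first and second derivatives — in that order. Signals: gape distance
#' `d(uj, lj)` and gape angle `angle(uj, jj, lj)`; hyoid-to-jaw-joint
#' distances `d(hd1, jj)` and `d(hd2, jj)`; head angle `angle(uj, e, sh)`;
#' and, for terrestrial strikes, tongue distance `d(tg, jj)`.
#'
#' @param series A calibrated [landmark_series()].
#' @param medium `"aquatic"` or `"terrestrial"` (the tongue pad `tg` is
#'   required iff terrestrial).
#' @param target_df Smoothing target effective df (see [smooth_track()]).
#' @return A `kinematic_profile`: list with `signals`, `vel`, `acc` tibbles
#'   (derivatives are one and two samples shorter, left-aligned in time),
#'   plus `video_id`, `medium`, `dt`, `effective_df`.
#' @export
build_profile <- function(series, medium = c("aquatic", "terrestrial"),
                          target_df = 80) {
  stopifnot(inherits(series, "landmark_series"))
  medium <- match.arg(medium)
  if (!isTRUE(series$calibrated)) {
    stop_strikekin("Series must be calibrated (cm, s) before profiling.",
                   "configuration_error")
  }
  need <- profile_landmarks(medium)
  miss <- setdiff(need, series$landmarks)
  if (length(miss)) {
    stop_strikekin(sprintf("Missing required landmark(s): %s.",
                           paste(miss, collapse = ", ")), "configuration_error")
  }
  t <- series$t
  sm <- list()
  eff <- c()
  for (lm in need) {
    df <- series$coords[[lm]]
    fx <- smooth_track(df$x, t, target_df)
    fy <- smooth_track(df$y, t, target_df)
    sm[[lm]] <- data.frame(x = fx$x_s, y = fy$x_s)
    eff[lm] <- (fx$effective_df + fy$effective_df) / 2
  }
  signals <- tibble::tibble(
    t = t,
    gape_dist  = euclidean_distance(sm$uj, sm$lj),
    gape_angle = alkashi_angle(sm$uj, sm$jj, sm$lj),
    hd1_dist   = euclidean_distance(sm$hd1, sm$jj),
    hd2_dist   = euclidean_distance(sm$hd2, sm$jj),
    head_angle = alkashi_angle(sm$uj, sm$e, sm$sh)
  )
  if (medium == "terrestrial") {
    signals$tongue_dist <- euclidean_distance(sm$tg, sm$jj)
  }
  sig_names <- setdiff(names(signals), "t")
  d1 <- lapply(signals[sig_names], function(s) differentiate(s, t)$value)
  t1 <- t[-length(t)]
  d2 <- lapply(d1, function(v) differentiate(v, t1)$value)
  structure(
    list(video_id = series$video_id, medium = medium,
         signals = signals,
         vel = tibble::as_tibble(c(list(t = t1), d1)),
         acc = tibble::as_tibble(c(list(t = t1[-length(t1)]), d2)),
         dt = t[2] - t[1],
         effective_df = eff, target_df = target_df),
    class = "kinematic_profile"
  )
}

#' @export
print.kinematic_profile <- function(x, ...) {
  cat(sprintf("<kinematic_profile> %s (%s): %d frames, dt = %g s, signals: %s\n",
              x$video_id, x$medium, nrow(x$signals), x$dt,
              paste(setdiff(names(x$signals), "t"), collapse = ", ")))
  invisible(x)
}

#' Export a kinematic profile as a tidy table
#'
#' @param profile A `kinematic_profile`.
#' @return A tibble with the smoothed signals and their first (`v_`) and
#'   second (`a_`) derivatives, padded with `NA` at the trailing frames where
#'   forward differences are undefined.
#' @export
profile_table <- function(profile) {
  stopifnot(inherits(profile, "kinematic_profile"))
  n <- nrow(profile$signals)
  out <- profile$signals
  for (s in setdiff(names(profile$vel), "t")) {
    out[[paste0("v_", s)]] <- c(profile$vel[[s]], NA_real_)
    out[[paste0("a_", s)]] <- c(profile$acc[[s]], NA_real_, NA_real_)
  }
  out
}
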