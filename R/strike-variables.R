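#' Canonical strike-variable names
#'
#' `kin_vars_common` are the 25 variables defined for every strike (gape,
#' hyoid and whole-event variables); `kin_vars_tongue` are the 7 additional
#' tongue variables recorded for terrestrial strikes. `HA0` (head angle at
#' strike onset) is reported alongside both sets.
#'
#' @format Character vectors.
#' @export
kin_vars_common <- c(
  "MG", "TMG", "MGA", "DG", "MSGO", "MAGO", "MSGC", "MAGC",
  "Mhd1", "TMhd1", "Dhd1", "MSDhd1", "MADhd1", "MSEhd1", "MAEhd1",
  "Mhd2", "TMhd2", "Dhd2", "MSDhd2", "MADhd2", "MSEhd2", "MAEhd2",
  "MHA", "TMHA", "PCD"
)

#' @rdname kin_vars_common
#' @export
kin_vars_tongue <- c("MTgP", "TMTgP", "TgD", "MSTgP", "MATgP", "MSTgR", "MATgR")

# excursion cycle of a signal around a fixed baseline, searched on a window.
# Returns peak time/magnitude and the frac-tolerance departure/return times.
cycle_events <- function(t, x, baseline, frac, from = t[1]) {
  in_win <- t >= from - 1e-12
  tw <- t[in_win]
  ex <- abs(x[in_win] - baseline)
  i_max <- which.max(ex)               # earliest on ties
  M <- ex[i_max]
  t_max <- tw[i_max]
  tol <- frac * M
  below_before <- which(ex[seq_len(i_max)] <= tol)
  t_start <- if (length(below_before)) tw[max(below_before)] else tw[1]
  after <- seq(i_max, length(ex))
  below_after <- after[ex[after] <= tol]
  truncated <- length(below_after) == 0
  t_end <- if (truncated) tw[length(tw)] else tw[min(below_after)]
  list(t_max = t_max, M = M, t_start = t_start, t_end = t_end,
       truncated = truncated)
}

#' Detect strike events on a kinematic profile
#'
#' Finds the landmarks in time of a strike: onset, maximum gape, mouth
#' closure, hyoid excursion maxima and return, maximum head angle and (for
#' terrestrial strikes) maximum tongue protraction, together with the resting
#' baselines all excursions are measured from.
#'
#' Clips are conventionally cropped to start at mouth opening, so the default
#' takes `t0` as the first frame and baselines as the median of the first
#' five frames. For uncropped clips, `t0_mode = "velocity_threshold"` sets
#' `t0` to the first time gape velocity exceeds `frac_v` of its maximum, and
#' baselines to medians of the pre-`t0` frames.
#'
#' Mouth closure is the first time after maximum gape at which gape distance
#' falls back to within `frac` of its excursion above baseline; hyoid (and
#' tongue) cycle starts/ends use the same `frac` tolerance on excursion from
#' baseline, and the hyoid return is the first time after both hyoid maxima
#' at which both hyoid distances are back within tolerance. Events that never
#' occur inside the clip are set to the last frame and flagged as truncated.
#' Ties at maxima take the earliest frame.
#'
#' @param profile A `kinematic_profile` from [build_profile()].
#' @param t0_mode `"first_frame"` (default) or `"velocity_threshold"`.
#' @param frac Cycle start/end tolerance as a fraction of peak excursion,
#'   in (0, 0.5). Default 0.05.
#' @param frac_v Velocity threshold fraction for `t0_mode =
#'   "velocity_threshold"`.
#' @return A `strike_events` list.
#' @export
detect_events <- function(profile, t0_mode = c("first_frame", "velocity_threshold"),
                          frac = 0.05, frac_v = 0.1) {
  stopifnot(inherits(profile, "kinematic_profile"))
  t0_mode <- match.arg(t0_mode)
  if (frac <= 0 || frac >= 0.5) stop_strikekin("`frac` must be in (0, 0.5).", "input_error")
  s <- profile$signals
  t <- s$t
  n <- length(t)

  if (t0_mode == "first_frame") {
    t0 <- t[1]
    base_idx <- seq_len(min(5, n))
  } else {
    gv <- profile$vel$gape_dist
    thr <- frac_v * max(gv)
    i0 <- which(gv > thr)[1]
    if (is.na(i0)) stop_strikekin("No rising gape velocity found.", "no_strike_error")
    t0 <- profile$vel$t[i0]
    base_idx <- if (i0 > 1) seq_len(i0) else seq_len(min(5, n))
  }
  g0   <- median(s$gape_dist[base_idx])
  hd1_0 <- median(s$hd1_dist[base_idx])
  hd2_0 <- median(s$hd2_dist[base_idx])
  tg_0 <- if ("tongue_dist" %in% names(s)) median(s$tongue_dist[base_idx]) else NA_real_

  win <- t >= t0
  MG <- max(s$gape_dist[win])
  if (MG - g0 <= 1e-6) {
    stop_strikekin("Gape never exceeds its baseline: no strike detected.",
                   "no_strike_error")
  }
  i_mg <- which(win)[which.max(s$gape_dist[win])]
  t_mg <- t[i_mg]
  close_level <- g0 + frac * (MG - g0)
  after <- which(t > t_mg & s$gape_dist <= close_level)
  closure_truncated <- length(after) == 0
  t_close <- if (closure_truncated) t[n] else t[after[1]]

  hd1 <- cycle_events(t, s$hd1_dist, hd1_0, frac, from = t0)
  hd2 <- cycle_events(t, s$hd2_dist, hd2_0, frac, from = t0)
  ret <- hyoid_return(t, s, hd1, hd2, hd1_0, hd2_0, frac, t0)

  win_ha <- t >= t0 & t <= ret$t_hd_return
  i_ha <- which(win_ha)[which.max(s$head_angle[win_ha])]
  events <- list(
    t0 = t0, g0 = g0, hd1_0 = hd1_0, hd2_0 = hd2_0, tg_0 = tg_0,
    t_mg = t_mg, MG = MG, t_close = t_close, closure_truncated = closure_truncated,
    hd1 = hd1, hd2 = hd2,
    t_hd_return = ret$t_hd_return, hd_truncated = ret$truncated,
    t_mha = t[i_ha], frac = frac, t0_mode = t0_mode
  )
  if ("tongue_dist" %in% names(s)) {
    tg <- cycle_events(t, s$tongue_dist, tg_0, frac, from = t0)
    events$tg <- tg
    events$t_mtgp <- tg$t_max
  }
  structure(events, class = "strike_events")
}

hyoid_return <- function(t, s, hd1, hd2, hd1_0, hd2_0, frac, t0) {
  t_both <- max(hd1$t_max, hd2$t_max)
  ok <- t >= t_both &
    abs(s$hd1_dist - hd1_0) <= frac * hd1$M &
    abs(s$hd2_dist - hd2_0) <= frac * hd2$M
  truncated <- !any(ok)
  list(t_hd_return = if (truncated) t[length(t)] else t[which(ok)[1]],
       truncated = truncated)
}

# max |value| of a derivative series on a closed time window (left-aligned
# timestamps; half-sample slack keeps boundary samples in).
win_max <- function(dt_series, a, b, dt, what) {
  sel <- dt_series$t >= a - dt / 2 & dt_series$t <= b + dt / 2
  if (!any(sel)) {
    stop_strikekin(sprintf("Empty phase window for %s.", what),
                   "degenerate_phase_error")
  }
  max(abs(dt_series$value[sel]))
}

phase_extrema <- function(profile, signal, a, b, what) {
  v <- list(t = profile$vel$t, value = profile$vel[[signal]])
  ac <- list(t = profile$acc$t, value = profile$acc[[signal]])
  c(speed = win_max(v, a, b, profile$dt, what),
    accel = win_max(ac, a, b, profile$dt, what))
}

hd_variables <- function(profile, events, which_hd, cyc, baseline, t0) {
  sig <- paste0(which_hd, "_dist")
  dep <- phase_extrema(profile, sig, cyc$t_start, cyc$t_max,
                       paste0(which_hd, " depression"))
  ele <- phase_extrema(profile, sig, cyc$t_max, cyc$t_end,
                       paste0(which_hd, " elevation"))
  out <- c(cyc$M, cyc$t_max - t0, cyc$t_end - cyc$t_start,
           dep[["speed"]], dep[["accel"]], ele[["speed"]], ele[["accel"]])
  names(out) <- paste0(c("M", "TM", "D", "MSD", "MAD", "MSE", "MAE"), which_hd)
  # names like Mhd1, TMhd1, Dhd1, MSDhd1...
  out
}

#' Extract the 25 common strike variables
#'
#' Scalar kinematics of the gape cycle, the two hyoid cycles and the whole
#' event, measured from a profile and its detected events. Amplitudes of the
#' hyoid are excursions from baseline; `MG` and `MGA` are absolute maxima
#' (the mouth at rest is near closed). Speeds and accelerations are maxima of
#' the magnitude of the forward-difference derivatives over the relevant
#' phase: opening/depression up to the peak, closing/elevation after it.
#' Times are relative to strike onset `t0`.
#'
#' @param profile A `kinematic_profile`.
#' @param events A `strike_events` from [detect_events()].
#' @return A named numeric vector with the 25 common variables plus `HA0`.
#' @export
extract_common <- function(profile, events) {
  stopifnot(inherits(profile, "kinematic_profile"), inherits(events, "strike_events"))
  s <- profile$signals
  t <- s$t
  t0 <- events$t0
  if (events$t_mg <= t0 && t0 > t[1]) {
    stop_strikekin("Maximum gape at onset: degenerate opening phase (TMG).",
                   "degenerate_phase_error")
  }
  win_g <- t >= t0 & t <= events$t_close
  open_ex <- phase_extrema(profile, "gape_dist", t0, events$t_mg, "gape opening")
  close_ex <- phase_extrema(profile, "gape_dist", events$t_mg, events$t_close,
                            "gape closing")
  win_ha <- t >= t0 & t <= events$t_hd_return
  ha0 <- s$head_angle[which(t >= t0)[1]]

  out <- c(
    MG = max(s$gape_dist[win_g]),
    TMG = events$t_mg - t0,
    MGA = max(s$gape_angle[win_g]),
    DG = events$t_close - t0,
    MSGO = open_ex[["speed"]], MAGO = open_ex[["accel"]],
    MSGC = close_ex[["speed"]], MAGC = close_ex[["accel"]],
    hd_variables(profile, events, "hd1", events$hd1, events$hd1_0, t0),
    hd_variables(profile, events, "hd2", events$hd2, events$hd2_0, t0),
    MHA = max(s$head_angle[win_ha]),
    TMHA = events$t_mha - t0,
    PCD = events$t_hd_return - t0,
    HA0 = ha0
  )
  out[kin_vars_common_ha0]
}

kin_vars_common_ha0 <- c(kin_vars_common, "HA0")

#' Extract the tongue variables of a terrestrial strike
#'
#' Tongue protraction/retraction kinematics, measured as the excursion of the
#' tongue-pad-to-jaw-joint distance from its resting value. Because hyoid and
#' tongue movements are mechanically linked on land, the hyoid cycle of a
#' terrestrial strike is only meaningful after maximum tongue protraction:
#' the returned vector therefore also carries recomputed hyoid variables
#' (and hyoid return / `PCD`, `MHA`, `TMHA`) restricted to the window from
#' maximum tongue protraction to the end of the clip.
#'
#' @inheritParams extract_common
#' @return Named numeric vector: the 7 tongue variables plus restricted
#'   hyoid/whole-event variables overriding those of [extract_common()].
#' @export
extract_tongue <- function(profile, events) {
  stopifnot(inherits(profile, "kinematic_profile"), inherits(events, "strike_events"))
  if (profile$medium != "terrestrial" || is.null(profile$signals$tongue_dist)) {
    stop_strikekin("Tongue variables need a terrestrial profile with a tg landmark.",
                   "configuration_error")
  }
  s <- profile$signals
  t <- s$t
  t0 <- events$t0
  tg <- events$tg
  prot <- phase_extrema(profile, "tongue_dist", tg$t_start, tg$t_max,
                        "tongue protraction")
  retr <- phase_extrema(profile, "tongue_dist", tg$t_max, tg$t_end,
                        "tongue retraction")
  # hyoid cycles restricted to after peak tongue protraction
  hd1 <- cycle_events(t, s$hd1_dist, events$hd1_0, events$frac, from = tg$t_max)
  hd2 <- cycle_events(t, s$hd2_dist, events$hd2_0, events$frac, from = tg$t_max)
  ret <- hyoid_return(t, s, hd1, hd2, events$hd1_0, events$hd2_0, events$frac,
                      tg$t_max)
  win_ha <- t >= t0 & t <= ret$t_hd_return
  i_ha <- which(win_ha)[which.max(s$head_angle[win_ha])]
  c(
    MTgP = tg$M,
    TMTgP = tg$t_max - t0,
    TgD = tg$t_end - tg$t_start,
    MSTgP = prot[["speed"]], MATgP = prot[["accel"]],
    MSTgR = retr[["speed"]], MATgR = retr[["accel"]],
    hd_variables(profile, events, "hd1", hd1, events$hd1_0, t0),
    hd_variables(profile, events, "hd2", hd2, events$hd2_0, t0),
    MHA = max(s$head_angle[win_ha]),
    TMHA = t[i_ha] - t0,
    PCD = ret$t_hd_return - t0
  )
}

#' Extract all strike variables for one profile
#'
#' Convenience wrapper: [detect_events()] then [extract_common()] and, for
#' terrestrial profiles, [extract_tongue()] (whose restricted hyoid and
#' whole-event values replace the unrestricted ones).
#'
#' @inheritParams detect_events
#' @return A one-row tibble with `video_id`, the variables, and truncation
#'   flags.
#' @export
extract_strike <- function(profile, t0_mode = "first_frame", frac = 0.05,
                           frac_v = 0.1) {
  events <- detect_events(profile, t0_mode = t0_mode, frac = frac, frac_v = frac_v)
  vars <- extract_common(profile, events)
  if (profile$medium == "terrestrial") {
    tg <- extract_tongue(profile, events)
    vars[intersect(names(tg), names(vars))] <- tg[intersect(names(tg), names(vars))]
    vars <- c(vars, tg[kin_vars_tongue])
  }
  out <- tibble::as_tibble(as.list(vars))
  out$video_id <- profile$video_id
  out$truncated <- events$closure_truncated || events$hd_truncated
  cols <- c("video_id",
            if (profile$medium == "terrestrial") c(kin_vars_common, kin_vars_tongue)
            else kin_vars_common,
            "HA0", "truncated")
  out[cols]
}

#' Extract a strike-variables table for a whole study
#'
#' Runs the full pipeline (likelihood gating, calibration, profiling, event
#' detection, variable extraction) for every video in a manifest, and returns
#' one table per medium: aquatic rows carry the 25 common variables (+HA0),
#' terrestrial rows all 32 (+HA0). Per-video failures are caught, reported as
#' a warning, and flagged in the `ok` column with `NA` variables — rows are
#' never silently dropped.
#'
#' @param series A named list of [landmark_series()] (names = video_id), or a
#'   directory containing `<video_id>.csv` DLC files.
#' @param manifest Manifest tibble (see [read_manifest()]).
#' @param target_df Smoothing target df, default 80.
#' @param frac Cycle tolerance, default 0.05.
#' @param t0_mode Onset mode, default `"first_frame"`.
#' @param gate Likelihood threshold for [gate_likelihood()], default 0.9.
#' @return A list with tibbles `aquatic` and `terrestrial`.
#' @export
extract_table <- function(series, manifest, target_df = 80, frac = 0.05,
                          t0_mode = "first_frame", gate = 0.9) {
  manifest <- validate_manifest(manifest)
  get_series <- function(vid) {
    if (is.character(series)) {
      read_dlc_csv(file.path(series, paste0(vid, ".csv")), video_id = vid)
    } else {
      series[[vid]]
    }
  }
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    meta <- manifest[i, ]
    res <- tryCatch({
      sr <- get_series(meta$video_id)
      sr <- gate_likelihood(sr, gate)
      sr <- calibrate(sr, meta)
      pr <- build_profile(sr, medium = meta$medium, target_df = target_df)
      row <- extract_strike(pr, t0_mode = t0_mode, frac = frac)
      row$ok <- TRUE
      row
    }, error = function(e) {
      rlang::warn(sprintf("Video '%s' failed: %s", meta$video_id,
                          conditionMessage(e)))
      tibble::tibble(video_id = meta$video_id, ok = FALSE, truncated = NA)
    })
    res$individual_id <- meta$individual_id
    res$medium <- meta$medium
    res$presentation <- meta$presentation
    res$capture_type <- meta$capture_type
    res
  })
  meta_cols <- c("video_id", "individual_id", "medium", "presentation",
                 "capture_type")
  assemble <- function(med, vars) {
    cols <- c(meta_cols, vars, "HA0", "truncated", "ok")
    sub <- rows[vapply(rows, function(r) r$medium[1] == med, logical(1))]
    if (!length(sub)) {
      out <- tibble::as_tibble(setNames(
        c(rep(list(character()), 5),
          rep(list(numeric()), length(vars) + 1),
          list(logical()), list(logical())), cols))
      return(out)
    }
    out <- do.call(rbind, lapply(sub, function(r) {
      for (v in setdiff(cols, names(r))) r[[v]] <- NA_real_
      r[cols]
    }))
    tibble::as_tibble(out)
  }
  list(
    aquatic = assemble("aquatic", kin_vars_common),
    terrestrial = assemble("terrestrial", c(kin_vars_common, kin_vars_tongue))
  )
}
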