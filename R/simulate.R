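#' Raised-cosine pulse
#'
#' Unit-amplitude pulse rising from 0 to 1 over `rise` seconds as
#' `0.5 * (1 - cos(pi * u / rise))` and falling back over `fall` seconds,
#' zero elsewhere. Its value, velocity and acceleration extrema have closed
#' forms (peak rise speed `pi / (2 rise)`, peak rise acceleration
#' `pi^2 / (2 rise^2)`, and the mirrored expressions on the fall), which is
#' what makes simulated strikes usable as exact ground truth.
#'
#' @param t Time vector (s).
#' @param onset Pulse start time (s).
#' @param rise,fall Rise and fall durations (s).
#' @return Numeric vector in `[0, 1]`.
#' @export
raised_cosine <- function(t, onset, rise, fall) {
  u <- t - onset
  out <- numeric(length(t))
  r <- u >= 0 & u < rise
  f <- u >= rise & u < rise + fall
  out[r] <- 0.5 * (1 - cos(pi * u[r] / rise))
  out[f] <- 0.5 * (1 + cos(pi * (u[f] - rise) / fall))
  out
}

pulse_spec <- function(baseline, amp, onset, rise, fall) {
  list(baseline = baseline, amp = amp, onset = onset, rise = rise, fall = fall)
}

#' Parameters of a synthetic feeding strike
#'
#' Defines the parametric motion model from which landmark trajectories and
#' their exact kinematic ground truth are generated. Every scalar signal
#' (gape distance, the two hyoid-to-jaw-joint distances, head-angle
#' excursion, tongue distance) is a raised-cosine pulse on top of a resting
#' baseline. Landmarks are then placed by a two-bar jaw linkage hinged at the
#' jaw joint (reproducing the gape signal exactly), hyoid markers displaced
#' along a fixed axis from the jaw joint, the tongue pad along the gape
#' bisector, and a rigid head rotation about the eye relative to the fixed
#' shoulder (reproducing the head-angle signal exactly).
#'
#' Defaults emulate a 1000 fps lateral-view recording with a 100 px/cm scale:
#' a 0.3 s aquatic suction strike (30 ms gape opening) or a slower 0.6 s
#' terrestrial tongue-prehension strike whose hyoid cycle starts only after
#' peak tongue protraction, as it does in tongue-feeding salamanders.
#'
#' @param medium `"aquatic"` or `"terrestrial"`.
#' @param fps Frames per second (default 1000).
#' @param scale Pixels per centimetre (default 100).
#' @param duration Clip length in seconds (default 0.3 aquatic, 0.6
#'   terrestrial).
#' @param gape,hyoid1,hyoid2,tongue Pulse specifications: lists with
#'   `baseline` (cm), `amp` (cm), `onset` (s), `rise` (s), `fall` (s).
#'   `tongue` is used only for terrestrial strikes.
#' @param head List with `angle0` (resting head angle, degrees), `excursion`
#'   (degrees), `peak_time` (s).
#' @param noise_sd Gaussian landmark noise, in pixels (default 0.5).
#' @param likelihood List with `base` (lower bound of the likelihood of a
#'   well-tracked frame), `dropout` (per-frame probability of a tracking
#'   failure) and `dropout_shift_px` (extra coordinate noise on failed
#'   frames).
#' @param seed Integer seed making the simulated CSV reproducible.
#' @param jaw_len Jaw bar length (cm) of the linkage; the gape (baseline +
#'   amplitude) must stay below `2 * jaw_len`.
#'
#' @return A `strike_params` list.
#' @export
strike_params <- function(medium = c("aquatic", "terrestrial"),
                          fps = 1000, scale = 100, duration = NULL,
                          gape = NULL, hyoid1 = NULL, hyoid2 = NULL,
                          head = NULL, tongue = NULL,
                          noise_sd = 0.5,
                          likelihood = list(base = 0.95, dropout = 0.02,
                                            dropout_shift_px = 15),
                          seed = NULL, jaw_len = NULL) {
  medium <- match.arg(medium)
  if (fps <= 0 || scale <= 0) {
    stop_strikekin("`fps` and `scale` must be positive.", "parameter_error")
  }
  if (medium == "aquatic") {
    duration <- duration %||% 0.3
    gape   <- modifyList(pulse_spec(0.08, 0.8, 0.010, 0.030, 0.050), gape %||% list())
    hyoid1 <- modifyList(pulse_spec(0.50, 0.50, 0.020, 0.040, 0.080), hyoid1 %||% list())
    hyoid2 <- modifyList(pulse_spec(0.90, 0.60, 0.025, 0.045, 0.090), hyoid2 %||% list())
    head   <- modifyList(list(angle0 = 100, excursion = 12, peak_time = 0.055),
                         head %||% list())
    jaw_len <- jaw_len %||% 1.2
    tongue <- NULL
  } else {
    duration <- duration %||% 0.6
    gape   <- modifyList(pulse_spec(0.12, 1.6, 0.010, 0.060, 0.090), gape %||% list())
    tongue <- modifyList(pulse_spec(0.35, 1.8, 0.015, 0.065, 0.110), tongue %||% list())
    hyoid1 <- modifyList(pulse_spec(0.70, 0.50, 0.090, 0.090, 0.130), hyoid1 %||% list())
    hyoid2 <- modifyList(pulse_spec(1.20, 0.60, 0.095, 0.095, 0.140), hyoid2 %||% list())
    head   <- modifyList(list(angle0 = 105, excursion = 8, peak_time = 0.090),
                         head %||% list())
    jaw_len <- jaw_len %||% 1.8
  }
  p <- list(medium = medium, fps = fps, scale = scale, duration = duration,
            gape = gape, hyoid1 = hyoid1, hyoid2 = hyoid2, head = head,
            tongue = tongue, noise_sd = noise_sd, likelihood = likelihood,
            seed = seed, jaw_len = jaw_len)
  validate_strike_params(p)
  structure(p, class = "strike_params")
}

validate_strike_params <- function(p) {
  pulses <- Filter(Negate(is.null), p[c("gape", "hyoid1", "hyoid2", "tongue")])
  for (nm in names(pulses)) {
    q <- pulses[[nm]]
    if (q$amp < 0 || q$baseline < 0 || q$rise <= 0 || q$fall <= 0 || q$onset < 0) {
      stop_strikekin(sprintf("Invalid %s pulse parameters.", nm), "parameter_error")
    }
    if (q$onset + q$rise + q$fall > p$duration) {
      stop_strikekin(sprintf("%s pulse does not fit inside the clip duration.", nm),
                     "parameter_error")
    }
  }
  if (p$gape$baseline + p$gape$amp >= 2 * p$jaw_len) {
    stop_strikekin("Maximum gape exceeds the jaw linkage span (2 * jaw_len).",
                   "parameter_error")
  }
  h <- p$head
  if (h$peak_time <= p$gape$onset || 2 * h$peak_time - p$gape$onset > p$duration) {
    stop_strikekin("Head-angle peak time must lie after gape onset and the
                    excursion must fit in the clip.", "parameter_error")
  }
  if (h$angle0 + h$excursion >= 178) {
    stop_strikekin("Head angle excursion would exceed 178 degrees.", "parameter_error")
  }
  invisible(p)
}

pulse_signal <- function(t, q) q$baseline + q$amp * raised_cosine(t, q$onset, q$rise, q$fall)

rot <- function(theta) matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)

# noiseless landmark trajectories (cm, world frame with y increasing downward)
strike_geometry <- function(p, t) {
  g  <- pulse_signal(t, p$gape)
  h1 <- pulse_signal(t, p$hyoid1)
  h2 <- pulse_signal(t, p$hyoid2)
  phi <- rad(p$head$excursion) *
    raised_cosine(t, 2 * p$gape$onset - p$gape$onset, # head moves with the strike
                  p$head$peak_time - p$gape$onset, p$head$peak_time - p$gape$onset)
  L <- p$jaw_len
  theta <- 2 * asin(g / (2 * L))

  e <- c(2, 1)                         # eye, fixed pivot of head rotation
  a_s <- rad(135)                      # shoulder direction from the eye
  r_sh <- if (p$medium == "aquatic") 1.8 else 3.0
  sh <- e + r_sh * c(cos(a_s), sin(a_s))
  a_u0 <- a_s - rad(p$head$angle0)     # upper-jaw-tip direction at rest
  r_u <- if (p$medium == "aquatic") 1.5 else 2.5
  uj_h <- e + r_u * c(cos(a_u0), sin(a_u0))
  b0 <- a_u0 - rad(10)                 # jaw bar direction jj -> uj
  jj_h <- uj_h - L * c(cos(b0), sin(b0))
  hd_ax <- rad(100)                    # hyoid axis from jj, ventral-posterior

  n <- length(t)
  pts <- list()
  lj_ang <- b0 + theta                 # lower jaw rotates ventrally (y down)
  bis <- b0 + theta / 2
  head_pts <- function(px, py) {
    # rotate head-frame points about the eye by -phi (opens the head angle)
    dx <- px - e[1]; dy <- py - e[2]
    cs <- cos(-phi); sn <- sin(-phi)
    cbind(x = e[1] + cs * dx - sn * dy, y = e[2] + sn * dx + cs * dy)
  }
  pts$e  <- cbind(x = rep(e[1], n), y = rep(e[2], n))
  pts$sh <- cbind(x = rep(sh[1], n), y = rep(sh[2], n))
  pts$uj <- head_pts(rep(uj_h[1], n), rep(uj_h[2], n))
  pts$lj <- head_pts(jj_h[1] + L * cos(lj_ang), jj_h[2] + L * sin(lj_ang))
  pts$jj <- head_pts(rep(jj_h[1], n), rep(jj_h[2], n))
  pts$hd1 <- head_pts(jj_h[1] + h1 * cos(hd_ax), jj_h[2] + h1 * sin(hd_ax))
  pts$hd2 <- head_pts(jj_h[1] + h2 * cos(hd_ax), jj_h[2] + h2 * sin(hd_ax))
  if (p$medium == "terrestrial") {
    tgd <- pulse_signal(t, p$tongue)
    pts$tg <- head_pts(jj_h[1] + tgd * cos(bis), jj_h[2] + tgd * sin(bis))
  }
  pts
}

# closed-form fraction of the pulse duration elapsed when the excursion
# crosses frac of the peak (same coefficient on rise departure and fall return)
cross_coef <- function(frac) acos(2 * frac - 1) / pi

pulse_truth <- function(q, t0, frac, window_start = -Inf) {
  cf <- cross_coef(frac)
  peak <- q$onset + q$rise
  if (window_start <= q$onset) {
    M <- q$amp
    t_max <- peak
    t_start <- q$onset + (1 - cf) * q$rise
    speed_up <- pi * q$amp / (2 * q$rise)
    accel_up <- pi^2 * q$amp / (2 * q$rise^2)
  } else if (window_start < peak) {
    # window clips the rise: peak still reached, departure at the window edge
    M <- q$amp
    t_max <- peak
    t_start <- max(window_start, q$onset + (1 - cf) * q$rise)
    speed_up <- pi * q$amp / (2 * q$rise)   # mid-rise speed may be clipped;
    accel_up <- NA_real_                    # no closed form claimed
    if (window_start > q$onset + q$rise / 2) speed_up <- NA_real_
  } else {
    # window starts after the peak: only the tail is visible
    M <- q$amp * raised_cosine(window_start, q$onset, q$rise, q$fall)
    t_max <- window_start
    t_start <- window_start
    speed_up <- NA_real_
    accel_up <- NA_real_
  }
  t_end <- peak + cf * q$fall
  list(
    M = M, t_max = t_max, t_start = t_start, t_end = max(t_end, t_max),
    TM = t_max - t0, D = max(t_end, t_max) - t_start,
    MS_up = speed_up, MA_up = accel_up,
    MS_down = pi * q$amp / (2 * q$fall),
    MA_down = pi^2 * q$amp / (2 * q$fall^2)
  )
}

#' Closed-form ground truth of a synthetic strike
#'
#' Analytic values of every strike variable implied by the noiseless
#' parametric motion model, using the same cycle tolerance `frac` as the
#' extractor. For terrestrial strikes the hyoid values are computed on the
#' window after peak tongue protraction, mirroring the extractor's
#' restriction.
#'
#' @param params A [strike_params()].
#' @param frac Cycle tolerance matching [detect_events()], default 0.05.
#' @return A one-row tibble of strike variables.
#' @export
strike_truth <- function(params, frac = 0.05) {
  p <- params
  t0 <- 0
  g <- pulse_truth(p$gape, t0, frac)
  head_peak <- p$head$peak_time
  out <- list(
    MG = p$gape$baseline + p$gape$amp,
    TMG = g$t_max - t0,
    MGA = deg(2 * asin((p$gape$baseline + p$gape$amp) / (2 * p$jaw_len))),
    DG = g$t_end - t0,
    MSGO = g$MS_up, MAGO = g$MA_up, MSGC = g$MS_down, MAGC = g$MA_down
  )
  win <- -Inf
  if (p$medium == "terrestrial") {
    tg <- pulse_truth(p$tongue, t0, frac)
    win <- tg$t_max
    out <- c(out, list(
      MTgP = tg$M, TMTgP = tg$TM, TgD = tg$D,
      MSTgP = tg$MS_up, MATgP = tg$MA_up,
      MSTgR = tg$MS_down, MATgR = tg$MA_down
    ))
  }
  h1 <- pulse_truth(p$hyoid1, t0, frac, window_start = win)
  h2 <- pulse_truth(p$hyoid2, t0, frac, window_start = win)
  out <- c(out, list(
    Mhd1 = h1$M, TMhd1 = h1$TM, Dhd1 = h1$D,
    MSDhd1 = h1$MS_up, MADhd1 = h1$MA_up, MSEhd1 = h1$MS_down, MAEhd1 = h1$MA_down,
    Mhd2 = h2$M, TMhd2 = h2$TM, Dhd2 = h2$D,
    MSDhd2 = h2$MS_up, MADhd2 = h2$MA_up, MSEhd2 = h2$MS_down, MAEhd2 = h2$MA_down,
    MHA = p$head$angle0 + p$head$excursion,
    TMHA = head_peak - t0,
    PCD = max(h1$t_end, h2$t_end) - t0,
    HA0 = p$head$angle0
  ))
  cols <- c(if (p$medium == "terrestrial") c(kin_vars_common, kin_vars_tongue)
            else kin_vars_common, "HA0")
  tibble::as_tibble(out)[cols]
}

#' Simulate one feeding strike
#'
#' Generates landmark trajectories from the parametric motion model of
#' [strike_params()], converts them to pixels, adds Gaussian landmark noise
#' and per-frame likelihoods (with occasional tracking dropouts), and returns
#' both the series (in the DLC dialect, ready for [write_dlc_csv()]) and the
#' closed-form ground truth.
#'
#' @param params A [strike_params()].
#' @param video_id Identifier for the emitted series.
#' @param frac Cycle tolerance used for the duration entries of the truth.
#' @return List with `series` (a [landmark_series()] in pixels), `truth`
#'   (one-row tibble) and `params`.
#' @export
simulate_strike <- function(params, video_id = "sim", frac = 0.05) {
  stopifnot(inherits(params, "strike_params"))
  p <- params
  n <- round(p$duration * p$fps)
  t <- (seq_len(n) - 1) / p$fps
  pts <- strike_geometry(p, t)
  px_off <- 50   # keep pixel coordinates positive
  build <- function() {
    coords <- lapply(pts, function(m) {
      x <- m[, "x"] * p$scale + px_off
      y <- m[, "y"] * p$scale + px_off
      lik <- runif(n, p$likelihood$base, 1)
      drop <- runif(n) < p$likelihood$dropout
      if (any(drop)) {
        lik[drop] <- runif(sum(drop), 0.05, 0.5)
        x[drop] <- x[drop] + rnorm(sum(drop), 0, p$likelihood$dropout_shift_px)
        y[drop] <- y[drop] + rnorm(sum(drop), 0, p$likelihood$dropout_shift_px)
      }
      if (p$noise_sd > 0) {
        x <- x + rnorm(n, 0, p$noise_sd)
        y <- y + rnorm(n, 0, p$noise_sd)
      }
      tibble::tibble(x = x, y = y, likelihood = lik)
    })
    landmark_series(video_id, coords)
  }
  series <- if (is.null(p$seed)) build() else withr::with_seed(p$seed, build())
  truth <- strike_truth(p, frac = frac)
  truth$video_id <- video_id
  list(series = series, truth = truth, params = p)
}
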