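# Shared fixtures: all built in code at test time.

# noise-free, dropout-free strike parameters
quiet_params <- function(medium = "aquatic", ...) {
  strike_params(medium, noise_sd = 0,
                likelihood = list(base = 0.99, dropout = 0, dropout_shift_px = 0),
                ...)
}

# simulate -> gate -> calibrate -> profile in one go
sim_profile <- function(params, video_id = "v", individual = "A1",
                        presentation = "substrate", target_df = 80) {
  sim <- simulate_strike(params, video_id)
  meta <- video_meta(video_id, individual, params$medium, presentation,
                     fps = params$fps, scale = params$scale)
  series <- calibrate(gate_likelihood(sim$series), meta)
  list(profile = build_profile(series, params$medium, target_df = target_df),
       truth = sim$truth, series = series, meta = meta, sim = sim)
}

# hand-built kinematic profile from raw signal vectors (for event-rule tests)
fake_profile <- function(t, gape, hd1 = NULL, hd2 = NULL, head = NULL,
                         tongue = NULL, medium = "aquatic") {
  n <- length(t)
  hd1 <- hd1 %||% rep(0.5, n)
  hd2 <- hd2 %||% rep(0.9, n)
  head <- head %||% rep(100, n)
  signals <- tibble::tibble(t = t, gape_dist = gape, gape_angle = gape * 50,
                            hd1_dist = hd1, hd2_dist = hd2, head_angle = head)
  if (!is.null(tongue)) signals$tongue_dist <- tongue
  nm <- setdiff(names(signals), "t")
  d1 <- lapply(signals[nm], function(s) diff(s) / diff(t))
  t1 <- t[-n]
  d2 <- lapply(d1, function(v) diff(v) / diff(t1))
  structure(
    list(video_id = "fake", medium = medium, signals = signals,
         vel = tibble::as_tibble(c(list(t = t1), d1)),
         acc = tibble::as_tibble(c(list(t = t1[-length(t1)]), d2)),
         dt = t[2] - t[1], effective_df = NA, target_df = NA),
    class = "kinematic_profile"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# value of a parametric pulse at times t
pulse_value <- function(t, q) {
  q$baseline + q$amp * raised_cosine(t, q$onset, q$rise, q$fall)
}

# small random landmark series (pixel units)
random_series <- function(n = 10, seed = 1, landmarks =
                            c("e", "uj", "lj", "jj", "hd1", "hd2", "sh")) {
  withr::with_seed(seed, {
    coords <- lapply(setNames(landmarks, landmarks), function(lm) {
      tibble::tibble(x = runif(n, 0, 500), y = runif(n, 0, 400),
                     likelihood = runif(n, 0.92, 1))
    })
    landmark_series("rand", coords)
  })
}

# per-strike random aquatic parameters for recovery experiments
draw_recovery_params <- function(noise_sd = 0.5) {
  strike_params(
    "aquatic", noise_sd = noise_sd,
    likelihood = list(base = 0.95, dropout = 0, dropout_shift_px = 0),
    gape = list(amp = runif(1, 0.6, 1.0), rise = runif(1, 0.025, 0.040),
                fall = runif(1, 0.045, 0.065)),
    hyoid1 = list(amp = runif(1, 0.40, 0.65), rise = runif(1, 0.035, 0.050),
                  fall = runif(1, 0.070, 0.095)),
    hyoid2 = list(amp = runif(1, 0.45, 0.70), rise = runif(1, 0.040, 0.055),
                  fall = runif(1, 0.075, 0.100)),
    head = list(excursion = runif(1, 8, 16), peak_time = runif(1, 0.045, 0.065))
  )
}
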