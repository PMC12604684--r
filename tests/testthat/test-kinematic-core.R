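test_that("smooth_track hits the target effective df and its limits", {
  withr::with_seed(11, {
    n <- 200
    t <- (0:(n - 1)) / 1000
    x <- sin(2 * pi * 8 * t) + rnorm(n, 0, 0.05)
    for (df_t in c(5, 20, 80, 150)) {
      fit <- smooth_track(x, t, target_df = df_t)
      expect_lt(abs(fit$effective_df - df_t), 0.1)
    }
    # penalty is monotone in df: higher df <-> smaller lambda
    lambdas <- vapply(c(5, 20, 80, 150),
                      function(d) smooth_track(x, t, d)$lambda, numeric(1))
    expect_true(all(diff(lambdas) < 0))

    # df -> 2 limit approaches the least-squares line
    fit2 <- smooth_track(x, t, target_df = 2)
    line <- stats::fitted(lm(x ~ t))
    expect_lt(abs(fit2$effective_df - 2), 0.1)
    expect_lt(max(abs(fit2$x_s - line)), 0.05)

    # data already on a line are reproduced at any df
    xl <- 3 + 5 * t
    expect_equal(smooth_track(xl, t, 40)$x_s, xl, tolerance = 1e-9)
  })
})

test_that("smooth_track denoises a known curve and validates input", {
  withr::with_seed(21, {
    n <- 500
    t <- (0:(n - 1)) / 1000
    truth <- sin(2 * pi * 6 * t)
    noisy <- truth + rnorm(n, 0, 0.1)
    fit <- smooth_track(noisy, t, 80)
    rmse <- function(a, b) sqrt(mean((a - b)^2))
    expect_lt(rmse(fit$x_s, truth), rmse(noisy, truth))
  })
  t <- (0:49) / 1000
  expect_error(smooth_track(rnorm(50), rev(t), 20), class = "strikekin_input_error")
  expect_error(smooth_track(rnorm(3), t[1:3], 2), class = "strikekin_input_error")
  expect_error(smooth_track(rnorm(50), t, 60), class = "strikekin_input_error")
  expect_warning(smooth_track(rnorm(50), t, 49), class = "strikekin_df_capped")
})

test_that("euclidean_distance follows the distance formula and its invariances", {
  a <- data.frame(x = c(0, 1), y = c(0, 1))
  b <- data.frame(x = c(3, 1), y = c(4, 1))
  expect_equal(euclidean_distance(a, b), c(5, 0))
  shift <- data.frame(x = a$x + 7, y = a$y - 2)
  shift_b <- data.frame(x = b$x + 7, y = b$y - 2)
  expect_equal(euclidean_distance(shift, shift_b), euclidean_distance(a, b))
  expect_error(euclidean_distance(a, b[1, ]), class = "strikekin_input_error")
})

test_that("alkashi_angle matches geometry and an atan2 oracle", {
  eq <- function(p) data.frame(x = p[1], y = p[2])
  expect_equal(alkashi_angle(eq(c(1, 0)), eq(c(0, 0)), eq(c(0.5, sqrt(3) / 2))), 60)
  expect_equal(alkashi_angle(eq(c(1, 0)), eq(c(0, 0)), eq(c(0, 1))), 90)
  expect_equal(alkashi_angle(eq(c(-1, 0)), eq(c(0, 0)), eq(c(2, 0))), 180)
  expect_error(alkashi_angle(eq(c(0, 0)), eq(c(0, 0)), eq(c(1, 1))),
               class = "strikekin_geometry_error")

  atan2_angle <- function(a, v, c) {
    u <- c(a$x - v$x, a$y - v$y); w <- c(c$x - v$x, c$y - v$y)
    th <- atan2(u[2], u[1]) - atan2(w[2], w[1])
    d <- abs(th) %% (2 * pi)
    min(d, 2 * pi - d) * 180 / pi
  }
  withr::with_seed(31, {
    worst <- 0
    for (i in 1:1000) {
      a <- data.frame(x = runif(1, -5, 5), y = runif(1, -5, 5))
      v <- data.frame(x = runif(1, -5, 5), y = runif(1, -5, 5))
      c <- data.frame(x = runif(1, -5, 5), y = runif(1, -5, 5))
      worst <- max(worst, abs(alkashi_angle(a, v, c) - atan2_angle(a, v, c)))
    }
    expect_lt(worst, 1e-9)
  })
})

test_that("differentiate is the forward difference, left-aligned", {
  t <- (0:9) / 1000
  d <- differentiate(0:9, t)
  expect_equal(d$value, rep(1000, 9))
  expect_equal(d$t, t[-10])
  expect_equal(differentiate(rep(4, 10), t)$value, rep(0, 9))
  # second derivative of t^2 is exactly 2 for forward differences
  d2 <- differentiate(differentiate(t^2, t)$value, t[-10])
  expect_equal(d2$value, rep(2, 8), tolerance = 1e-9)
  # affine signal has exactly constant derivative
  daff <- differentiate(2 - 3 * t, t)
  expect_equal(daff$value, rep(-3, 9), tolerance = 1e-9)
  expect_error(differentiate(1, t[1]), class = "strikekin_input_error")
})

test_that("build_profile computes signals from smoothed coordinates in order", {
  run <- sim_profile(quiet_params("aquatic"))
  pr <- run$profile
  # gape equals the generator's pulse up to spline tolerance
  p <- quiet_params("aquatic")
  t <- pr$signals$t
  pulse <- p$gape$baseline + p$gape$amp *
    raised_cosine(t, p$gape$onset, p$gape$rise, p$gape$fall)
  expect_lt(max(abs(pr$signals$gape_dist - pulse)), 0.01)
  # schema: no tongue signal in water
  expect_false("tongue_dist" %in% names(pr$signals))
  # derivatives one/two samples shorter, shared time base
  expect_equal(nrow(pr$vel), nrow(pr$signals) - 1)
  expect_equal(nrow(pr$acc), nrow(pr$signals) - 2)
  expect_equal(pr$vel$t, t[-length(t)])
})

test_that("profile signals are invariant under rigid motion of the landmarks", {
  run <- sim_profile(quiet_params("aquatic"))
  series <- run$series
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- series
  for (lm in rot$landmarks) {
    xy <- as.matrix(rot$coords[[lm]][, c("x", "y")]) %*% t(R)
    rot$coords[[lm]]$x <- xy[, 1] + 3.2
    rot$coords[[lm]]$y <- xy[, 2] - 1.1
  }
  pr0 <- run$profile
  pr1 <- build_profile(rot, "aquatic")
  for (s in c("gape_dist", "gape_angle", "hd1_dist", "head_angle")) {
    expect_equal(pr1$signals[[s]], pr0$signals[[s]], tolerance = 1e-6)
  }
})

test_that("build_profile demands its landmarks and a calibrated series", {
  run <- sim_profile(quiet_params("aquatic"))
  s <- run$series
  s$coords$hd1 <- NULL
  s$landmarks <- setdiff(s$landmarks, "hd1")
  expect_error(build_profile(s, "aquatic"), class = "strikekin_configuration_error")
  raw <- simulate_strike(quiet_params("aquatic"), "x")$series
  expect_error(build_profile(raw, "aquatic"), class = "strikekin_configuration_error")
  expect_error(build_profile(run$series, "terrestrial"),
               class = "strikekin_configuration_error")
})
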