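test_that("detect_events finds closure, ties and truncation correctly", {
  p <- quiet_params("aquatic")
  run <- sim_profile(p)
  ev <- detect_events(run$profile, frac = 0.05)
  # closed-form 95%-return time of the gape pulse
  t_close_true <- p$gape$onset + p$gape$rise + acos(2 * 0.05 - 1) / pi * p$gape$fall
  expect_lt(abs(ev$t_close - t_close_true), 2 / p$fps)
  expect_equal(ev$t0, 0)
  expect_false(ev$closure_truncated)

  # monotone non-decreasing gape: truncation flag, closure at the last frame
  t <- (0:99) / 1000
  pr <- fake_profile(t, gape = 0.1 + cumsum(rep(0.005, 100)))
  ev2 <- detect_events(pr, frac = 0.05)
  expect_true(ev2$closure_truncated)
  expect_equal(ev2$t_close, t[100])

  # two equal gape maxima: the earliest wins
  g <- rep(0.1, 100); g[40] <- 0.9; g[60] <- 0.9
  ev3 <- detect_events(fake_profile(t, gape = g), frac = 0.05)
  expect_equal(ev3$t_mg, t[40])

  # flat gape: no strike
  expect_error(detect_events(fake_profile(t, gape = rep(0.1, 100))),
               class = "strikekin_no_strike_error")
  expect_error(detect_events(run$profile, frac = 0.7),
               class = "strikekin_input_error")
})

test_that("gape phase maxima match the raised-cosine closed forms", {
  p <- quiet_params("aquatic", gape = list(amp = 0.8, rise = 0.030))
  run <- sim_profile(p)
  row <- extract_strike(run$profile)
  expect_lt(abs(row$MSGO / (pi * 0.8 / (2 * 0.030)) - 1), 0.01)
  # the onset corner is rounded by the spline: allow 10% on the acceleration
  expect_lt(abs(row$MAGO / (pi^2 * 0.8 / (2 * 0.030^2)) - 1), 0.10)
})

test_that("reversing rise and fall swaps opening and closing extrema", {
  pa <- quiet_params("aquatic", gape = list(rise = 0.030, fall = 0.050))
  pb <- quiet_params("aquatic", gape = list(rise = 0.050, fall = 0.030))
  ra <- extract_strike(sim_profile(pa)$profile)
  rb <- extract_strike(sim_profile(pb)$profile)
  expect_equal(ra$MSGO, rb$MSGC, tolerance = 0.02)
  expect_equal(ra$MSGC, rb$MSGO, tolerance = 0.02)
})

test_that("constant hyoid signals give zero excursion and zero phase maxima", {
  p <- quiet_params("aquatic",
                    hyoid1 = list(amp = 0), hyoid2 = list(amp = 0))
  row <- extract_strike(sim_profile(p)$profile)
  expect_lt(row$Mhd1, 1e-4)
  expect_lt(row$Mhd2, 1e-4)
  expect_lt(row$MSDhd1, 1e-2)
})

test_that("tongue extraction restricts the hyoid cycle to after peak protraction", {
  p <- quiet_params("terrestrial")
  run <- sim_profile(p, individual = "T1")
  row <- extract_strike(run$profile)
  expect_lt(abs(row$TMTgP - run$truth$TMTgP), 2 / p$fps)
  expect_lt(abs(row$MTgP / run$truth$MTgP - 1), 0.02)
  # all 32 variables + HA0 present
  expect_true(all(c(kin_vars_common, kin_vars_tongue, "HA0") %in% names(row)))

  # hyoid bump entirely before peak tongue protraction is excluded
  early <- quiet_params("terrestrial",
                        hyoid1 = list(onset = 0.015, rise = 0.020, fall = 0.030))
  run_e <- sim_profile(early, individual = "T1")
  row_e <- extract_strike(run_e$profile)
  expect_lt(row_e$Mhd1, 0.05 * early$hyoid1$amp)
  # the unrestricted computation would have seen the full bump
  ev <- detect_events(run_e$profile)
  unrestricted <- extract_common(run_e$profile, ev)
  expect_gt(unrestricted[["Mhd1"]], 0.9 * early$hyoid1$amp)

  # aquatic records carry no tongue fields
  aq <- extract_strike(sim_profile(quiet_params("aquatic"))$profile)
  expect_false(any(kin_vars_tongue %in% names(aq)))
  expect_error(extract_tongue(sim_profile(quiet_params("aquatic"))$profile,
                              detect_events(sim_profile(quiet_params("aquatic"))$profile)),
               class = "strikekin_configuration_error")
})

test_that("event ordering and equivariances hold on noiseless strikes", {
  run <- sim_profile(quiet_params("aquatic"))
  row <- extract_strike(run$profile)
  expect_true(0 <= row$TMG && row$TMG <= row$DG && row$DG <= row$PCD)

  # scale equivariance: multiplying coordinates by c scales lengths, speeds,
  # accelerations by c; timings and angles unchanged
  c_ <- 2.5
  scaled <- run$series
  for (lm in scaled$landmarks) {
    scaled$coords[[lm]]$x <- scaled$coords[[lm]]$x * c_
    scaled$coords[[lm]]$y <- scaled$coords[[lm]]$y * c_
  }
  row_s <- extract_strike(build_profile(scaled, "aquatic"))
  for (v in c("MG", "Mhd1", "Mhd2", "MSGO", "MAGO", "MSDhd1", "MAEhd2")) {
    expect_equal(row_s[[v]], c_ * row[[v]], tolerance = 1e-6)
  }
  for (v in c("TMG", "DG", "TMhd1", "PCD", "MGA", "MHA", "HA0")) {
    expect_equal(row_s[[v]], row[[v]], tolerance = 1e-6)
  }
})

test_that("halving the frame rate doubles timings, halves speeds, quarters accelerations", {
  p <- quiet_params("aquatic")
  raw <- simulate_strike(p, "v")$series
  m1 <- video_meta("v", "A1", "aquatic", "substrate", fps = 1000, scale = 100)
  m2 <- video_meta("v", "A1", "aquatic", "substrate", fps = 500, scale = 100)
  r1 <- extract_strike(build_profile(calibrate(raw, m1), "aquatic"))
  r2 <- extract_strike(build_profile(calibrate(raw, m2), "aquatic"))
  expect_equal(r2$TMG, 2 * r1$TMG, tolerance = 1e-9)
  expect_equal(r2$PCD, 2 * r1$PCD, tolerance = 1e-9)
  expect_equal(r2$MSGO, r1$MSGO / 2, tolerance = 1e-9)
  expect_equal(r2$MAGO, r1$MAGO / 4, tolerance = 1e-9)
  expect_equal(r2$MG, r1$MG, tolerance = 1e-9)
})

test_that("extract_table assembles per-medium tables and flags failures", {
  dir <- withr::local_tempdir()
  des <- study_design(
    tibble::tibble(individual_id = rep(c("A1", "A2"), each = 2),
                   medium = "aquatic",
                   presentation = rep(c("substrate", "tweezers"), 2),
                   n = 2),
    base_overrides = list(noise_sd = 0.3,
                          likelihood = list(base = 0.95, dropout = 0,
                                            dropout_shift_px = 0))
  )
  out <- simulate_study(des, seed = 5, level = "videos", dir = dir)
  # poison one file so its row is flagged, not dropped
  writeLines("garbage", file.path(dir, paste0(out$manifest$video_id[3], ".csv")))
  tabs <- suppressWarnings(extract_table(dir, out$manifest))
  expect_equal(nrow(tabs$aquatic), 8)
  expect_equal(nrow(tabs$terrestrial), 0)
  expect_equal(sum(!tabs$aquatic$ok), 1)
  expect_true(all(is.na(tabs$aquatic$MG[!tabs$aquatic$ok])))
  expect_true(all(is.finite(tabs$aquatic$MG[tabs$aquatic$ok])))
  # empty manifest: empty tables with the full header
  empty <- suppressWarnings(extract_table(dir, out$manifest[0, ]))
  expect_equal(nrow(empty$aquatic), 0)
  expect_true(all(c(kin_vars_common, "HA0") %in% names(empty$aquatic)))
  expect_true(all(c(kin_vars_common, kin_vars_tongue) %in% names(empty$terrestrial)))
})
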