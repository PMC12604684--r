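#' Landmark time series for one video
#'
#' A `landmark_series` holds, for each tracked body part, the per-frame
#' `(x, y, likelihood)` triplets produced by a markerless pose estimator.
#' Coordinates are in pixels (frames as time base) until [calibrate()] is
#' applied, after which they are in centimetres with a time column in seconds.
#'
#' @param video_id Character scalar identifying the video.
#' @param coords Named list, one element per landmark, each a data frame with
#'   numeric columns `x`, `y`, `likelihood`. All landmarks must have the same
#'   number of frames and likelihoods must lie in `[0, 1]` (NA allowed to mark
#'   tracking gaps).
#'
#' @return An object of class `landmark_series`.
#' @export
landmark_series <- function(video_id, coords) {
  if (!is.character(video_id) || length(video_id) != 1) {
    stop_strikekin("`video_id` must be a single string.", "input_error")
  }
  nm <- names(coords)
  if (is.null(nm) || anyDuplicated(nm)) {
    stop_strikekin("Landmark names must be unique and non-empty.", "input_error")
  }
  n <- nrow(coords[[1]])
  if (n < 2) stop_strikekin("A landmark series needs at least 2 frames.", "input_error")
  for (lm in nm) {
    df <- coords[[lm]]
    if (!all(c("x", "y", "likelihood") %in% names(df))) {
      stop_strikekin(
        sprintf("Landmark '%s' must have x, y and likelihood columns.", lm),
        "format_error"
      )
    }
    if (nrow(df) != n) {
      stop_strikekin(
        sprintf("Landmark '%s' has %d frames; expected %d.", lm, nrow(df), n),
        "input_error"
      )
    }
    lik <- df$likelihood
    if (any(lik < 0 | lik > 1, na.rm = TRUE)) {
      stop_strikekin(
        sprintf("Landmark '%s' has likelihoods outside [0, 1].", lm),
        "input_error"
      )
    }
    coords[[lm]] <- tibble::as_tibble(df[c("x", "y", "likelihood")])
  }
  structure(
    list(video_id = video_id, landmarks = nm, n = n, coords = coords,
         calibrated = FALSE, t = NULL, meta = NULL),
    class = "landmark_series"
  )
}

#' @export
print.landmark_series <- function(x, ...) {
  cat(sprintf(
    "<landmark_series> %s: %d frames, %d landmarks (%s)%s\n",
    x$video_id, x$n, length(x$landmarks),
    paste(x$landmarks, collapse = ", "),
    if (isTRUE(x$calibrated)) " [calibrated: cm, s]" else " [pixels, frames]"
  ))
  invisible(x)
}

#' Read a DeepLabCut-dialect landmark CSV
#'
#' Parses the three-row header (`scorer` / `bodyparts` / `coords`) followed by
#' one row per frame with `x`, `y`, `likelihood` columns per body part. Empty
#' cells are recorded as `NA` (tracking gaps).
#'
#' @param path Path to the CSV file.
#' @param video_id Video identifier; defaults to the file name without
#'   extension.
#'
#' @return A [landmark_series()].
#' @export
read_dlc_csv <- function(path, video_id = NULL) {
  if (!file.exists(path)) {
    stop_strikekin(sprintf("File not found: %s", path), "input_error")
  }
  lines <- readLines(path)
  if (length(lines) < 4) {
    stop_strikekin("DLC CSV needs 3 header rows plus at least one frame.", "format_error")
  }
  hdr <- strsplit(lines[1:3], ",", fixed = TRUE)
  labels <- vapply(hdr, `[`, character(1), 1)
  expected <- c("scorer", "bodyparts", "coords")
  bad <- which(tolower(labels) != expected)
  if (length(bad)) {
    stop_strikekin(
      sprintf("Malformed DLC header: row %d should start with '%s', found '%s'.",
              bad[1], expected[bad[1]], labels[bad[1]]),
      "format_error"
    )
  }
  parts <- hdr[[2]][-1]
  coords_row <- hdr[[3]][-1]
  if (length(parts) != length(coords_row)) {
    stop_strikekin("Malformed DLC header: bodyparts row and coords row differ in length.",
                   "format_error")
  }
  body <- read.csv(path, skip = 3, header = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (ncol(body) != length(parts) + 1) {
    stop_strikekin("Data rows do not match the header column count.", "format_error")
  }
  lm_names <- unique(parts)
  coords <- list()
  for (lm in lm_names) {
    idx <- which(parts == lm)
    have <- coords_row[idx]
    if (!identical(sort(have), sort(c("x", "y", "likelihood")))) {
      stop_strikekin(
        sprintf("Landmark '%s' must have exactly x, y and likelihood columns (found: %s).",
                lm, paste(have, collapse = ", ")),
        "format_error"
      )
    }
    cols <- lapply(c("x", "y", "likelihood"), function(w) {
      raw <- body[[idx[which(have == w)] + 1]]
      raw[raw == ""] <- NA_character_
      val <- suppressWarnings(as.numeric(raw))
      bad <- which(!is.na(raw) & is.na(val))
      if (length(bad)) {
        stop_strikekin(
          sprintf("Non-numeric %s value for landmark '%s' at frame %d: '%s'.",
                  w, lm, bad[1] - 1, raw[bad[1]]),
          "parse_error"
        )
      }
      val
    })
    coords[[lm]] <- tibble::tibble(x = cols[[1]], y = cols[[2]], likelihood = cols[[3]])
  }
  landmark_series(video_id %||% sub("\\.[^.]*$", "", basename(path)), coords)
}

#' Write a landmark series as a DeepLabCut-dialect CSV
#'
#' @param series A [landmark_series()] (in pixel units).
#' @param path Output path.
#' @param scorer Scorer name written in the first header row.
#' @return `path`, invisibly.
#' @export
write_dlc_csv <- function(series, path, scorer = "strikekin") {
  stopifnot(inherits(series, "landmark_series"))
  nlm <- length(series$landmarks)
  h1 <- c("scorer", rep(scorer, 3 * nlm))
  h2 <- c("bodyparts", rep(series$landmarks, each = 3))
  h3 <- c("coords", rep(c("x", "y", "likelihood"), nlm))
  mat <- do.call(cbind, lapply(series$coords, function(df) {
    cbind(df$x, df$y, df$likelihood)
  }))
  body <- cbind(0:(series$n - 1), mat)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste(h1, collapse = ","),
               paste(h2, collapse = ","),
               paste(h3, collapse = ",")), con)
  write.table(format(body, digits = 15, trim = TRUE, scientific = FALSE),
              con, sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE,
              na = "")
  invisible(path)
}

#' Repair low-likelihood frames by interpolation
#'
#' Frames whose tracker likelihood is at or below `threshold` (or whose
#' coordinates are missing) are replaced by linear interpolation between the
#' nearest flanking frames above threshold; leading/trailing sub-threshold
#' runs are held constant at the nearest reliable value. The pipeline needs
#' equispaced samples for the smoothing-spline and differencing stages, so
#' frames are repaired rather than dropped.
#'
#' @param series A [landmark_series()].
#' @param threshold Likelihood cut-off in `[0, 1)`; frames with
#'   `likelihood <= threshold` are replaced. Default 0.9.
#'
#' @return The gated series; the number of replaced frames per landmark is
#'   available via `attr(, "n_replaced")`.
#' @export
gate_likelihood <- function(series, threshold = 0.9) {
  stopifnot(inherits(series, "landmark_series"))
  if (threshold < 0 || threshold >= 1) {
    stop_strikekin("`threshold` must be in [0, 1).", "input_error")
  }
  idx <- seq_len(series$n)
  n_replaced <- integer(length(series$landmarks))
  names(n_replaced) <- series$landmarks
  for (lm in series$landmarks) {
    df <- series$coords[[lm]]
    ok <- !is.na(df$likelihood) & df$likelihood > threshold &
      !is.na(df$x) & !is.na(df$y)
    if (!any(ok)) {
      stop_strikekin(
        sprintf("Landmark '%s' has no frames above likelihood %.3g.", lm, threshold),
        "unusable_landmark_error"
      )
    }
    if (all(ok)) next
    df$x <- approx(idx[ok], df$x[ok], xout = idx, rule = 2)$y
    df$y <- approx(idx[ok], df$y[ok], xout = idx, rule = 2)$y
    n_replaced[lm] <- sum(!ok)
    series$coords[[lm]] <- df
  }
  attr(series, "n_replaced") <- n_replaced
  series
}

#' Per-video metadata
#'
#' @param video_id,individual_id Identifiers.
#' @param medium `"aquatic"` or `"terrestrial"`.
#' @param presentation Prey presentation method: `"substrate"` or `"tweezers"`.
#' @param capture_type `"suction"`, `"tongue"` or `"jaw"`.
#' @param fps Recording frame rate (frames/second), default 1000.
#' @param scale Spatial calibration in pixels per centimetre (from the
#'   0.5 cm checkerboard background).
#' @param svl_cm Optional snout-vent length (cm), a body-size proxy.
#'
#' @return A one-row tibble.
#' @export
video_meta <- function(video_id, individual_id, medium, presentation,
                       capture_type = if (medium == "aquatic") "suction" else "tongue",
                       fps = 1000, scale = 100, svl_cm = NA_real_) {
  medium <- match.arg(medium, c("aquatic", "terrestrial"))
  presentation <- match.arg(presentation, c("substrate", "tweezers"))
  capture_type <- match.arg(capture_type, c("suction", "tongue", "jaw"))
  if (fps <= 0) stop_strikekin("`fps` must be positive.", "input_error")
  if (scale <= 0) stop_strikekin("`scale` must be positive.", "input_error")
  tibble::tibble(video_id = video_id, individual_id = individual_id,
                 medium = medium, presentation = presentation,
                 capture_type = capture_type, fps = fps, scale = scale,
                 svl_cm = svl_cm)
}

#' Read / write a video manifest
#'
#' The manifest is a plain CSV with one row per video and the columns of
#' [video_meta()]. DLC landmark CSVs carry no metadata, so frame rate, scale,
#' individual and condition labels travel in this side file.
#'
#' @param path CSV path.
#' @return A tibble (one row per video).
#' @export
read_manifest <- function(path) {
  df <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  if ("svl_cm" %in% names(df)) df$svl_cm <- as.numeric(df$svl_cm)
  validate_manifest(df)
}

#' @rdname read_manifest
#' @param manifest Manifest tibble.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

validate_manifest <- function(manifest) {
  need <- c("video_id", "individual_id", "medium", "presentation",
            "capture_type", "fps", "scale")
  miss <- setdiff(need, names(manifest))
  if (length(miss)) {
    stop_strikekin(sprintf("Manifest is missing columns: %s.",
                           paste(miss, collapse = ", ")), "format_error")
  }
  if (anyDuplicated(manifest$video_id)) {
    stop_strikekin("Manifest video_ids must be unique.", "input_error")
  }
  if (any(manifest$fps <= 0) || any(manifest$scale <= 0)) {
    stop_strikekin("Manifest fps and scale must be positive.", "input_error")
  }
  tibble::as_tibble(manifest)
}

#' Calibrate a landmark series to centimetres and seconds
#'
#' Divides pixel coordinates by the pixels-per-cm scale and attaches a time
#' vector `t = frame / fps` (0-based, so the first frame is t = 0).
#'
#' @param series A [landmark_series()] in pixel units.
#' @param meta A one-row manifest entry ([video_meta()]) carrying `fps` and
#'   `scale`.
#' @return The calibrated series.
#' @export
calibrate <- function(series, meta) {
  stopifnot(inherits(series, "landmark_series"))
  if (meta$scale <= 0 || meta$fps <= 0) {
    stop_strikekin("`scale` and `fps` must be positive.", "input_error")
  }
  for (lm in series$landmarks) {
    series$coords[[lm]]$x <- series$coords[[lm]]$x / meta$scale
    series$coords[[lm]]$y <- series$coords[[lm]]$y / meta$scale
  }
  series$t <- (seq_len(series$n) - 1) / meta$fps
  series$calibrated <- TRUE
  series$meta <- tibble::as_tibble(meta)
  series
}

#' Long-format view of a landmark series
#'
#' @param series A [landmark_series()].
#' @return A tibble with columns `video_id`, `landmark`, `frame`, (`t_s` if
#'   calibrated), `x`, `y`, `likelihood`.
#' @export
landmark_long <- function(series) {
  stopifnot(inherits(series, "landmark_series"))
  out <- do.call(rbind, lapply(series$landmarks, function(lm) {
    df <- series$coords[[lm]]
    tibble::tibble(video_id = series$video_id, landmark = lm,
                   frame = seq_len(series$n) - 1L,
                   x = df$x, y = df$y, likelihood = df$likelihood)
  }))
  if (isTRUE(series$calibrated)) {
    out$t_s <- series$t[out$frame + 1L]
    out <- out[c("video_id", "landmark", "frame", "t_s", "x", "y", "likelihood")]
  }
  out
}
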