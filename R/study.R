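# parameters that vary between individuals / videos (multiplicative, log-normal)
jitter_keys <- c("gape_amp", "gape_rise", "gape_fall",
                 "hyoid1_amp", "hyoid1_rise", "hyoid1_fall",
                 "hyoid2_amp", "hyoid2_rise", "hyoid2_fall",
                 "tongue_amp", "tongue_rise", "tongue_fall",
                 "head_excursion")

#' Design of a simulated feeding study
#'
#' Describes a multi-individual, two-condition feeding experiment from which
#' [simulate_study()] draws strikes: per-cell video counts, the multiplicative
#' condition effects applied to strike parameters under each presentation
#' level, and the between-individual and residual (between-video) variation
#' of the strike parameters on the log scale.
#'
#' @param cells Tibble with columns `individual_id`, `medium`,
#'   `presentation`, `n` (videos per cell).
#' @param effects Named list: for a presentation level, a named vector of
#'   multipliers on strike parameters (keys like `"gape_amp"`, `"gape_rise"`,
#'   `"head_excursion"`; see `strikekin:::jitter_keys`) plus optionally
#'   `"head_angle0"` as an additive shift in degrees. Levels not listed get
#'   no effect.
#' @param sd_ind Between-individual SD of log parameter multipliers
#'   (default 0.08).
#' @param sd_resid Between-video (residual) SD of log multipliers
#'   (default 0.06).
#' @param sd_angle_ind,sd_angle_resid SDs (degrees) of the additive
#'   individual and residual variation of the resting head angle.
#' @param base_overrides Named list of [strike_params()] overrides applied to
#'   every video (e.g. `list(noise_sd = 0)`).
#' @return A `study_design` object.
#' @export
study_design <- function(cells, effects = list(), sd_ind = 0.08,
                         sd_resid = 0.06, sd_angle_ind = 2,
                         sd_angle_resid = 1.5, base_overrides = list()) {
  cells <- tibble::as_tibble(cells)
  need <- c("individual_id", "medium", "presentation", "n")
  if (!all(need %in% names(cells))) {
    stop_strikekin("`cells` needs individual_id, medium, presentation, n.",
                   "parameter_error")
  }
  if (any(cells$n <= 0)) {
    stop_strikekin("Every design cell needs a positive number of videos.",
                   "parameter_error")
  }
  if (length(unique(cells$individual_id)) < 2 ||
      length(unique(cells$presentation)) < 2) {
    stop_strikekin("A study needs at least 2 individuals and 2 conditions.",
                   "parameter_error")
  }
  structure(list(cells = cells, effects = effects, sd_ind = sd_ind,
                 sd_resid = sd_resid, sd_angle_ind = sd_angle_ind,
                 sd_angle_resid = sd_angle_resid,
                 base_overrides = base_overrides),
            class = "study_design")
}

apply_multipliers <- function(params, mult, angle_shift = 0) {
  p <- unclass(params)
  for (key in names(mult)) {
    parts <- strsplit(key, "_", fixed = TRUE)[[1]]
    comp <- parts[1]; field <- paste(parts[-1], collapse = "_")
    if (comp == "head" && field == "excursion") {
      p$head$excursion <- p$head$excursion * mult[[key]]
    } else if (!is.null(p[[comp]])) {
      p[[comp]][[field]] <- p[[comp]][[field]] * mult[[key]]
    }
  }
  p$head$angle0 <- p$head$angle0 + angle_shift
  class(p) <- "strike_params"
  validate_strike_params(p)
  p
}

#' Simulate a whole feeding study
#'
#' Draws per-video strike parameters as population default x individual
#' offset x condition effect x residual video variation (log-normal
#' multipliers, clamped to `[0.6, 1.6]` so pulses always fit the clip), and
#' returns the study's manifest together with either the closed-form strike
#' variables of every video (`level = "variables"`, the fast path used to
#' validate the statistics layer) or rendered DLC landmark CSVs
#' (`level = "videos"`).
#'
#' The generating effects are returned so that downstream statistics can be
#' checked for type-I error (no effects) and power/direction (planted
#' effects).
#'
#' @param design A [study_design()].
#' @param seed Integer seed.
#' @param level `"variables"` or `"videos"`.
#' @param dir Output directory for `level = "videos"`.
#' @param frac Cycle tolerance for the truth/extraction conventions.
#' @return List with `manifest`, `variables` (truth-level strike variables,
#'   one row per video, with metadata columns), `params` (per-video
#'   [strike_params()]), `effects`, and for `level = "videos"` the emitted
#'   `paths`.
#' @export
simulate_study <- function(design, seed = 1, level = c("variables", "videos"),
                           dir = NULL, frac = 0.05) {
  stopifnot(inherits(design, "study_design"))
  level <- match.arg(level)
  if (level == "videos" && is.null(dir)) {
    stop_strikekin("`dir` is required when emitting videos.", "parameter_error")
  }
  withr::with_seed(seed, simulate_study_impl(design, level, dir, frac))
}

simulate_study_impl <- function(design, level, dir, frac) {
  cells <- design$cells
  inds <- unique(cells$individual_id)
  ind_mult <- lapply(inds, function(i) {
    setNames(exp(rnorm(length(jitter_keys), 0, design$sd_ind)), jitter_keys)
  })
  names(ind_mult) <- inds
  ind_angle <- setNames(rnorm(length(inds), 0, design$sd_angle_ind), inds)

  manifest <- list(); vars <- list(); params_list <- list(); paths <- c()
  vid <- 0
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    eff <- design$effects[[cell$presentation]] %||% c()
    eff_angle <- if ("head_angle0" %in% names(eff)) eff[["head_angle0"]] else 0
    eff <- eff[setdiff(names(eff), "head_angle0")]
    base <- do.call(strike_params,
                    c(list(medium = cell$medium), design$base_overrides))
    for (k in seq_len(cell$n)) {
      vid <- vid + 1
      video_id <- sprintf("%s_%s_%02d", cell$individual_id, cell$presentation, k)
      mult <- ind_mult[[cell$individual_id]] *
        exp(rnorm(length(jitter_keys), 0, design$sd_resid))
      full_eff <- setNames(rep(1, length(jitter_keys)), jitter_keys)
      full_eff[names(eff)] <- eff
      mult <- pmin(pmax(mult * full_eff, 0.6), 1.6)
      angle_shift <- ind_angle[[cell$individual_id]] + eff_angle +
        rnorm(1, 0, design$sd_angle_resid)
      p <- apply_multipliers(base, mult, angle_shift)
      if (cell$medium == "terrestrial") p <- couple_hyoid_to_tongue(p, base)
      params_list[[video_id]] <- p
      manifest[[video_id]] <- video_meta(
        video_id, cell$individual_id, cell$medium, cell$presentation,
        capture_type = if (cell$medium == "aquatic") "suction" else "tongue",
        fps = p$fps, scale = p$scale
      )
      tr <- strike_truth(p, frac = frac)
      tr$video_id <- video_id
      vars[[video_id]] <- tr
      if (level == "videos") {
        sim <- simulate_strike(p, video_id = video_id, frac = frac)
        path <- file.path(dir, paste0(video_id, ".csv"))
        write_dlc_csv(sim$series, path)
        paths <- c(paths, path)
      }
    }
  }
  manifest <- do.call(rbind, manifest)
  add_meta <- function(df) {
    df$individual_id <- manifest$individual_id[match(df$video_id, manifest$video_id)]
    df$medium <- manifest$medium[match(df$video_id, manifest$video_id)]
    df$presentation <- manifest$presentation[match(df$video_id, manifest$video_id)]
    common <- intersect(c("video_id", "individual_id", "medium", "presentation",
                          kin_vars_common, kin_vars_tongue, "HA0"), names(df))
    df[common]
  }
  variables <- add_meta(rbind_fill(vars))
  out <- list(manifest = manifest, variables = variables,
              params = params_list, effects = design$effects)
  if (level == "videos") out$paths <- paths
  out
}

# In tongue feeders the hyoid cycle is driven by tongue retraction: keep each
# video's hyoid onset at its template lag after that video's peak protraction,
# so the cycle always starts after the peak whatever the jitter drew.
couple_hyoid_to_tongue <- function(p, base) {
  base_peak <- base$tongue$onset + base$tongue$rise
  peak <- p$tongue$onset + p$tongue$rise
  q <- unclass(p)
  for (h in c("hyoid1", "hyoid2")) {
    lag <- base[[h]]$onset - base_peak
    q[[h]]$onset <- peak + lag
  }
  class(q) <- "strike_params"
  validate_strike_params(q)
  q
}

# rbind tibbles with possibly different columns (aquatic vs terrestrial rows)
rbind_fill <- function(dfs) {
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (c in setdiff(cols, names(d))) d[[c]] <- NA_real_
    d[cols]
  }))
}

#' Video counts of the motivating axolotl / tiger-salamander study
#'
#' Per-individual video counts of the two-condition feeding experiment the
#' package is modelled on: five aquatic axolotls (suction feeding) and five
#' terrestrial tiger salamanders (tongue/jaw prehension), each filmed taking
#' prey presented on the substrate and prey suspended from tweezers. Summed,
#' the aquatic set has 23 substrate and 31 tweezers videos, the terrestrial
#' set 20 and 31.
#'
#' @param medium `"aquatic"`, `"terrestrial"` or `"both"`.
#' @param ... Passed to [study_design()] (effects, variation SDs, overrides).
#' @return A [study_design()] with those cell counts.
#' @export
ambystoma_study_design <- function(medium = c("aquatic", "terrestrial", "both"),
                                   ...) {
  medium <- match.arg(medium)
  aq <- tibble::tibble(
    individual_id = rep(paste0("A", 1:5), 2),
    medium = "aquatic",
    presentation = rep(c("substrate", "tweezers"), each = 5),
    n = c(5, 5, 4, 5, 4, 6, 6, 7, 6, 6)
  )
  te <- tibble::tibble(
    individual_id = rep(paste0("T", 1:5), 2),
    medium = "terrestrial",
    presentation = rep(c("substrate", "tweezers"), each = 5),
    n = c(3, 5, 4, 4, 4, 3, 7, 6, 6, 9)
  )
  cells <- switch(medium, aquatic = aq, terrestrial = te, both = rbind(aq, te))
  study_design(cells, ...)
}

#' Jaw-prehension counts of the terrestrial individuals
#'
#' Number of terrestrial sequences ending in jaw prehension (the tongue
#' failed and the jaws ensured the capture) out of the total number of
#' sequences, per individual and prey presentation method.
#'
#' @return A tibble with per-individual counts.
#' @export
jaw_prehension_counts <- function() {
  tibble::tibble(
    individual_id = paste0("T", 1:5),
    tweezers_jaw = c(0L, 2L, 4L, 2L, 4L),
    tweezers_total = c(3L, 7L, 6L, 6L, 9L),
    substrate_jaw = c(0L, 1L, 0L, 0L, 0L),
    substrate_total = c(3L, 5L, 4L, 4L, 4L)
  )
}

#' Jaw-prehension rates by presentation method
#'
#' Pools the per-individual counts of [jaw_prehension_counts()] and reports
#' the percentage of sequences ending in jaw prehension under each prey
#' presentation method.
#'
#' @return A tibble with one row per presentation method: counts and percent.
#' @export
jaw_prehension_summary <- function() {
  cnt <- jaw_prehension_counts()
  tibble::tibble(
    presentation = c("tweezers", "substrate"),
    n_jaw = c(sum(cnt$tweezers_jaw), sum(cnt$substrate_jaw)),
    n_total = c(sum(cnt$tweezers_total), sum(cnt$substrate_total)),
    percent_jaw = 100 * n_jaw / n_total
  )
}
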