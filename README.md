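# strikekin

Feeding-strike kinematics from markerless landmark tracking.

Comparative studies of salamander feeding film strikes in lateral view at
1000 fps and track anatomical landmarks (jaw tips, jaw joint, hyoid, eye,
shoulder, tongue pad) with markerless pose estimators such as DeepLabCut.
`strikekin` is the downstream half of that workflow, for researchers who
have landmark CSVs and want defensible numbers out of them:

* **I/O and calibration** — read the DeepLabCut CSV dialect (three header
  rows: scorer / bodyparts / coords), repair low-likelihood frames by
  interpolation, convert pixels and frames to centimetres and seconds via a
  per-video manifest.
* **Kinematic signals** — cubic smoothing splines at a target effective
  degrees of freedom (df = 80 by default, matched by the smoother-matrix
  trace), then frame-by-frame distances
  (`d = sqrt((x_A-x_B)^2 + (y_A-y_B)^2)`), law-of-cosines angles, and
  forward-difference speeds and accelerations.
* **Strike variables** — event detection (onset, maximum gape, closure,
  hyoid maxima and return, peak tongue protraction) and the standard 25
  common + 7 tongue scalar variables (`MG`, `TMG`, `MGA`, `DG`, `MSGO`,
  `MAGO`, ..., `MTgP`, ..., plus `HA0`), with terrestrial hyoid variables
  restricted to after peak tongue protraction, as tongue-hyoid linkage
  demands.
* **Statistics** — type II MANOVA with Pillai's trace
  (`V = tr(H (H+E)^-1)`, ridge-regularised error SSCP, Freedman–Lane
  permutation null), pairwise post-hoc Pillai tests, per-variable
  random-intercept mixed-model contrasts with within-individual permutation
  p-values, correlation-matrix PCA with variable contributions, type II
  ANOVA on PC1, per-group disparity with bootstrap + Wilcoxon comparison,
  and a Mahalanobis-distance QQ normality diagnostic.
* **Synthetic strikes** — a generator that builds landmark videos from
  raised-cosine motion pulses through an explicit jaw/hyoid/head geometry,
  with exact closed-form ground truth for every strike variable (e.g.
  maximum opening speed `pi*A/(2*tau)`), so the entire pipeline is testable
  against known answers.

## Worked example

Simulate one noisy aquatic strike, run it through the full pipeline, and
compare with the generator's closed-form truth:

```r
library(strikekin)

p    <- strike_params("aquatic", seed = 11)      # 1000 fps, 100 px/cm, 0.5 px noise
sim  <- simulate_strike(p, "demo")
meta <- video_meta("demo", "A1", "aquatic", "tweezers")
prof <- build_profile(calibrate(gate_likelihood(sim$series), meta), "aquatic")
extract_strike(prof)[c("MG", "TMG", "MGA", "DG", "MSGO", "Mhd1", "PCD", "HA0")]
#>      MG   TMG    MGA    DG   MSGO  Mhd1   PCD     HA0
#> 1 0.883 0.041 43.239 0.083 41.959 0.501 0.147 100.105
sim$truth[c("MG", "TMG", "MGA", "DG", "MSGO", "Mhd1", "PCD", "HA0")]
#>     MG  TMG   MGA    DG   MSGO Mhd1   PCD HA0
#> 1 0.88 0.04 43.02 0.083 41.888  0.5 0.147 100
```

`MG` is the maximum gape distance (cm), `TMG` the time to reach it (s),
`MSGO` the maximum jaw-opening speed (cm/s), `PCD` the whole prey-capture
duration (s), `HA0` the head angle at onset (degrees): the noisy extraction
lands within a fraction of a percent / one frame of the truth.

Simulate a whole two-condition study in which suspended prey widens and
slows the gape, then test it:

```r
des <- ambystoma_study_design(
  "aquatic",
  effects = list(tweezers = c(gape_amp = 1.35, gape_rise = 1.10,
                              gape_fall = 1.10, head_excursion = 1.20))
)
v  <- simulate_study(des, seed = 11, level = "variables")$variables
manova_typeII(v, kin_vars_common, c("presentation", "individual_id"),
              B = 999, seed = 11)
#>                         term df    pillai p_value
#> 1               presentation  1 0.9432963   0.001
#> 2              individual_id  4 3.0247183   0.001
#> 3 presentation:individual_id  4 1.0521472   0.716
lmm_contrast(v$MG, v$presentation, v$individual_id, B = 999, seed = 11)
#>   estimate     se t_wald p_perm
#> 1    0.266 0.0144 18.509  0.001
```

The presentation effect and the (simulated) individual differences are
detected; their interaction, which was not planted, is not. The contrast
says tweezers-presented strikes open the mouth 0.27 cm wider on average.

A thin command-line wrapper is available at `inst/cli/strikekin.R`
(`simulate` a study design to DLC CSVs; `extract` a variables table from a
directory + manifest).

## Limitations

Maximum-acceleration variables inherit a substantial upward noise bias from
the max-of-double-forward-difference procedure (see the methods vignette,
`vignettes/strike-kinematics.Rmd`); amplitudes, timings and most speed
maxima are recovered to within ~1% / 1 frame at realistic tracker noise.
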