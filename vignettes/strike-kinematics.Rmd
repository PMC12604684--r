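---
title: "From landmark tracks to feeding-strike statistics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From landmark tracks to feeding-strike statistics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strikekin)
```

## The problem

Salamander feeding strikes — suction feeding in water, tongue or jaw
prehension on land — are conventionally quantified from lateral-view
high-speed video (1000 fps) by tracking anatomical landmarks: eye (`e`),
upper and lower jaw tips (`uj`, `lj`), jaw joint (`jj`), anterior and
posterior hyoid (`hd1`, `hd2`), shoulder (`sh`) and, on land, the tongue pad
(`tg`). Markerless pose estimators such as DeepLabCut emit these tracks as
CSVs with per-frame `(x, y, likelihood)` per body part. `strikekin` turns
such tracks into the standard scalar description of a strike — 25 variables
common to aquatic and terrestrial feeding plus 7 tongue variables — and runs
the comparative statistics used to ask whether experimental conditions (how
the prey is presented, which individual is striking, which medium) shape the
kinematics.

## The measurement pipeline

The pipeline is deliberately plain and mirrors standard practice:

1. **Gating.** Frames whose tracker likelihood is at or below 0.9 (or with
   missing coordinates) are repaired by linear interpolation between the
   nearest reliable frames (leading/trailing runs held constant). Repair
   rather than deletion keeps the sampling equispaced, which the smoothing
   and differencing stages require. The threshold is configurable; 0.9 is
   the conventional adequacy cut-off for these trackers.
2. **Calibration.** Pixels become centimetres through the checkerboard scale
   (px/cm); frame `k` becomes `t = k / fps` seconds, 0-based.
3. **Smoothing.** Each coordinate series is smoothed with a cubic smoothing
   spline whose penalty is chosen so that the trace of the smoother matrix
   (the effective degrees of freedom) equals a target, 80 by default — the
   conventional setting for 1000 fps feeding sequences. All samples serve as
   knots so the full df range is reachable; for clips shorter than 84 frames
   the target is capped at `n - 4` with a warning. The df match is verified
   to 0.1.
4. **Signals.** From the smoothed coordinates, frame by frame: gape distance
   `d(uj, lj)`; gape angle at the jaw joint; hyoid-to-jaw-joint distances
   `d(hd1, jj)`, `d(hd2, jj)`; head angle at the eye between the upper jaw
   tip and the shoulder; and on land the tongue distance `d(tg, jj)`.
   Distances use the Euclidean formula; angles the law of cosines, with the
   arc-cosine argument clamped to `[-1, 1]` and a degeneracy floor of
   1e-9 cm on the arm lengths. All signals are invariant under translation,
   rotation and reflection of the image frame, which is why no axis flip is
   applied for the image convention of y growing downward.
5. **Derivatives.** Speeds are forward differences of the signals divided by
   the frame interval, accelerations forward differences of the speeds; each
   series is one sample shorter than its parent and timestamped at the left
   interval endpoint. Forward differencing (rather than analytic spline
   derivatives) is retained deliberately: it is the procedure the field's
   published numbers are based on.

## Events and strike variables

Clips are conventionally cropped to start at mouth opening, so strike onset
`t0` defaults to the first frame and resting baselines to the median of the
first five frames (a velocity-threshold onset mode is available for
uncropped clips, with baselines from the pre-onset frames). Cycle endpoints
need a tolerance because a smoothed, noisy signal never returns exactly to
baseline: a cycle starts/ends where the excursion from baseline crosses
`frac` of its peak, with `frac = 0.05` by default and exposed everywhere.
Mouth closure is the first time after maximum gape at which gape falls back
to within `frac` of its excursion; the event ends when both hyoid distances
are back within `frac` of their peak excursions ("hyoid return"); windows
that never close are truncated at the last frame and flagged. Ties at maxima
take the earliest frame.

From the events: amplitudes (`MG`, `MGA` as absolute maxima, since the mouth
at rest is nearly closed; `Mhd1`, `Mhd2`, `MTgP` as excursions from
baseline), times to maxima and cycle durations (`TMG`, `DG`, `TMhd*`,
`Dhd*`, `TMHA`, `PCD`, `TMTgP`, `TgD`), and phase-restricted extrema of the
derivative magnitudes: opening/depression/protraction phases run up to the
respective peak, closing/elevation/retraction after it. The phase
restriction resolves the signed-versus-magnitude ambiguity of "maximum
speed": within a monotone phase the two readings coincide. `HA0`, the head
angle at onset, is recorded for both media.

On land, tongue and hyoid movements are mechanically linked: the hyoid
depresses as the tongue retracts. Terrestrial hyoid variables are therefore
recomputed on the window after peak tongue protraction, and the hyoid
return (hence `PCD` and the head-angle window) follows the restricted
cycle. A snout-prey distance is computed only when a prey landmark is
supplied; none of the bundled analyses require it.

## The synthetic strike generator

Every stage above is validated against simulated strikes with closed-form
ground truth. Scalar signals are raised-cosine pulses
`w(u) = (1 - cos(pi u / tau)) / 2` on a resting baseline, rising over
`tau_rise` and falling over `tau_fall`; their extrema are analytic (peak
speed `pi A / (2 tau)`, peak acceleration `pi^2 A / (2 tau^2)`), which makes
the truth table exact. Landmarks are then placed by a two-bar jaw linkage
hinged at the jaw joint (so the gape distance and gape angle are reproduced
exactly), hyoid markers along a fixed axis from the jaw joint, the tongue
pad along the gape bisector, and a rigid head rotation about the eye
relative to the fixed shoulder (so the head angle is `angle0 + excursion *
w(t)` exactly). Coordinates are mapped to pixels (100 px/cm default),
Gaussian landmark noise added (0.5 px default), and likelihoods drawn from
a base-plus-dropout model so the gating stage has something to do.

Defaults emulate the recording regime of the motivating experiments: a
0.3 s aquatic strike (gape opening ~30 ms) and a slower 0.6 s terrestrial
strike whose hyoid cycle starts after peak tongue protraction. The study
simulator draws per-video parameters as population default x individual
offset x condition effect x residual video variation (log-normal
multipliers, SD 0.08 between individuals and 0.06 between videos by
default, clamped to `[0.6, 1.6]` so pulses always fit the clip; the resting
head angle varies additively in degrees). For terrestrial studies each
video's hyoid onset keeps its template lag after that video's tongue peak,
preserving the tongue-hyoid linkage under jitter. Condition effects are
specified as multipliers on generating parameters, so directional power
studies know the true sign of every induced difference.

What the generator does **not** emulate: prey motion, lunges and body
translation, perspective and parallax, tracker failure modes other than
frame-wise dropout, non-stationary baselines, and pulse shapes other than
the raised cosine. Passing the recovery tests therefore shows that the
extraction chain is faithful to a known smooth motion under realistic
tracker noise — not that every real strike is described this well.

## The statistics layer

- **Type II MANOVA with Pillai's trace.** Hypothesis SSCPs respect
  marginality (a main effect is tested after the other main effect, the
  interaction after both), the error SSCP comes from the full model, and
  Pillai's trace is `tr(H (H + E)^-1)`. With 25-32 variables on ~50 strikes
  the error SSCP can be singular or ill-conditioned, so `E` is
  ridge-regularised by `delta * tr(E)/k * I` with the smallest power of ten
  that makes it positive definite; the permutation null then self-calibrates
  the regularised statistic. Significance is assessed either parametrically
  (Pillai-to-F) or, by default, by Freedman-Lane permutation: residuals of
  the reduced model for each term are row-permuted, added back to the
  reduced fit, and the statistic recomputed identically, with
  `p = (b + 1) / (B + 1)` and `B = 5000` by default. Freedman-Lane is used
  rather than raw-row permutation because only reduced-model residuals are
  exchangeable in a multi-factor design. The univariate case collapses
  exactly to the type II ANOVA F test, which the test suite verifies to
  1e-8 against an independent implementation.
- **Post-hoc pairwise tests** run the same machinery per level pair on that
  pair's rows, the other factor retained where it still varies, with
  Bonferroni (default) or Holm correction.
- **Per-variable contrasts** fit `y ~ condition + (1 | individual)` by REML.
  The primary p-value permutes condition labels within individuals, ranking
  a GLS t statistic whose variance ratio is estimated once from the null
  model — fast, and valid because the statistic is recomputed identically
  for every relabelling. A Wald t with `N - m - 1` df is reported and
  labelled approximate; software-specific fractional df machinery is
  deliberately out of scope. Contrasts are two-sided.
- **PCA** standardises the 25 common variables (correlation-matrix PCA) and
  reports percent variance, loadings, and per-variable contributions
  (squared loading as a share of its axis, summing to 100 per axis) with
  the expected-average flag at `100/k` percent. A type II ANOVA tests
  presentation, medium and their interaction on PC1.
- **Disparity** is computed per group on the jointly standardised variable
  space (or on PCA scores): either the sum of column variances (default) or
  the median pairwise distance — the literature uses both, so both are
  implemented and results are labelled with the metric. Groups are compared
  by bootstrap (resampling rows within group) and a two-sided Wilcoxon
  rank-sum test between bootstrap distributions, Bonferroni-corrected.
- **Multinormality** is checked by a Mahalanobis-distance QQ diagnostic
  against chi-square quantiles, summarised by the Pearson correlation of
  the QQ pairs.

## Numerical choices and test scales

Permutation p-values are lower-bounded at `1/(B+1)` and reproducible under
a seed. The test suite and the acceptance script scale simulations to
desk size: null calibration uses 200-permutation MANOVAs on studies of the
motivating design's cell counts (54 aquatic strikes across 5 individuals),
with rejection rates checked against the binomial band around the nominal
level; directional power uses planted tweezers effects that widen and slow
the gape (amplitude x1.35, rise/fall x1.10, head excursion x1.20), chosen
to mirror the qualitative suction-feeding pattern: a wider, later, faster
opening when prey must be pulled off tweezers. Statistical validation runs
on the generator's closed-form variables directly — rendering thousands of
videos would test the renderer, not the statistics; the video-level path is
exercised separately by the recovery experiments.

## Known limitations

- **Maximum accelerations are the pipeline's weak point.** The maximum of a
  double forward difference of a smoothed noisy signal is biased upward: at
  0.5 px landmark noise, 100 px/cm and df 80, maximum-acceleration
  estimates run tens of percent high (and slow-phase speed maxima, e.g.
  hyoid elevation at ~10 cm/s, around 10-20% high), even though amplitudes
  and timings recover to <1% and ~1 frame. In noiseless data the remaining
  acceleration bias is the spline's rounding of the pulse's curvature
  corners (about -5% at onset; up to tens of percent where a closing phase
  begins at an asymmetric peak). Comparisons *between* conditions are much
  less affected (both arms share the bias), but absolute acceleration
  values should be read with this in mind.
- Event endpoints depend on the `frac` tolerance; durations are defined to,
  and only comparable at, a stated tolerance.
- The mixed-model Wald df is approximate by design; trust the permutation p.
- The disparity point values depend on the metric and the space
  (standardised variables vs PCA scores); results are labelled, and no
  equivalence with any particular published value is claimed.
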