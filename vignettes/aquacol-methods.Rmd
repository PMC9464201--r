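---
title: "Measuring aqueous outflow in episcleral veins: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring aqueous outflow in episcleral veins: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquacol)
```

## The measurement problem

Aqueous humor leaves the eye mostly through the conventional outflow
pathway and drains into episcleral veins, where it is visible under a
green-filtered slit lamp as a clear central stream — the *aqueous column* —
flanked by dark, hemoglobin-rich blood lanes (hemoglobin absorbs strongly
between 505 and 575 nm). A drug that lowers intraocular pressure by
reducing conventional-outflow resistance should widen that column. aquacol
implements the full quantitative chain for such hemoglobin video imaging
studies: video handling, blink-anchored segment selection, camera-shake
removal, cross-sectional width measurement, a temporal-autocorrelation
flow proxy, and the statistics of a two-sequence 2x2 crossover trial
comparing a Rho-kinase inhibitor (ripasudil) with a prostaglandin analog
(latanoprost).

Because no raw trial videos are publicly available, the package carries a
first-class synthetic-scene module with exact ground truth. Every
downstream stage is validated against that generator; the published
summary statistics enter only as the generator's default calibration and
as fixed inputs to the exactly recomputable baseline tests.

## The synthetic vein scene

`render_video()` draws frames from an analytic cross-section plus three
stochastic fields, all governed by one seed (rendering is a pure function
of `scene_params()`, bit-reproducible).

**Cross-sectional profile.** As a function of signed distance $d$ from
the vessel axis, the noiseless profile is piecewise $C^1$: a bright
aqueous core at $d = 0$, blood-lane minima at $d = \pm c/2$ (where $c$ is
the true column width), and a background plateau beyond the vessel
half-width $v/2$. Each minimum sits at the bottom of a *quadratic valley
that is even around the minimum*. This is the load-bearing construction:
Gaussian smoothing preserves even symmetry, so the smoothing built into
the width measurement cannot displace the minima, and the generator's
ground truth is exact rather than fitted. The valley half-width is
$\min(0.5\,\min(c/2, (v-c)/2),\ 8)$ px — capped so the valley stays steep
(curvature $\propto 1/\rho^2$) for wide vessels, which keeps per-frame
minima localization stable under sensor noise. Cubic Hermite segments
join the valley to the core peak and to the plateau with matched values
and slopes.

**Blood speckle.** The lanes carry a band-limited texture (white noise
smoothed to a chosen grain, default 2 px) that is advected along the axis
at the true flow speed and, independently, decorrelates frame-to-frame as
an AR(1) process (`speckle_turnover`, default 0.9). The turnover reflects
red-cell rearrangement in real flow; a frozen, purely advected pattern
would stay coherent across an entire clip, which real blood speckle does
not. The speckle weight is a smooth bump over each lane with a guard gap
of 35% of the lane width at both the lane minima and the vessel edge, so
the moving texture cannot perturb the ground-truth minima.

**Scleral background texture.** Outside the vessel a *static* fine-grained
texture stands in for episcleral surface detail (vessels, mottling). It is
dark-dominant — clamped at $-2.2$ sd below and $+0.6$ sd above the plateau —
because scleral vessels absorb strongly in green light while inter-vessel
brightness varies mildly; the asymmetric clamp also guarantees by
construction that the plateau never outshines the aqueous core and never
dips below the blood lanes, so the texture can anchor registration without
ever confusing the width measurement. The validation rule
`2.2 * amp < background - blood` enforces the latter bound.

**Blinks, jitter, noise.** Blinks are multiplicative global dimming by a
factor 0.3 (the pipeline only uses blinks as segment markers, so eyelid
geometry is not modeled). Camera shake is a per-frame global translation
drawn from $N(0, \sigma_j^2)$ per axis, applied analytically in scene
coordinates so the recorded shift trace is exact. Sensor noise is
additive, white, clipped to $[0, 1]$.

What the generator does *not* emulate: vessel curvature and branching,
illumination gradients, rolling-shutter and compression artifacts,
rotation, and depth-of-field blur. Passing tests demonstrate that the
algorithms recover known truth under controlled conditions; they do not
certify performance on clinical footage with those additional effects.

## Frame-rate handling and blink anchoring

Capture is nominally 4K at 60 fps; analysis uses 30 fps obtained by
dropping alternate frames. `subsample_alternate_frames()` keeps frames
with even 0-based index — which alternate frame the original workflow
dropped is not knowable, so the convention is fixed and documented rather
than inferred. Blink detection flags frames whose global mean intensity
falls below `dim_factor` (default 0.6) times a rolling median (default
window 31 frames); the rolling median makes the rule self-normalizing, so
constant or uniformly dark clips produce no events. Measurement segments
start at the first frame after a blink (offset 0: "immediately after
blinking" has no stated offset, so none is added), taking the earliest
blink that leaves room for a full 30-frame segment.

## Stabilization

`stabilize()` removes translation only. Slit-lamp shake is overwhelmingly
translational at these magnifications, and the width measurement is
itself translation-invariant when frame and line move together; rotation
correction is out of scope and listed as a limitation.

The estimator is built for scenes whose interior moves: a straight vessel
is translation-ambiguous along its own axis, and flowing speckle offers a
decoy alignment displaced by the flow. Three ingredients make the
estimate robust:

1. *Candidates, not a single peak.* Whitened cross-power (phase
   correlation, Hann-windowed) peaks plus the plain cross-correlation
   peak are collected as candidate integer shifts, and every candidate is
   scored by direct image agreement (mean squared difference over a fixed
   central region, averaging only samples that stay inside the frame).
2. *Sequential first pass.* Frame-to-frame shifts are estimated pairwise
   and accumulated, giving a trustworthy prior even for frames far from
   the reference; the accumulated prior is added to the candidate set.
3. *Median template second pass.* First-pass-aligned frames are reduced
   to a pixel-wise temporal median, which averages the moving speckle
   away; re-registering every frame against this template removes the
   speckle decoy entirely. Subpixel refinement is a parabolic fit on the
   local SSD surface.

The shift trace is reported relative to the reference frame (default: the
first frame of the segment, i.e. the frame right after the blink), where
it is exactly zero. Corrected frames are resampled bilinearly with edge
replication. On synthetic clips with jitter SD up to 5 px and noise SD up
to 0.05 the RMS error of the recovered trace is about 0.1-0.25 px
(tested bound: 0.5 px).

## Width measurement

The column width is *the distance between the two intensity minima*
flanking the bright core of a cross-sectional profile. `extract_profile()`
samples the frame along a user-supplied line by bilinear interpolation at
(approximately) unit spacing — the line is divided into `round(length)`
equal steps, endpoints inclusive, so axis-aligned integer-length lines
reproduce raw pixels exactly. `measure_width()` then:

1. Gaussian-smooths the profile (`smooth_sigma_px`, default 2 px; 0
   measures the raw profile). The default stabilizes minima under sensor
   noise; whether the original workflow smoothed is unknown, so the
   parameter is exposed.
2. Locates the global maximum (the aqueous core). A maximum at the
   profile edge means no flanked core: "unmeasurable profile".
3. Takes the deepest local minimum on each side; exact ties break toward
   the minimum nearer the core.
4. Refines each minimum to subpixel position by a parabolic fit over its
   3-point neighborhood, and reports the distance between the two refined
   minima.

`measure_width_clip()` applies this to the first 30 frames (the
measurement convention), excludes and counts unmeasurable frames, and
fails if more than half are unmeasurable. Two observers' clip
measurements are combined by `average_observers()` — the plain mean of
the two mean widths. Widths are reported in pixels throughout: the
imaging chain has no physical calibration.

Percent change from baseline is `100 * (value - baseline) / baseline`,
computed per subject before averaging. Note the distinction, visible in
any summary table: the mean of per-subject percent changes is not the
percent change of the mean widths.

Tested recovery: over true widths 10-80 px (vessel twice the column,
noise SD up to 0.05, 30 frames) the absolute error of the mean width is
below 1 px; for the 10 px column the error is dominated by a stable
+0.8 px smoothing bias (the 2 px kernel is wide relative to the core),
which is inherent to smoothing narrow columns and documented rather than
corrected.

## The flow proxy

For a pixel time series $p(t)$, the normalized temporal autocorrelation is

$$R(n) = \frac{E[(p(t) - \mu)(p(t+n) - \mu)]}{\sigma^2},$$

with the expectation estimated over the $T - n$ valid pairs (denominator
$T - n$). Two normalization conventions ship, because the wording of the
source formula is ambiguous about whether $\mu, \sigma$ belong to the
pixel or to the segmented region:

* **per-pixel-temporal** (default): $\mu, \sigma$ are the series' own
  mean and population SD, so $R(0) = 1$ exactly and the curve is a
  correlation;
* **segment-spatial**: $\mu, \sigma$ are supplied from the segment, as
  when one normalization is shared by all pixels.

Results carry their convention tag. `flow_metric()` reduces the per-pixel
curves over a region of interest to the *decorrelation lag* $n^*$ — the
smallest lag with $R(n) < 0.5$ — and summarizes the region as the median
of $1/n^*$ (frames$^{-1}$). Faster flow turns speckle over faster, so the
lag falls monotonically with advection speed (tested over 0.5, 1, 2 and
4 px/frame). Constant pixels and pixels that never cross the threshold
within `max_lag` are excluded and counted; a region with no decorrelating
pixel returns a flagged result, not an error. The 0.5 threshold and the
median reduction are robustness choices, both exposed as parameters; no
conversion to physical velocity is attempted (no calibration exists).

## Crossover statistics

The trial design is a two-sequence 2x2 crossover: each of 16 subjects
receives both drugs in randomized order with a washout between periods.
The statistical layer implements:

* `chi_square_2x2()` — Pearson chi-square *without* continuity correction,
  df = 1. The no-correction form is required to reproduce the published
  baseline-characteristics p-values (0.590, 0.131, 0.302) from their 2x2
  counts, which the acceptance tests verify to 3 decimals.
* `unpaired_t_test()` — two-sided pooled-variance t from summary
  statistics.
* `wilcoxon_signed_rank()` / `wilcoxon_rank_sum()` — zeros dropped
  (classic convention; the source names none); exact two-sided p-values
  for small samples from the full sign-pattern / subset distribution,
  computed by convolution on doubled midranks so ties stay exact;
  tie-corrected normal approximation (no continuity correction) beyond
  that. Both are tested against brute-force enumeration.
* `fit_crossover_lmm()` — the primary between-drug comparison:
  $y = \beta_0 + \beta_{seq} + \beta_{drug} + \beta_{period} + u_{subj} + \varepsilon$
  with a subject random intercept, one observation per subject x drug,
  outcome = percent change in width from the same-drug baseline at the
  chosen timepoint (raw width behind `outcome = "width"`). Estimation is
  REML, profiled to a 1-D optimization over
  $\lambda = \sigma_u^2/\sigma^2$ on a log grid with an explicit check of
  the $\lambda = 0$ boundary, where the fit provably reduces to ordinary
  least squares (tested to 1e-6). The drug-effect p-value is a two-sided
  Wald test against the normal reference. Small-sample df corrections
  (Satterthwaite, Kenward-Roger) are deliberately out of scope; the
  resulting mild anti-conservatism is measured, not hidden — the null
  rejection rate at $\alpha = 0.05$ over 2,000 simulated null studies of
  16 subjects is about 0.07, inside the tested 0.05 ± 0.02 band but at
  its edge. The fit object reports an honest convergence flag and the
  fitted variance components, and the test suite cross-checks
  coefficients, SEs and variance components against lme4 on the same
  data.

`summarize_study()` produces the three report tables (width and percent
change, between-group LMM effects at 2 h and 8 h, IOP) with within-group
signed-rank p-values; missing cells are reported per cell and
single-subject cells get flagged SDs. Significance is two-sided at 0.05
throughout; no multiplicity adjustment is applied (none was used in the
original analysis), and carryover is handled only through the sequence
fixed effect.

## The study simulator's calibration

`study_design_params()` defaults *are* the published study conditions: 16
subjects randomized 1:1; per-drug baseline widths 63.7 and 66.0 px with
total SD 19.3 px, of which 80% is between-subject (the published tables
give only totals, so the split is a design choice; it affects only the
random-intercept structure, not the marginal distributions); per-subject
percent changes drawn from N(28.8, 16.3²) and N(7.6, 12.6²) for
ripasudil at 2 h and 8 h and N(-2.5, 5.7²) and N(-4.3, 8.1²) for
latanoprost; IOP per timepoint from the published means and SDs. Drawn
widths are floored at 5 px (baselines) and 1 px (post-dose) — a physical
positivity guard that is essentially never active at these parameters.
The design validator rejects negative SDs; zero SDs are allowed so that
noise-free identity checks are expressible.

## Numerical choices and degenerate inputs

* Frame indices are 0-based everywhere in the public API (video
  convention); pixel centers sit at integer 0-based coordinates.
* AVI I/O is an uncompressed RIFF subset (8-bit paletted grayscale or
  24-bit RGB) written and read by the package itself; pixels are
  quantized to 8 bits at write time and round-trip bit-exactly
  thereafter. Compressed AVIs are rejected with an I/O error.
* Parabolic subpixel offsets are clamped to ±0.5 sample and degenerate
  (collinear) neighborhoods return 0.
* Constant frames in `stabilize()` yield zero shifts with a warning;
  constant pixel series in the autocorrelation are a degenerate-signal
  error at the operation level but are excluded-and-counted at the
  region level.
* All stochastic functions take explicit seeds and restore the caller's
  RNG state; a lazily supplied seed expression is forced before the
  state is captured so its own draws count against the caller's stream.

## Problem sizes used in the shipped analyses

The test-suite and acceptance analyses use scenes of roughly 120x160 to
220x240 px and 30-150 frames, 500 replicates for the calibrated headline
simulation and 2,000 for the null calibration. These sizes give
Monte-Carlo errors comfortably inside the tested tolerances while keeping
the full suite reproducible in minutes on one core; the algorithms
themselves are resolution-independent.

## A worked run

```{r example}
# simulate the default 16-subject crossover study and analyze it
study <- render_crossover_study(seed = 7)
fit <- fit_crossover_lmm(study$table)
summary(fit)

# one synthetic clip, measured end to end
p <- scene_params(column_width_px = 40, vessel_width_px = 80,
                  image_height_px = 140, image_width_px = 160,
                  jitter_sd_px = 2, noise_sd = 0.03,
                  blink_frames = list(c(10, 4)), n_frames = 80, seed = 21)
r <- render_video(p)
blinks <- detect_blinks(r$clip, window = 21)
seg <- select_post_blink_segment(r$clip, blinks)
st <- stabilize(seg)
measure_width_clip(st$clip, scene_cross_section_line(p))
```
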