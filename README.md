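# aquacol

Quantitative analysis of aqueous humor outflow in episcleral veins from
green-filter slit-lamp video (hemoglobin video imaging), for
ophthalmology researchers studying the conventional outflow pathway and
drugs that act on it.

Under a green filter (505–575 nm) hemoglobin absorbs strongly, so an
episcleral vein appears as two dark blood lanes flanking a bright central
stream of aqueous humor — the **aqueous column**. A drug that lowers
intraocular pressure by reducing conventional-outflow resistance (a
Rho-kinase inhibitor such as ripasudil) should widen that column, while a
drug acting on the uveoscleral route (latanoprost) should not. aquacol
implements the full measurement and analysis chain for such studies:

* **Synthetic vein videos with exact ground truth** — an analytic
  cross-section whose blood-lane minima sit exactly `column_width_px`
  apart by construction, advected blood speckle with AR(1) turnover,
  static scleral texture, blink dimming, camera jitter and sensor noise
  (`scene_params()`, `render_video()`, `render_crossover_study()`).
* **Video I/O and frame handling** — lossless uncompressed AVI read/write,
  green-channel extraction, 60→30 fps alternate-frame subsampling.
* **Preprocessing** — blink detection from global intensity dips,
  post-blink segment selection, and translation-only stabilization by
  phase correlation with candidate disambiguation and a median-template
  second pass (`detect_blinks()`, `select_post_blink_segment()`,
  `stabilize()`).
* **Width measurement** — the column width is the distance between the
  two intensity minima flanking the bright core of a cross-sectional
  profile: Gaussian smoothing, deepest-minimum search on each side of the
  global maximum, subpixel parabolic refinement, 30-frame averaging and
  two-observer averaging (`measure_width()`, `measure_width_clip()`).
* **Flow proxy** — per-pixel temporal autocorrelation
  `R(n) = E[(p(t) − μ)(p(t+n) − μ)] / σ²`, reduced over a region to the
  decorrelation lag `n*` (smallest `n` with `R(n) < 0.5`) and the median
  of `1/n*` (`autocorrelation()`, `flow_metric()`).
* **Crossover statistics** — exact Wilcoxon signed-rank and rank-sum
  tests (enumeration via doubled midranks), Pearson χ² without continuity
  correction, pooled t from summaries, and the primary linear mixed model
  `y = β₀ + β_seq + β_drug + β_period + u_subject + ε` fitted by REML with
  a 1-D profile over the variance ratio, Wald drug-effect p
  (`fit_crossover_lmm()`, `summarize_study()`).

Pipeline commands (`cmd_simulate()`, `cmd_measure()`, `cmd_flow()`,
`cmd_analyze()`) tie the stages together over a plain-text config; a thin
command-line wrapper ships in `inst/scripts/aquacol`.

## Worked example

Simulate a 16-subject two-sequence crossover study calibrated to the
published effect sizes and fit the primary model:

```r
library(aquacol)
study <- render_crossover_study(seed = 7)
fit <- fit_crossover_lmm(study$table)   # percent change in width at 2 h
summary(fit)
#> Crossover LMM (REML), outcome = percent_change_width at 2h, n = 32
#>             Estimate Std. Error z value  Pr(>|z|)
#> (Intercept) -2.47122    4.71665 -0.5239    0.6003
#> sequence    -1.84954    4.74781 -0.3896    0.6969
#> drug        34.29650    4.68528  7.3201 2.479e-13 ***
#> period      -0.56304    4.68528 -0.1202    0.9043
#> Random intercept variance 2.36, residual variance 175.6
#> Drug effect (Wald) p = 2.479e-13; converged: TRUE
```

The `drug` row is the ripasudil − latanoprost contrast in percent change
from baseline: in this replicate ripasudil dilates the column about 34
percentage points more than latanoprost (true simulated contrast:
28.8 − (−2.5) = 31.3), and the crossover model detects it at p ≪ 0.001
while absorbing sequence and period effects.

Render one synthetic clip and measure it end to end:

```r
p <- scene_params(column_width_px = 40, vessel_width_px = 80,
                  image_height_px = 140, image_width_px = 160,
                  jitter_sd_px = 2, noise_sd = 0.03,
                  blink_frames = list(c(10, 4)), n_frames = 80, seed = 21)
r <- render_video(p)
blinks <- detect_blinks(r$clip, window = 21)
seg <- select_post_blink_segment(r$clip, blinks)  # 30 frames after the blink
st <- stabilize(seg)                              # remove camera shake
measure_width_clip(st$clip, scene_cross_section_line(p))
#> <width_measurement> mean 39.91 px (sd 0.57) over 30 frame(s), 0 excluded
```

The measured 39.91 px recovers the constructed 40 px column through
blink anchoring, stabilization and subpixel minima refinement. Widths are
in pixels throughout — the imaging chain has no physical calibration.

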