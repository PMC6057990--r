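---
title: "Slip-based texture coding: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slip-based texture coding: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

When a rat sweeps a whisker across a surface, friction converts the 3D
texture into a vibration of the hair shaft long before any neuron fires.
Two families of candidate codes can read that vibration out:

* **global (intensive) codes** that integrate over the whole sweep —
  *intensity* `i`, the mean modulation speed after the imposed driving
  speed is subtracted, and *frequency* `f`, the single frequency carrying
  maximum spectral power ("best frequency");
* a **local code** carried by discrete stick-slip events ("slips") — their
  peak velocity `sv`, peak acceleration `sa`, and rate `sr`.

`slipcode` implements the full comparison pipeline: surface profilometry
statistics, slip detection in kinematic traces, global feature extraction,
pairwise ROC/AUC discriminability, and a classifier analysis in which the
features are degraded to the perceptual resolution a rat could plausibly
access. A statistical generator produces surfaces and sweeps with known
ground truth so that every stage is testable end to end without raw
recordings.

All kinematics are in degrees, deg/s and deg/s²; surface heights and pixel
pitches in micrometers; sampling at 4000 samples/s; sweeps cover 60° of
protraction, so their duration is `60 / driving_speed` (100 ms at 600 deg/s,
33 ms at 1800 deg/s). The first 15 ms of every sweep are discarded
(movement-onset artifacts).

## Surface profilometry

A texture is a 200×200 grid of heights with a known pixel pitch. Optical
profilometers occasionally fail in deep valleys and write an extreme
sentinel value. `detect_artifacts()` flags pixels that are simultaneously

1. extreme low outliers — below `Q1 − 5·IQR` of the height distribution
   (the sentinel sits far outside the data range; the multiplier is
   configurable), and
2. locally implausible — the absolute height difference to a neighbor,
   per unit distance, exceeds the 95th percentile of that neighbor-slope
   field. The percentile is computed over the bulk (pixels not adjacent to
   an extreme value) so that a few percent of sentinels cannot drag the
   threshold up to sentinel magnitudes.

The 8-neighbors of every detection are flagged too, since bins adjacent to
an error are unreliable. `interpolate_artifacts()` replaces flagged pixels
by the average of two independent 1D linear interpolations (row-wise and
column-wise, nearest-value extension at the edges); "2D linear
interpolation" is underdetermined, and this concretization restores planes
exactly, which is the behavior the tests pin down. Cleaning can only shrink
the height variance in the sentinel-valley regime, and the distribution
summaries omit every sample whose differencing support touches an
interpolated pixel.

Slope and angularity use a moving 2×2 window: the two differences along
rows and the two along columns are averaged, and the length of the vector
sum of the two cardinal difference vectors, divided by the pitch, gives the
(unsigned) slope; the identical operator applied to the dimensionless slope
field gives angularity in 1/µm. Direction is deliberately ignored. On any
affine surface the slope is constant and the angularity is zero to machine
precision — a useful oracle.

Texture scale is summarized by the **correlation length**: the full width
at half height of the central peak of the normalized spatial
autocorrelogram. The autocorrelogram is computed by the zero-padded FFT
method, which equals the direct double sum over all lags (asserted to
1e-8 on 16×16 grids in the tests); the 2D field is reduced by radial
averaging in 1-pixel annuli, and the half-height crossing is located by
linear sub-pixel interpolation at the first crossing going outward. If the
profile never drops below half height the function raises an error carrying
the lower bound rather than returning a fabricated number. For white noise
the expected width is one pixel; for noise smoothed with a Gaussian kernel
of width σ the autocorrelation is Gaussian with width σ√2 and the closed
form `2·sqrt(2·ln 2)·σ·√2` provides a quantitative oracle.

The radial spatial spectrum excludes the DC bin, which makes the summed
power equal the variance of the windowed grid exactly (Parseval), and the
spectral centroid is the power-weighted mean spatial frequency of the
radially averaged spectrum.

## Trajectory kinematics and slip detection

Position traces are differentiated twice with central differences
(one-sided at the edges; second-order accurate, attenuating a 200 Hz
component by ~3%). The slip criterion is calibrated per driving speed from
in-air control sweeps: threshold = 2 × SD of the pooled in-air acceleration
samples. With Gaussian noise this criterion passes 2(1−Φ(2)) ≈ 4.55% of
contact-free samples — in-air sweeps pushed through the detector therefore
show a predictable false-event load, which is a property of the 2·SD
criterion itself, not a bug, and is asserted in the tests.

`detect_slips()` forms candidate events from contiguous runs of samples
with |acceleration| above threshold (two-sided by default; slips jerk in
either direction), merges runs separated by less than 1 ms (one physical
event should not be split by a brief dip), and reads the peak
|acceleration| sample as the event time and `sa`; `sv` is the maximum
|velocity − driving speed| inside the event window (ego-motion removed, for
symmetry with intensity; configurable). One caveat is documented in the
test suite: with biphasic events, raising the threshold can *split* a
merged event into its two lobes, so event counts are only monotone in the
threshold when the merge gap bridges the inter-lobe dip.

## Global coding variables

* `intensity()` — mean |velocity − driving speed| over the analyzed window,
  computed on the unfiltered velocity so that a pure ramp gives exactly 0.
  The alternative reading (mean |v|, then subtract the scalar) is exposed
  as an argument.
* `best_frequency()` — linear detrend, zero-phase 5th-order Chebyshev
  type II band-pass with cut-offs [30, 250] Hz and 40 dB stop-band
  attenuation (the order and cut-offs are protocol constants; the
  attenuation is a free choice and configurable), Hanning window, FFT
  zero-padded to 1 Hz bins, argmax within the pass band. Zero-phase
  (forward–backward) filtering avoids group delay, so filtering cannot
  shift event times; zero-padding matches the stated 1 Hz resolution of
  the frequency code without claiming new information. Spectra are
  computed on velocity modulation (position vs velocity is an open choice;
  velocity is the default and the input is configurable). A silent trace
  returns `NA` rather than an arbitrary bin.

33 ms sweeps at 1800 deg/s are shorter than one period of the 30 Hz band
edge; the estimate is then dominated by the window, which is the price of
the protocol's fastest condition — the function warns on direct use and the
table builder accepts it silently as part of the standard design.

`build_feature_table()` assembles one row per sweep (`f`, `i`, `sr`, and
median per-event `sv`, `sa`) plus a long event-level table. The per-sweep
aggregation of the heavy-tailed event variables is the median, which is
robust; event-level pooling remains available for distribution-level AUC.

## Discriminability

`auc()` is the Mann–Whitney formulation, `P(X_a < X_b) + ½·P(X_a = X_b)`,
computed from ranks — ties get half credit, identical samples give exactly
0.5. The tests pin it to a brute-force all-pairs enumeration and to the
`wilcox.test` statistic. Pairwise comparisons enumerate all ten texture
pairs in the canonical roughest-first order. The neighboring-pair summary
averages the four adjacent-grain-size comparisons after **folding** each
AUC around 0.5 (`0.5 + |AUC − 0.5|`): discriminability can invert between
whiskers and textures, and raw averaging would cancel opposite-signed
effects; the raw average is reported alongside because either convention is
defensible.

## Perceptual blurring and classification

Measured change thresholds — ~36 Hz for frequency, ~450 deg/s for
intensity, 23600 deg/s² for slip acceleration — define the blur: each
feature value is replaced by a draw from a Gaussian centered on it with SD
equal to a fraction (100/50/30%) of its threshold. In the standard
comparison `sa` is always blurred at 100% (the most unfavorable condition
for the slip code), while `f` and `i` get the graded fractions.

`train_and_select()` implements the model-selection protocol: stratified
80/20 train/test split, grid search by stratified 10-fold cross-validation
on the training split over three families — linear SVM (C ∈ 10^(−2..2)),
RBF SVM (same C × γ at 0.1/1/10 times the 1/n_features scale heuristic) and
ridge logistic regression (λ = 1/C) — selection of the best mean CV
accuracy, and a single held-out evaluation. Features are standardized with
training-split statistics only (required for comparable C grids);
multi-class problems use one-against-all with argmax over sign-oriented
decision functions. The split fraction, the grids and the standardization
are free choices documented here; seeds make the whole selection
reproducible. `run_tasks()` crosses blur levels × feature sets × tasks
(5-way identity, chance 0.2; neighboring-pair discrimination averaged over
the four pairs, chance 0.5). A `n_repeats` argument re-runs the split and
reports the median score; the default is a single run, which is
proportionate at the package's test scales.

## The synthetic-data generator

The generator emulates the *statistical* structure the analysis assumes —
it is not a friction simulation.

* **Surfaces**: spherical-cap grains with lognormal diameters (CV 0.25)
  at ~2 grains per mean-diameter square ("tightly packed"), height = max
  over caps. The five presets use the standard sandpaper grain diameters
  (201, 58.5, 35.0, 25.8, 15.3 µm) on 200×200 grids spanning 4000–500 µm a
  side. Coarser grain ⇒ longer correlation length, the ordering the
  profilometry stage must recover. `inject_profilometry_errors()` plants
  sentinel values in the lowest-height decile with a ground-truth mask, so
  detector recall/precision are measurable.
* **Sweeps**: position = driving ramp + Poisson train of biphasic slip
  pulses + integrated band-limited Gaussian acceleration noise. The pulse
  is one full sine period of acceleration over 5 ms: twice differentiable
  in effect, zero net velocity step, forward displacement, and the peak
  acceleration is directly the drawn amplitude. Peak amplitudes are
  lognormal (heavy right tail, matching jerky-event phenomenology; no
  distributional form is established empirically). Poisson event times are
  thinned so no two pulses start within one pulse duration plus a 2 ms
  guard — a shaft point cannot slip twice at once, and distinct events must
  not fuse under the default merge gap, which keeps noise-free recovery
  exact. The acceleration noise is low-passed at the 250 Hz analysis band
  edge: its marginal stays Gaussian (so the 2·SD tail fraction is
  preserved) while the finite-difference second derivative recovers the
  noise SD within a few percent, which white noise would not allow.
* **Rate–speed coupling**: the effective rate is
  `rate + slope·(speed − 600)` with a default slope of −2.65/600 events/s
  per deg/s — the observed mean slip-rate decrement per speed step, in
  direction and magnitude.
* **Texture → slip mapping**: the presets give rougher textures higher
  median peak accelerations (40000 down to 12000 deg/s² across the five
  textures) at a shared rate and noise floor. The induced `f` and `i`
  differences are far below the 36 Hz / 450 deg/s thresholds, which is the
  regime the blurred-classifier comparison probes.

Seeding: every generator takes a seed and restores the caller's RNG; a
dataset uses one master seed with child seeds
`(master·1000 + counter) mod (2³¹−1)` in generation order, so reruns are
byte-identical after serialization.

What the generator does **not** emulate: whisker elasticity and cone
mechanics, distance- and whisker-dependent filtering, correlated slip
trains, non-stationary rates within a sweep, or any mechanistic link
between a surface grid and the slip statistics of the sweeps "recorded" on
it. Passing tests therefore demonstrate that the *analysis* is correct and
self-consistent under the stated statistical assumptions — not that real
whisker data would show any particular effect size.

## Problem sizes and numerical choices

The test suite and the acceptance script run the pipeline at reduced but
statistically meaningful sizes chosen as part of the package's design:
40–100 sweeps per condition for pipeline checks, 25–40 seeds for recovery
and chance-level properties, 10⁴ draws for blur calibration, 128×128 grids
for the Gaussian-ACF oracle. Degenerate inputs fail loudly: a zero-density
texture warns and returns a flat surface; constant grids refuse
autocorrelation; missing air controls abort feature building; classes too
small for 10-fold stratification raise an explanatory error rather than
silently reducing folds.

## Known limitations

* Slope/angularity units follow the degree/µm convention throughout; the
  literature is not always consistent about angularity units, and the
  package states its units in every header instead of resolving that.
* Event-level `sa` distributions mix true slips with the ~4.55% false-event
  load implied by the 2·SD criterion; at realistic noise floors this
  compresses, but does not reorder, texture differences in the per-sweep
  medians.
* The classifier comparison reports held-out accuracy after selection over
  a modest grid; it is a comparison instrument, not a tuned production
  classifier.
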