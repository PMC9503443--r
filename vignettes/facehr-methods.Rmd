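---
title: "Methods: facial-color tracking of exercise intensity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: facial-color tracking of exercise intensity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

During a ramped cycling test, cardiac output rises with workload and the
perfusion of facial skin changes; the mean color of a small forehead patch
therefore drifts with effort. `facehr` models that drift at the level of
1 Hz *trends*, not beat-to-beat pulse waves: the quantity of interest is
exercise intensity expressed as a percentage of the age-predicted maximal
heart rate,

$$\mathrm{maxHR\%}(t) = \frac{100 \cdot \mathrm{HR}(t)}{220 - \mathrm{age}},$$

and the predictors are the per-second spatial means of a forehead patch in
five color models. Two model families are fitted:

* **Personalized** (one participant): a lag-1 multivariate autoregression
  $$y_t = a_1 + w_1 y_{t-1} + \textstyle\sum_{n=1}^{3} w_n\, CR_{n,t-1} + e_t,$$
  with $y = \mathrm{maxHR\%}$ and $CR_n$ the three min–max normalized
  channels of one color model, estimated by ordinary least squares over
  $t = 2..n$ (`fit_ar1()`).
* **Universal** (pooled over participants): all rows pooled, channels
  expanded to every monomial of total degree ≤ 3 (19 terms), fitted by
  ridge-regularized least squares with a tiny penalty
  (`lambda = 1e-6`, on standardized terms), or optionally by an
  epsilon-insensitive support-vector loss (`epsilon = 0.1`, `cost = 1`)
  on the same terms (`fit_poly_global()`). The ridge default was chosen
  because it is deterministic, dependency-light and numerically stable
  under the severe collinearity of expanded chromaticity channels; the SVR
  option reproduces the epsilon-insensitive loss family literally.

The assumptions are those of the trend-level view: the face is frontal and
roughly static within one second, illumination changes are multiplicative,
the color–intensity association is smooth in time, and the channels are
stationary after detrending (checked with `adf_test()`).

Both age-based heart-rate formulas in the literature appear here in their
proper places: `220 − age` defines maxHR% (the regression target), while
the protocol's termination ceiling uses `0.85 · (208 − 0.7·age)`
(`ramp_ceiling()`); they are different estimators and are deliberately not
interchangeable.

## Extraction chain

Per frame: sharpness is the variance of the 4-neighbour Laplacian of the
luma image (`frame_sharpness()`); frames below `blur_threshold` (default
100, squared 8-bit units) are restored by frequency-domain Wiener
deconvolution with a linear-motion PSF (default: horizontal, 9 px — cycling
head bob in a frontal view is predominantly horizontal) and
noise-to-signal ratio `nsr = 0.01`. The config also supports deconvolving
*all* frames or none, and a raw pixel-variance blur statistic, since the
named statistic/policy is a genuinely open choice. Gaussian denoising
(`sigma = 1` px, reflective borders) follows.

The face is localised, cropped and bilinearly resized to 400×400, and a
16×16 patch is taken at (50%, 18%) of the crop — just above typical brow
position on a frontal crop; "lower forehead" fixes only the region, so the
exact fractions are exposed in `pipeline_config()`. Boxes are 0-based and
half-open throughout; a failed detection reuses the most recent successful
box (temporal hold, logged) so the 1 Hz cadence is never broken; multiple
detections resolve to the largest.

**Face detection.** The detector is a deterministic skin-chromaticity blob
finder: the classic RGB skin rule (R > 95, G > 40, B > 20, R > G, R > B,
max−min > 15) marks candidate pixels, the box spans the central 96% of
their row/column marginals (trimming stray matches), and a fill-fraction
gate (≥ 0.3) rejects diffuse matches such as noise frames. This is not a
general-purpose cascade detector; it is designed for frontal faces on
non-skin backgrounds, which is exactly what the synthetic renderer
produces, and ground-truth boxes can always be injected
(`box = "ground_truth"`, `manual_box =`).

Each patch pixel is chromaticity-normalized,
$I_{\mathrm{norm}}[i,j,c] = I[i,j,c] / \sum_c I[i,j,c]$, so components sum
to exactly 1. This eliminates any multiplicative brightness change —
including mains-lamp flicker — and is scale-invariant by construction
(asserted as a property test). Pure black pixels take the achromatic
sentinel (1/3, 1/3, 1/3), preserving the unit sum without dividing by
zero. Normalization happens per pixel, so applying it after patch cropping
is algebraically identical to normalizing the whole frame first; the
implementation exploits this for speed.

Conversions are pinned to mainstream standards, since the model names
alone do not fix them: HSV by the hexcone model (H in degrees, S unit
interval, V 8-bit), YCbCr per BT.601 with the 8-bit chroma offset 128, YUV
per BT.601 analog weights (chroma centred on 0), Lab via sRGB with D65
white. The normalized chromaticity is rescaled by 255 first so every
conversion operates on its native 8-bit domain. Achromatic inputs map to
the achromatic locus of every model, which the tests assert. Because
conversion consumes chromaticity, brightness-carrying channels (V, L, Y)
encode only relative color — this is the price of flicker immunity, and it
is why the red *chromaticity* can fall while raw red rises.

## Filtering

25 Hz patch means are block-averaged to 1 Hz (trailing partial second
dropped). Smoothing is a 201-point sliding median followed by a causal
moving average (default window 21 s ≈ 10% of the median window; the
"small" window is otherwise unspecified). The median's endpoint problem is
solved by reflecting 40 samples at each end (mirror, without duplicating
the edge sample) and edge-replicating the remaining
$(\mathrm{window}-1)/2 - 40$ samples — the stated pad and reflection do
not by themselves define a composition, so this resolution is documented
and oracle-tested. The moving average is causal as written; its first
`ws − 1` outputs are computed on a reflected prefix so length is
preserved (only the median stage has a prescribed endpoint fix). When a
recording is shorter than the median window, the window shrinks to the
largest odd number ≤ length, with a message. Signals shorter than the
moving-average window are rejected.

## Degenerate inputs and numerical choices

* constant vectors min–max normalize to all 0.5 (keeps designs finite);
* constant series are reported by `adf_test()` as degenerate and
  stationary rather than erroring;
* exactly collinear predictors are *rejected* by `fit_ar1()` (QR rank
  check, offending column named) and reported as infinite VIF with a
  warning by `vif_report()`;
* frames are validated to `[0, 255]`; all filters preserve shape and
  range; rendered frames are integer-quantized (8-bit), so identity
  checks are asserted to within ±0.5.

ADF lag order is selected by AIC over `0..⌊12(n/100)^{0.25}⌋` on a common
sample, and p-values use the MacKinnon (1994/2010) response-surface
approximation for the constant-only regression; the implementation was
verified against an independent reference implementation on frozen seeded
series (statistics agree to 10⁻⁸).

**Chromaticity collinearity.** After normalization the three RGB-model
channels sum to exactly 255, so a joint design on all three is
rank-deficient up to the small asymmetries introduced by the (nonlinear)
median filter. Joint coefficient signs are therefore not identifiable for
that model; association signs are read from univariate pooled slopes, and
the VIFs of chromaticity channels are legitimately large. This mirrors
what any analysis of sum-constrained compositions encounters.

## The synthetic generator

`scenario()` fixes the study conditions; `simulate_session()` produces the
ramp, the ground-truth signals and a lazy frame stream.

* **Ramp**: linear from `initial_hr`, saturating at
  `0.85(208 − 0.7·age)` at 90% of the session, plus AR(1) beat-to-beat
  jitter (coefficient 0.9, innovation 1 bpm — small against the ~0.15
  bpm/s ramp slope, mimicking short-range heart-rate variability), clipped
  to the ceiling.
* **Coupling**: each raw channel is `baseline + coupling · maxHR% +
  N(0, noise_sd)`. The magnitude of color change per intensity point is
  not an established quantity; the defaults (+0.25, −0.05, −0.05 intensity
  units per percentage point, baseline (200, 140, 110)) encode a face that
  reddens with effort by ~10 units over a typical ramp — visually subtle,
  recoverable by regression, and with signs that survive chromaticity
  normalization (so sign checks are meaningful end to end).
* **Corruption defaults** (noise_sd = 1, flicker amplitude 0.02, blur
  fraction 0.1) are the moderate-corruption condition used by the
  package's own end-to-end checks.
* **Flicker**: fluorescent lamps driven at 50 Hz mains modulate intensity
  at 100 Hz. Sampled at exactly 25 Hz that would alias to 0 Hz (a constant),
  which contradicts what unsynchronised cameras record; the renderer
  therefore models the observable *beat* as a multiplicative sinusoid at
  `flicker_freq` (default 2.5 Hz), giving the closed-form within-second
  brightness CV of amplitude/√2 that the tests verify by brute force.
* **Frames**: an elliptical skin-tone face with dark brow/eye blobs and a
  forehead band painted exactly with the per-second signal color, at a
  fixed, metadata-recorded box. 360×640 at 25 Hz is the default working
  size (study-scale recordings are 1080×1920; everything is configurable).
  Per-pixel sensor noise is available (`pixel_noise_sd`) but defaults to 0:
  patch-level variability is already carried by `noise_sd`, and the patch
  mean of 256 iid-noise pixels would add an order of magnitude less spread
  than the channel noise itself.
* **Determinism**: every draw (jitter, channel noise, blur flags,
  per-frame pixel noise) derives from `scenario$seed`; identical scenarios
  are bit-identical, which the tests assert.

What the generator does *not* emulate: sub-second pulse waveforms (the
analysis is at 1 Hz trends), photorealistic skin texture and specularity,
head pose changes and occlusion, and camera compression artifacts. Passing
the end-to-end checks therefore demonstrates that the pipeline is
self-consistent and recovers known couplings under controlled corruption —
not that it would meet the same error on arbitrary real recordings.

## Scales used by the checks

The packaged checks run the complete pipeline on a 360-second session at
360×640 (9000 frames) with the moderate-corruption defaults, ADF
size/power at n = 500 over 50 seeds, and coefficient recovery at n = 600
over 100 seeds; unit tests use shorter sessions at 320×180. These sizes
were chosen to exercise every stage at full fidelity while keeping a
complete run in the minutes range on a single core.

## Known limitations

* The skin-rule detector assumes a frontal face on a non-skin background;
  real footage needs a cascade/CNN detector or a manual box
  (`manual_box =`).
* In-sample RMSE is reported (no train/test split is prescribed for this
  analysis); a holdout can be built with `predict()` on withheld rows.
* The universal model's F degrees of freedom follow the terms actually
  fitted (19 at degree 3). A linear-in-channels reading (3 terms) is
  available via `degree = 1`.
* maxHR% is modelled on its natural percent scale; set
  `normalize_y = TRUE` in `pipeline_config()` to normalize the dependent
  variable to [0, 1] as well, which rescales RMSEs by the participant's
  maxHR% range.
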