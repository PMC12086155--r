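---
title: "Methods: smartphone RGB color indices for lettuce canopies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: smartphone RGB color indices for lettuce canopies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopyRGB)
```

## The measurement model

A top-down canopy photograph is reduced to a per-color pixel histogram:
every uniquely observed RGB code with the number of segmented pixels showing
it. The histogram is an exact, lossless summary of the segmented pixels, so
all downstream indices can be computed from it instead of the raster — the
package asserts this equivalence against a per-pixel brute-force oracle in
its test suite.

A pixel enters the analysis only if its G channel value **strictly** exceeds
both R and B. Strictness matters: ties are excluded, so black `(0,0,0)`,
grays and white `(255,255,255)` never count as green, and the rule needs no
tunable threshold. Two statistics summarize the retained pixels:

* **Normalized intensity.** `I = (R + G + B)/3` after dividing each channel
  by 255, averaged over green pixels with their counts as weights. `I = 0`
  is black, `I = 1` white. Normalization before or after averaging is
  equivalent by linearity; the implementation fixes the order (integer
  channel sums, then one division by 765 and one by the pixel count) so the
  result is bit-reproducible and exactly matches a per-pixel tally.
* **Dark green proportion.** The fraction of analyzed pixels classified
  dark. The G channel is banded dark 0–85, medium 86–170, light 171–255
  (boundaries inclusive as stated). Two variants coexist because the field
  uses both: *threshold* mode counts every green pixel with G ≤ 85;
  *codeset* mode counts only pixels matching four dark palette codes
  — (0,43,0), (0,85,0), (51,85,0), (51,85,51) — which arise naturally after
  GIF palette reduction. The code set is a strict subset of the dark band,
  so codeset ≤ threshold always; *threshold* is the default because it is
  robust to quantizer differences, and both are reported by the pipeline.

**Denominator choice.** Whether the dark fraction should be taken over
green-filtered pixels or over the whole segmented leaf area is genuinely
ambiguous in field practice. The default divides by green pixels (the same
population the intensity is averaged over); `denominator = "all"` divides
by all segmented pixels. The two differ by the green fraction of the leaf
area, which for healthy lettuce is close to 1.

## Image front end

* **Palette quantization** (`quantize_palette()`) emulates the JPEG→GIF
  conversion step of smartphone workflows: median cut to ≤ 256 colors,
  boxes split along their largest-range channel at the pixel-weighted
  median, each box represented by its weighted mean color. *No dithering*:
  dithering trades color fidelity for spatial texture, which would scatter
  palette codes across the canopy and corrupt the histogram the indices are
  computed from. An input already within budget is returned bit-identically.
* **Segmentation** (`segment_vegetation()`) is deliberately simple, because
  acquisition protocols control the background: luminance `(R+G+B)/3 > 12`
  for plants photographed on a black sheet, excess-green `2G − R − B > 20`
  for pots over soil (thresholds on the 0–255 scale, both configurable).
  The luminance default of 12 sits between a near-black sheet (a few
  units) and the darkest common leaf code (0,43,0), whose luminance is
  14.3. Externally produced masks (`read_mask()`; nonzero PNG = vegetation)
  bypass segmentation entirely, decoupling index computation from
  segmentation quality.
* **Formats.** PNG and JPEG are read natively, TIFF via the suggested
  `tiff` package. GIF is not decoded directly; the palette-reduction
  semantics a GIF file would impose are available in code via
  `quantize_palette()`, which is the part of that conversion that affects
  the indices.
* **Multi-plant photos.** Protocols that photograph 4–6 plants at once need
  per-plant cropping before analysis; the pipeline analyzes one image per
  plant and device and documents tiling as the user's responsibility. How a
  multi-plant campaign maps photos to plants before correlating with
  per-plant weight is an open protocol question; per-plant tiles are the
  supported interpretation.

## Device agreement and averaging

Phone cameras render color differently (Apple-class devices tend to be more
saturated than Samsung-class ones), so the same leaf yields different index
values on different phones. With paired values `x` (device A) and `y`
(device B), the Bland-Altman summary uses `d = y − x`:

* `m = mean(d)`, `s = sd(d)` (sample sd, n−1 denominator — the conventional
  choice; only "the standard deviation" is ever stated in field reports);
* 95% limits of agreement `m ± 1.96·s` — the range individual differences
  are expected to fall in;
* 95% CI of the mean difference `m ± 1.96·s/√n` — systematic bias if it
  excludes zero.

`z = 1.96` is used throughout, not a t-quantile, matching how the intervals
are printed in practice; no confidence bounds on the LOA themselves are
computed. The sign convention is `d = Apple-class − Samsung-class`. Pairs
missing either device are dropped with a logged count.

Since both intervals share midpoint `m` and their half-widths differ exactly
by √n, a published LOA interval plus n determines the CI:
`reconstruct_ci_from_loa()`. This is used to audit printed agreement tables
to their two-decimal precision.

When bias is detected (and by default regardless), the two devices' values
are averaged per plant before the growth statistics — neither device is
known to be closer to the truth, and the average is more robust than either.

## Growth statistics

* **Treatment comparisons.** One-way ANOVA of a response (fresh weight in
  grams, leaf count) across the four fertilizer treatments C, N, LV, I,
  plus pairwise Welch t-tests *without* multiplicity adjustment — raw
  pairwise p-values are the field's reporting convention; Holm adjustment
  is available via `adjust = "holm"`. Leaf counts (leaves ≥ 2 cm on the
  longest side) are analyzed as continuous.
* **Weight–color model.** `fresh_weight ~ treatment + index` — an ANCOVA
  with per-treatment intercepts and a common slope (g per unit index). A
  "mixed-effects model within treatment groups" is under-specified when
  each plant contributes one endpoint observation: a plant-level random
  effect is unidentifiable, and treatment is the only grouping, so fixed
  treatment intercepts are the identifiable reading and the default. For
  records pooled across several experiments,
  `random_experiment = TRUE` fits a random intercept per experiment via
  `lme4` instead.
* **R².** Reported R² values for two different predictors on the same data
  imply per-predictor fits, so two variants are emitted and labeled rather
  than guessing: `r_squared` (squared correlation of fitted and observed
  weights for the full ANCOVA) and `r_squared_marginal` (squared
  weight–index correlation ignoring treatment).

## What the synthetic generator emulates — and what it does not

`gen_canopy_image()` renders elliptical leaf blobs over a noisy near-black
background. Leaf pixels take *exact palette codes* drawn from a categorical
mixture (as a GIF-quantized photo would), so ground-truth metrics are exact
and codeset mode is exercised; background pixels get Gaussian channel noise
(default mean 2, sd 1.5) and stay far below the segmentation threshold.
Geometry is decorative: only the color distribution matters to the indices,
so no lighting, shadows, leaf venation, overlap structure, or JPEG
compression artifacts are modeled. Passing tests therefore validate the
*measurement chain* — segmentation, tallying, filtering, index arithmetic,
statistics — not robustness to photographic conditions (illumination
variation, white balance, specular soil) that real campaigns face.

`device_model()` emulates the observed between-brand differences with an
additive intensity bias (unit scale) and a saturation gain applied about
each pixel's mean (image level), or additive bias plus Gaussian noise
(metric level). Both exist because the brand effect is observed
qualitatively; defaults (bias +0.02, gain 1.15 for device B) reproduce the
reported direction: higher intensity and lower dark proportion on the
Apple-class device.

`gen_experiment()` encodes the published qualitative pattern as ground
truth: per-treatment mean dark proportions C 0.20 < I 0.30 < LV 0.45 <
N 0.60 (sd 0.08 between plants), intensity `0.42 − 0.45·dark + N(0, 0.02)`
(negative association, values ≈ 0.1–0.4), and weight
`a_t + β·dark + N(0, σ)` with defaults `a_t = 20` g for all treatments,
`β = 200` g per unit dark proportion and `σ = 5` g — giving 4 treatments ×
8 plants and weights ≈ 30–150 g, the scale of a pot-grown lettuce
experiment. Leaf counts are treatment-independent (mean 25, sd 4),
reflecting that leaf number responds little to fertilizer. These defaults
*are* the study conditions for all calibration tests and are not tuned.

## Numerical and testing choices

* Integer channel sums before division make histogram-path indices
  bit-identical to per-pixel tallies; the oracle-equivalence test asserts
  exact equality on 100 random 64×64 images.
* Coordinate convention: row-major, origin top-left — internal only, no
  geometric quantity is reported.
* Degenerate inputs: an empty green-filtered histogram signals a
  no-green-pixels error rather than returning NaN; a constant color
  predictor is reported as rank deficiency naming the term; Bland-Altman
  requires n ≥ 2 (sample sd).
* Calibration suite sizes: 1000 simulated paired samples of n = 50 for CI
  coverage, one n = 10,000 sample for the within-LOA fraction, 500
  synthetic experiments for slope coverage/sign, 100 for the directional
  pattern — sizes at which binomial noise on the checked rates is a small
  fraction of the asserted bands.
* Determinism: every generator takes a seed and restores the caller's RNG
  state; the pipeline is deterministic given its configuration.

## Known limitations

No color-constancy or color-chart calibration is applied — images are
assumed white-balanced, and calibration charts present in field photos are
not used computationally. No vegetation indices beyond the two above (GLI,
NGRDI, SI and relatives are out of scope), no count models for leaves, no
longitudinal modeling of the twice-weekly monitoring data (endpoints only),
and no instance separation of overlapping plants within one photo.
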