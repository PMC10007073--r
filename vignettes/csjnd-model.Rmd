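---
title: "Modelling notes: color-sensitive JND estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling notes: color-sensitive JND estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csjnd)
```

This vignette records how the model is put together, which choices were
genuinely open, and what the synthetic test program does and does not
establish. The README states the equations; here we explain them.

## The model and its assumptions

A just-noticeable-difference (JND) map assigns each pixel of each YCbCr
channel the largest intensity perturbation assumed invisible. The model
is pixel-domain and stationary: it assumes a standard viewing geometry
baked into its constants, a mid-photopic adaptation state, and no
temporal context. Thresholds come from three mechanisms:

1. **Luminance adaptation** (`luminance_adaptation()`): Weber-like
   behavior of the eye against background luminance. The curve is the
   classical two-branch form — square-root rise of thresholds toward
   darkness, gentle linear rise toward white, minimum 3 gray levels at
   l = 127. The background is the unweighted 5 × 5 local mean. The
   printed source of this curve is ambiguous about the radical in the
   dark branch; we use the canonical `17(1 − √(l/127)) + 3`, the only
   form continuous at l = 127.
2. **Visual masking**: contrast masking, pattern masking and edge
   protection are positively correlated and are combined by product
   (`visual_masking()`), then modulated by saliency. Two points deserve
   comment:
   * *Contrast statistic.* The contrast term c is described in the
     lineage of this model family as a "variance", but the transducer's
     half-saturation constant a₂ = 26 only makes dimensional sense on the
     gray-level (standard deviation) scale — a variance of 26 would be a
     barely-visible texture. We therefore default to the population
     standard deviation over the 5 × 5 window and expose
     `contrast_stat = "var"` for the literal reading.
   * *Pattern complexity.* Orientation is the folded Prewitt gradient
     angle in [0°, 180°); the histogram uses 12 bins over a 5 × 5 region.
     Neither count is fixed by the model's description; 12 bins (15° each)
     matches the granularity of the pattern-complexity literature and
     5 × 5 matches every other window in the model. Both are config keys.
     Pixels with gradient magnitude ≤ 2 gray levels/pixel are excluded
     from histograms: a flat region has no orientation, and without the
     gate it would contribute one spurious bin and nonzero pattern
     masking. The gate is what makes `PC = 0 ⇒ PM = 0` hold exactly on
     flat stimuli.
3. **Edge protection**: the maximal response of the four classical 5 × 5
   directional kernels (1/16-normalized, zero-sum) times a Canny-derived
   weight that drops to 0.1 on edge pixels and is smoothed by a 7 × 7,
   σ = 0.8 Gaussian. Edges attract attention, so thresholds there must
   not inherit the large gradients that surround them. Canny defaults
   (σ = 1.4, hysteresis 0.1/0.3 on the max-normalized magnitude) follow
   the construction this weight is inherited from; all are config keys.
   The gradient and the weight are computed per channel, since the
   protection term carries a channel subscript (`edge_source = "luma"`
   switches to shared luma edges).

**Saliency modulation.** The SDSP detector multiplies a log-Gabor
band-pass (frequency) prior, a Gaussian center bias and a warm-color
prior, computed in CIE L\*a\*b\* at a working resolution whose longer
side is 256 pixels — the center-bias scale σ_D = 114 px is defined at
that resolution, so resizing is part of the definition, not an
optimization. Parameters (ω₀ = 0.002, σ_F = 6.2, σ_C = 0.25) follow the
SDSP reference. The raw map is resized back (bilinear), min–max
normalized, and inverted: `U = 1 − S′`, so masking in attended regions
shrinks while maximally non-salient regions keep their full estimate.
A degenerate, constant saliency map (e.g. a flat image) normalizes to
S′ ≡ 0, hence U ≡ 1: when no region stands out, nothing is suppressed.

**NAMM fusion.** `LA + VMS − α·min(LA, VMS)` with α = 0.3. The min term
discounts the overlap between adaptation and masking; for α ∈ [0, 1) the
result is sandwiched between `max(LA, VMS)` and `LA + VMS`, which the
tests assert pixel-wise on every fixture.

**Color sensitivity.** The critical viewing-distance ratio
1 : 0.432 : 0.501 for Y : Cb : Cr turns into sensitivity parameters by
squared shares, `S_θ = D_θ²/ΣD²`. (The geometric story of perceptual
sub-units with side length ∝ 1/D_θ would give different numbers; only
the squared-share reading reproduces the published triple, so that is
what `sensitivity_params()` computes.) Recomputing gives
(0.6956, 0.1298, 0.1746); the published rounded triple is
(0.695, 0.130, 0.175) — the Y entry appears to have been rounded down.
Weights invert the sensitivities and normalize to sum to 3. By default
(`cs_from = "printed"`) the weights start from the published rounded
triple, which reproduces the published weights (0.291, 1.554, 1.155) to
three decimals; `cs_from = "unrounded"` recomputes from the distance
ratio and yields (0.2908, 1.5545, 1.1548). The difference is below 0.3%
and immaterial to the maps, but the flag keeps both readings available.

Luminance adaptation is defined on background *luminance*; it is
computed once from Y and shared by the chroma channels
(`la_source = "per_channel"` applies the curve to Cb/Cr planes directly,
which stretches its meaning and is off by default).

## Noise injection and calibration

`inject()` applies `F̂ = F + β·r·JND` with r a fair ±1 coin drawn
independently per pixel and per channel from a seeded generator.
Channel-independent signs avoid correlated color artifacts; the sign
field is a pure function of the seed, making the whole pipeline
bit-reproducible. `calibrate_beta()` bisects β (sign field fixed) until
the pooled PSNR hits the target within ±0.05 dB, clipping to [0, 255]
*inside* the loop so the achieved PSNR honors the target even when
thresholds exceed the 8-bit headroom; it fails loudly when clipping
makes a target unreachable or the maps are identically zero. PSNR pools
the MSE over all three YCbCr planes (`psnr_domain` offers luma-only and
RGB pooling): the injector perturbs all three planes, so an equal-energy
comparison must see chroma noise. SSIM is the standard single-scale
Gaussian-window form (11 × 11, σ = 1.5, K = 0.01/0.03, L = 255) with
edge-replicate borders.

## Numerical choices

* All spatial filters use edge-replicate padding — no artificial
  contrast or gradients at borders — and are computed by exact
  shift-and-add correlation (kernels are ≤ 9 × 9).
* Images are float throughout; quantization (round half away from zero,
  clip to [0, 255]) happens only when writing 8-bit PNG output.
* The RGB↔YCbCr transform is full-range BT.601 (JPEG convention): the
  λ_θ and CS_θ constants originate in literature using JPEG-style
  YCbCr. The inverse is the exact matrix inverse, so round trips that do
  not clip deviate by far less than one gray level.
* Threshold maps are written as single-strip little-endian float32 TIFF
  so out-of-range values survive; `tiff::readTIFF` and Python's
  `tifffile` read them verbatim.
* The Canny stage treats a maximal gradient below 10⁻⁶ gray levels as
  "no edges" rather than normalizing numerical dust into a full-frame
  edge map.
* Min–max degeneracies (constant saliency, constant chroma) are defined
  to the neutral value (0), not left NaN.

## The fixture program

`fixture_suite()` generates twelve deterministic stimuli at 128 × 128
and 192 × 128: flat fields (thresholds collapse to the closed-form
weighted adaptation value), a luminance ramp (sweeps the adaptation
curve), gratings (one known orientation bin), checkerboards (two
orientations, regular structure), step edges (a known line for the edge
detector), seeded random textures (dense orientation content; the
calibration workhorse), and a two-region image — flat gray left half,
warm textured right half — that separates salient/textured from
flat/unattended regions and drives the channel-allocation experiment.
These sizes keep a full-model run under a second while exercising every
window in the pipeline; the generator scales to arbitrary sizes.

What passing on fixtures shows: the arithmetic of every stage, the
stated invariants (NAMM sandwich, range contracts, monotonicities,
oracle equivalence of the histogram pipeline), determinism, and the
mechanism by which color-sensitivity weighting moves noise out of Y at
matched energy. What it cannot show: agreement with human judgments on
natural images. Natural images couple the stages in ways synthetic
stimuli do not (textured edges, chromatic gradients, salient objects off
center), and the model's perceptual validity rests on subjective viewing
tests outside the scope of a test suite. Learned quality metrics (VMAF)
are likewise external: the injector reports PSNR/SSIM and per-channel
MSE, and its outputs can be fed to any external metric.

## Known limitations

* Constants assume 8-bit full-range material; 10/16-bit pipelines and
  ICC-managed color are out of scope.
* The pattern-complexity bin count, region size and magnitude gate are
  defensible defaults, not fitted values; strongly anisotropic noise
  could shift the PM term within its plausible range.
* Chroma planes reuse the luminance adaptation curve by default; a
  dedicated chroma adaptation model does not exist in this lineage.
* The saliency stage is a fast prior-product detector; images whose
  salient content is achromatic and off-center will be under-weighted
  relative to eye-tracking ground truth.
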