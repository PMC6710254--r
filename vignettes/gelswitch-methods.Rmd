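---
title: "Methods: quantifying thermoresponsive gel switching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying thermoresponsive gel switching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gelswitch)
```

## The measurement problem

Electron-beam crosslinked collagen/elastin hydrogels contract sharply when
heated through a transition temperature that is tunable by the absorbed
dose: roughly 43 °C at 50 kGy falling almost linearly to 36 °C at 90 kGy,
with the projected top-view area dropping by more than 80% across the
transition and recovering on cooling except for a small irreversible
contribution per cycle. `gelswitch` implements the analysis chain for three
kinds of raw data from such experiments:

1. **Top-view video** of a gel on a heating stage (camera at 0.9 frames/s,
   stage ramping at ~0.04 °C/s), from which the projected area versus
   temperature is extracted and the transition characterized;
2. **Confocal image series** of the fluorescently stained fibril network,
   from which pore-size distributions are computed by maximal-inscribed-
   circle analysis;
3. **Circular-dichroism spectra** (250–190 nm, 0.2 nm steps) of dissolved
   gel, collagen and elastin, which report on the secondary-structure
   changes underlying the contraction.

Because raw recordings of this kind are rarely shareable, every stage has a
synthetic counterpart with known ground truth (`make_temperature_profile()`,
`make_contraction_trace()`, `render_contraction_frames()`,
`make_fibril_image()`, `make_cd_spectrum()`), and the test suite validates
each estimator by recovery of those truths.

## Area model and transition analysis

The synthetic contraction model is

$$A(t) = A_0 \, r(t) \left[1 - s \, S\!\left(\frac{T(t) - T_t}{w}\right)\right],$$

with $S$ the logistic function, $s$ the area stroke, $w$ the transition
width and $r(t) = (1-\ell)^{k(t)}$ stepping down by the irreversible loss
$\ell$ after each completed heating cycle. The logistic was chosen because
the transition's first derivative is then symmetric about the midpoint,
matching the observed near-symmetric derivative; cooling retraces the same
sigmoid, so only $\ell$ is unrecovered per cycle.

**Area per frame** comes either from Otsu (or fixed) thresholding — the
count of gel-side pixels, with polarity auto-detected from the border — or
from a gradient circle fit: the circle maximizing the mean gradient
magnitude along its perimeter, seeded at the gradient centroid, coarse-
scanned in radius and refined by Nelder–Mead. Thresholding is the fast
default (used for cycling runs); the circle fit reports a residual
(sd/mean of the perimeter gradient) as a shape diagnostic. Physical areas
use the pixel size calibrated from a reference object of known size
(`calibrate()`), and per-frame temperatures come from linear interpolation
of the stage log (`align_temperature()`).

**Transition temperature.** On the heating segment (the longest
non-decreasing temperature run, or a user window), the area signal is
Gaussian-smoothed and dA/dT computed by central finite differences;
$T_t$ is the temperature of the most negative derivative. Two numerical
guards matter:

* *Apex samples* where the temperature barely changes are excluded from
  dA/dT (the denominator vanishes there and the quotient is pure noise).
* *Boundary folding*: a kernel whose 4σ support reaches past the segment
  ends mixes the trace with its own fold and biases the peak position —
  with a σ = 50-sample window at 0.9 frames/s and 0.04 °C/s (a ±2.2 °C
  window) the bias reaches −0.8 °C for a transition 2 °C below the ramp
  top. `find_transition()` therefore re-estimates the peak with σ shrunk so
  the support fits the margin between the located peak and the segment
  ends. The package default σ remains 50 samples (appropriate away from the
  ends); σ is expressed in **samples**, not seconds — at 0.9 frames/s these
  differ, and any resampled data should scale σ to keep the ~55 s temporal
  window.

**Stroke** is the relative drop between plateau medians over the first and
last 5% (by time) of the heating segment, computed on the **raw** trace:
the median already supplies noise robustness, whereas plateau medians of a
heavily smoothed trace are biased low when the transition sits near a short
plateau (the kernel bleeds the transition into it). The volume stroke
$1-(1-s)^{3/2}$ assumes isotropic shrinkage and is reported separately as a
model-based estimate (area and volume phrasings of the contraction differ:
an 80% area stroke corresponds to a ~91% volume stroke).

**Cycling metrics.** Cycle boundaries come from the protocol's dwell
structure. Dwell areas are medians over dwell windows; the per-cycle
amplitude is $(A_{\mathrm{cool}} - A_{\mathrm{hot}})/A_{\mathrm{cool}}$ and
the irreversible loss $1 - A_{\mathrm{cool}}(k{+}1)/A_{\mathrm{cool}}(k)$,
summarized as mean ± sd over cycles. The loss baseline uses the
**cool-end** dwells (the hot-end alternative would convolve the loss with
any amplitude drift; with the cool-end definition the synthetic model's
loss is recovered exactly in the noiseless case). Inflection points are
dA/dt extrema within each ramp. The dose–response line is an ordinary
least-squares fit of $T_t$ against dose; the printed end points (43 °C at
50 kGy, 36 °C at 90 kGy) correspond to −0.175 °C/kGy.

## Pore-size analysis

Fibrils are segmented by Otsu or a fixed threshold (bright phase = stained
fibrils, overridable; specks under 4 px removed). Pores are maximal
inscribed circles in the remaining pore space, with the frame boundary
treated as an obstacle ring just outside the image; circles that would
touch the boundary are excluded by default (`border_policy`), since they
are truncated by the field of view.

Two decompositions are provided, and they answer different questions:

* `method = "greedy"` (default) repeatedly takes the global maximum of the
  Euclidean distance transform of the *unclaimed* pore space (fibrils and
  previously accepted circles are obstacles), with ties broken by smallest
  row, then column. It is a complete, non-overlapping decomposition whose
  radii are non-increasing, and it is verified in the tests against a
  brute-force oracle that computes every distance by direct enumeration.
  Its radius *counts*, however, are necessarily dominated by the small
  circles that fill the packing leftovers — the count density rises toward
  `r_min` for any network geometry, so the KDE mode of greedy radii mostly
  reflects the cutoff.
* `method = "maxima"` takes all local maxima of a single distance
  transform, merging connected equal-valued plateaus into one pore. This
  yields one circle per pore cell and a radius distribution that reflects
  the pore geometry; it is the method used for distribution statistics
  (`pores_vs_temperature()` defaults to it), and it reproduces the peaked,
  unimodal pore-size distributions seen in real networks.

`pore_distribution()` estimates the radius density with a Gaussian KDE
(Silverman bandwidth by default), renormalized to integrate to one on its
grid; the modal pore size `P_max` is the grid argmax. `r_min` defaults to
2 px to suppress quantization pores; it is a configuration choice, as no
canonical minimum exists.

The synthetic network generator (`make_fibril_image()`) defaults to a
**mesh** layout — two near-orthogonal families of fibers at jittered,
roughly regular spacings — because fibrillar gels have a characteristic
mesh size. A Poisson-line layout (`layout = "random"`) is also available,
but its cells have exponentially distributed inscribed radii (no interior
mode), which is not how gel networks look. The generator renders straight
strokes only: it does not emulate fiber curvature, thickness variation,
out-of-plane blur or staining noise, so passing recovery tests show the
*estimators* are correct, not that segmentation of real confocal data is
trivial.

For shrink analyses the package compares a network with a uniformly
rescaled copy (`rescale_mask()`, bilinear); the tests pool pores from three
1024×1024 px networks at 1 µm/px (about the field of a stitched 5×5 tile
mosaic, with `P_max` around 20–26 µm) per condition — pooling stabilizes
the KDE mode, and the fine raster keeps distance-transform quantization
(which is visible at 4 µm/px) negligible.

## CD spectra

`preprocess_cd()` applies a fixed, documented order: replicate averaging →
water-reference subtraction → HT masking → Gaussian smoothing (σ = 10
samples, small to preserve band shape) → optional normalization. Typical
method sections leave this order underdetermined, so the package fixes one
and records it in the output metadata; note that
normalization last means band positions are unaffected (only amplitudes
scale), which the tests verify. Normalization divides by the **Euclidean
norm** over valid (unmasked) samples — "the norm of each spectrum" is not
otherwise specified — and ellipticities stay in measured millidegrees (no
mean-residue conversion, since chain concentrations of filtered gel
suspensions are unknown).

HT masking invalidates wavelengths where the photomultiplier voltage
reaches 600 V; a spectrum crossing 600 V above 195 nm fails acquisition QC
(flag, not error), mirroring the instrument acceptance rule. Band features
are local extrema (sign changes of the first difference with a prominence
floor of 2% of the dynamic range) plus values read off the grid at
197/203/207/220/222 nm — the canonical coil, elastin Cotton band,
beta-turn, PPII and triple-helix positions. `fit_superposition()` computes
least-squares component weights on the common valid support (optionally
non-negative, or fixed weights such as the 2:1 collagen:elastin mass
ratio), with the residual RMS as the misfit measure.

The synthetic basis bands of `make_cd_spectrum()` are fixed Gaussian
fixtures centered at those canonical wavelengths, with a documented
temperature-dependent shift of the elastin band from 203 toward 207 nm;
they are test scaffolding, not claims about real protein spectra.

## Problem sizes, determinism and limits

The test and acceptance runs use desk-scale problem sizes chosen once:
synthetic videos at one frame per 5 s (σ scaled to 11 samples to keep the
~55 s smoothing window of σ = 50 at 0.9 frames/s), 128×128 px frames with
a ~42 px gel disk, cyclic traces sampled at 5 s, and the pooled network
construction above. All generators are bit-reproducible under a seed, and
`run_pipeline()` runs are bit-identical across repeats for a fixed seed
(verified by manifest MD5 comparison).

Known limitations: one specimen per video (no multi-gel tracking); no
drift correction (drift is modeled but off by default); 2-D pore analysis
only; no CONTIN/SELCON-style secondary-structure deconvolution — band
positions and superposition weights are reported instead; the volume
stroke is an isotropy-based estimate, not a measurement.
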