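---
title: "Methods: models, parameters and design choices in vasquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in vasquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasquant)
```

vasquant packages five measurement pipelines for microscopy of the
developing vasculature and of endothelial monolayers. This vignette is the
package's account of the underlying models, the tunable parameters and their
defaults, the synthetic-data generators the tests rest on, and the places
where the design was genuinely open and a choice had to be made.

## Calibration and coordinate conventions

All images are plain matrices wrapped with a single isotropic `pixel_size`
(µm per pixel). Anisotropic calibration is rejected rather than silently
averaged, because every downstream quantity (areas in µm², distances in µm)
assumes isotropy. Pixel size always comes from the caller or a config file,
never from TIFF metadata; resolution tags are written in too many dialects
to be trusted, so when an interpretable tag disagrees with the configured
value by more than 1% the package warns and uses the config. Coordinates are
row-major with the origin at the top-left, x along columns, y along rows,
0-based, reported in µm as `(col · pixel_size, row · pixel_size)`.

## Monolayer coordination

Endothelial nuclei are elongated, and the long axis of the nucleus is a
usable proxy for the orientation of the cell. An orientation has no head or
tail — θ and θ + π are the same axis — so orientations are *nematic* and any
statistic must be invariant under θ → θ + π in either argument. The pairwise
alignment score used throughout is

$$s(\theta_1, \theta_2) = \cos 2(\theta_1 - \theta_2),$$

the unique smooth nematic-invariant interpolation through the anchor values
1 at 0°, 0 at 45° and −1 at 90°. Under independent uniform orientations
E[s] = 0 exactly, which is what makes the score readable: a randomly
organized monolayer scores 0, a perfectly parallel one scores 1. The
implementation evaluates the score with `cospi`, so the 45° and 90° anchors
are hit exactly in floating point rather than to 1e-16.

The monolayer readout is the *coordination curve*: the mean score of all
unordered nucleus pairs, binned by centroid distance into half-open bins
`[lo, hi)`. Defaults are a 25 µm bin width and a 1000 µm maximum distance;
both are exposed because they are presentation choices, not model
parameters. Pairs at exactly the maximum distance fall outside the last
half-open bin and are dropped; empty bins carry `NA`, never a fabricated 0.
Pairs never cross images — multi-image experiments compute one curve per
image and pool them with `aggregate_curves()`, which weights each bin by its
pair count so the result equals the curve of the pooled pairs.

Nucleus segmentation is deliberately standard: Gaussian smoothing (σ = 1 px),
global Otsu threshold, hole filling, watershed on the Euclidean distance
transform to split touching nuclei, an area filter, and exclusion of
border-touching regions (their moments, and thus orientations, would be
biased by the crop). Orientation comes from the moment-equivalent ellipse:
the eigendecomposition of the second central moments of the pixel set gives
the axis lengths (4√λ) and the major-axis angle, folded into [0, π).
Externally supplied records are used as-is — border exclusion is a
segmentation concern, not a property of the records.

## Plexus regularity

A vascular plexus is a network of vessels enclosing tissue *loops*. The
pipeline thresholds the vessel marker (Otsu by default; fixed-value and
percentile thresholds are available), closes 1 px gaps, removes speckle
below 10 µm², and defines loops as connected components of the mask
complement that do not touch the image border — an open component is not a
closed loop. Background components use 4-connectivity and vessel foreground
8-connectivity, the standard complementary pairing that prevents a diagonal
vessel junction from being both connected and leaky at once. Loops smaller
than 86 µm² are discarded as segmentation artifacts; the cutoff is the
`min_loop_area` default and is logged in every report.

Circularity is the ImageJ convention `4πA/P²`, clamped to [0, 1]. The
perimeter of a rasterized region is biased if naively chain-coded, so the
package uses a corrected chain-code estimator (Vossepoel–Smeulders weights
0.980 per axial step, 1.406 per diagonal step, −0.091 per corner) on the
traced contour; on test shapes this keeps a disc's circularity within 2% of
1 and a 10:1 rectangle within 10% of its analytic value. Regularity is
summarized as the *sample* SD (n − 1) of loop area and circularity — with
fewer than two loops the SDs are reported `NA`, not 0 — and capillary
density is vessel pixels over field pixels.

## Front gradients

Marker expression near the sprouting front is profiled in three steps:
divide the raw channel by the mean intensity outside the vessel mask (so
extravascular tissue reads 1 and intravascular values are fold-over-
background — this also makes the profile exactly invariant to detector
gain), compute the exact Euclidean distance of every pixel to the nearest
front pixel, and average the normalized intensity over intravascular,
non-artery pixels in half-open 15 µm bins from 0 to 500 µm. The front is an
input mask (it is drawn by the experimenter; there is no automatic front
detection). Replicate curves are combined unweighted — each replicate
counts once, whatever its pixel count — with SEM = sd/√n per bin, and a bin
is reported only where every replicate has data. An optional constant
background subtraction is exposed for workflows that record a dark offset;
by default the pipeline operates on the raw channel.

## FLAP turnover curves

After photoconverting a junctional pool, the converted-channel ROI intensity
jumps and then decays as converted molecules exchange with the unconverted
pool. The processing chain is: per-frame background subtraction; bleach
correction by dividing with `exp(−k_b t)`, `t` from acquisition start, with
`k_b` fitted by least squares on a fixed-cell control trace (a single
exponential — one control trace cannot constrain a richer model; the fit
uses the post-conversion frames, since before conversion the converted
channel holds only background); and an affine normalization sending the
pre-conversion mean to 0 and the first post-conversion frame to 1 (an option
averages the first few frames instead). The normalized post-conversion curve
is

$$I(t) = f + (1 - f)\,2^{-t/t_{1/2}},$$

read out directly: the immobile fraction `f` is the mean of the trailing
plateau (last 10% of frames, at least 5, clamped to [0, 1]) and the
half-time is the first time the moving-average-smoothed curve (window 5
frames; full-width windows shifted inward at the edges) drops below the
mobile-span midpoint `(1 + f)/2`, linearly interpolated between frames —
the standard convention for recovery/loss half-times. If the curve never
crosses the midpoint the half-time is `NA`, never a silent 0. Traces
shorter than ~3 half-times trigger a warning because the plateau is then
biased. Manual quality control ("the junction did not move or remodel") is
carried as a boolean flag, not automated.

Because background subtraction removes offsets and normalization removes
gain, the estimates are invariant under affine rescaling of the raw
intensities; the tests assert this.

## Synthetic data: what it emulates, and what it does not

Each generator is a pure function of its spec, seed included — identical
specs give bit-identical outputs, and the caller's RNG stream is left
untouched. Ground truth is always returned with the rendering.

**Nematic fields.** Orientations come from a smooth director field: complex
white noise of the *doubled* angle is Gaussian-smoothed (via FFT, periodic
boundary) with kernel width ξ and the argument halved. Smoothing the 2θ
representation avoids the π-wraparound artifacts of smoothing angles
directly; ξ = 0 degenerates to i.i.d. uniform orientations and ξ = ∞ to a
single common orientation. Per-nucleus "von-Mises-style" jitter is
wrapped-normal noise of sd κ on the doubled angle (κ defaults to 0.2;
von Mises and wrapped normal are indistinguishable at such concentrations).
Nuclei (defaults 14 × 7 µm, realistic for endothelial nuclei) are placed by
rejection sampling with centre spacing of at least one major axis, which
guarantees non-overlap, and rendered as binary ellipses without
anti-aliasing so segmentation tests are deterministic.

**Vessel networks.** Seeds on a triangular lattice — whose Voronoi cells
are regular hexagons of the requested mean area (default 900 µm²) — are
displaced uniformly within `perturbation × spacing`; the discrete Voronoi
boundary is dilated to the vessel width (default 5 µm) with an exact
Euclidean disc. Ground-truth loop records are measured from the rendered
mask itself with the package's own `extract_loops`, so generator and
analyzer share one geometric definition; tests against an independent
analytic oracle (the inset-hexagon area of the unperturbed lattice) keep
that shared definition honest.

**Front gradients.** Intravascular pixels get
`extravascular_mean · (B + (A − B) e^{−d/λ})` plus Gaussian noise, with `d`
the exact distance to the front; extravascular pixels get the plain mean.

**FLAP traces.** Raw traces are
`(background + amplitude · I(t)) · e^{−k_b t_{global}}` plus noise, with
pre-conversion frames at background and bleaching running from acquisition
start (a microscope bleaches from the first frame, not from conversion).
Each trace is paired with a fixed-cell control (`I ≡ 1`) sharing the bleach
rate — exactly the object the bleach fit needs.

**Pulse-chase patches.** Each (16 µm)² patch carries 1–2 random quadratic
Bézier "junctions" ~1.2 µm wide; the surface channel stains them fully, the
pulse channel retains a class-dependent ratio drawn from three distributions
(means 0.85 / 0.5 / 0.15 for low / intermediate / high turnover, sd 0.03 —
separated by far more than 4 sd). The default class mix (44 / 24 / 32% for
high / intermediate / low) reflects a typical wild-type composition.

These generators emulate geometry and first-order intensity statistics, not
microscopy: there is no point-spread function, no shot noise or camera
model, no uneven illumination, no z-dimension, and segmentation targets are
rendered binary. Passing tests therefore demonstrate that the *measurement*
chain is correct and unbiased on data whose truth is known — not that
segmentation would be robust on any particular microscope's images.

## Numerical choices and degenerate inputs

- Distance transforms are exact Euclidean (verified against brute-force
  nearest-pixel search); distances and bins are half-open `[lo, hi)`
  everywhere, with ties at a maximum excluded.
- Collinear pixel regions get their minor axis clamped to one pixel with a
  warning; regions under 5 pixels are not fitted.
- Constant images yield empty segmentations with a warning, not errors;
  empty front masks and length-mismatched traces are errors.
- The bleach fit starts from a log-linear regression and refines with
  `nls`; if the start already fits to machine precision (noiseless data)
  the refinement is skipped, and the rate is floored at 0.
- The 1-D 3-means initialization in `classify_turnover` uses the 10/50/90%
  score quantiles, making the clustering deterministic.

## Problem sizes used by the test suite

The statistical tests run at desk scale, chosen once: the random-monolayer
null uses 10⁴ nuclei (~2.4 × 10⁷ pairs within 1 mm); the coordination-decay
check pools three 2000 µm monolayers of 900 nuclei (mirroring a three-
experiment design with >10⁴ pairs each); segmentation agreement uses one
rendered 1200 µm field of 550 nuclei; plexus agreement uses ~50-loop
networks; FLAP recovery uses 20 seeds per parameter combination, summarized
by the mean recovered parameter per combination (at an immobile fraction of
0.7 the mobile span is only 0.3, so single-trace half-time reads under 1%
noise scatter by up to ~30% around a correct mean — an intrinsic property
of reading a shallow crossing, which averaging over traces removes).

## Known limitations

- Loop perimeters (and hence circularities) carry rasterization bias of a
  few percent for loops only a few pixels across; areas do not.
- The half-time estimator reads a single crossing; for very high immobile
  fractions a model fit would have lower variance, but the plot-reading
  definition is kept because it matches how such curves are convention-
  ally quantified.
- `aggregate_curves` assumes identical bin definitions and refuses
  otherwise; it does not resample.
- The junction-patch module manages blinding and bookkeeping; it does not
  classify morphology. The quantitative turnover score is an extension
  calibrated on synthetic data only.
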