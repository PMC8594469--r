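---
title: "Quantifying single-molecule mRNA transport: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying single-molecule mRNA transport: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnatraffic)
```

This vignette is the package's own account of the models it implements, the
parameters that matter, the numerical choices made where the design was
genuinely open, and what validation on synthetic data does and does not
establish about real microscopy data.

## The biological setting and the motion model

In live-cell single-molecule imaging of localized mRNAs, most molecules
diffuse in the cytoplasm while a small subpopulation is carried by
microtubule motors in fast, nearly rectilinear runs toward the cell
periphery. The package models a particle population as a two-state mixture:

- **Diffusive particles** perform a 2D random walk with per-axis step
  variance $2D\,\Delta t$, so the ensemble MSD is $4D\tau$. The default
  diffusion coefficient is $D = 0.1\ \mu m^2/s$, a typical value for
  cytoplasmic mRNP particles of this size class.
- **Directed particles** advance $v\,\Delta t$ per frame along a heading
  that accumulates Gaussian angular jitter (default 0.1 rad/step). The
  default speed is $v = 2.6\ \mu m/s$, the regime of fast kinesin-driven
  cargo. No pausing occurs by default; a geometric run/pause model is
  available behind `pause_prob`, because published run/pause statistics for
  this cargo class are not established and the classifier's target
  phenotype (high displacement, high linearity) does not require them.

Apparent positions carry Gaussian localization noise (default
$0.03\ \mu m$, a typical single-molecule localization precision at these
signal levels). Acquisition defaults to 6.66 frames/s over 100 frames for
single-colour tracking and 7.36 frames/s for two-colour work, matching
common spinning-disk protocols for this kind of experiment.

Drug perturbations act at the population level: `nocodazole`
(microtubule depolymerization) forces the directed fraction to zero;
`cytochalasinD` (actin disruption) and `dmso` (vehicle) leave the
population untouched — with an identical seed they reproduce the untreated
population exactly, which is what makes the A/B control comparisons in the
tests sharp.

The default directed fraction is 5%, the middle of the few-percent range
this kind of reporter typically shows; when a cell geometry is supplied,
directed tracks head toward the nearest cell-edge point (anterograde bias),
otherwise headings are uniform.

## Synthetic images

Rendered frames are `background + sum of Gaussian PSFs + Gaussian noise`.
Emitter intensity is *integrated* intensity: a multiplicity-$m$ cluster
draws $m \times N(\mu, \sigma)$ (default $\mu = 1000$, $\sigma = 150$
a.u., clipped at zero), and the rendered Gaussian integrates to that value,
so rendering conserves total signal. The PSF sigma defaults to
$0.17\ \mu m$ (diffraction-limited imaging around 500–600 nm with a high-NA
objective) on a $0.16\ \mu m$ pixel grid.

Deliberately **not** modelled: photobleaching and blinking, EMCCD
excess noise, 3D defocus, and microtubule-network geometry. Passing tests
on these synthetics therefore validates the *estimators* (detection,
linking, metrics, classification, PDI, pairing) under the statistical
structure the analysis assumes; they do not certify performance under
camera-specific noise or dense, heterogeneous backgrounds of real movies.

## Spot detection

Detection follows the standard LoG pipeline: Gaussian smoothing at scale
`log_sigma` (in µm, converted by the pixel size; match it to the PSF),
a negated discrete 5-point Laplacian scaled by $\sigma_{px}^2$, local
maxima over 8-neighbourhoods, thresholding, non-maximum suppression, and
3×3 quadratic sub-pixel interpolation (offsets clamped to half a pixel).
Numerical choices:

- Boundary handling is by reflection, for both smoothing and Laplacian.
- The automatic threshold is *mean + 5 sd of the filtered background*,
  estimated robustly as median + 5 MAD of the filtered image so that the
  spots themselves cannot inflate the cut. Real datasets should calibrate
  `threshold` explicitly; arbitrary-unit thresholds do not transfer
  between cameras or gain settings.
- Plateau ties in the maxima are resolved deterministically (descending
  response, then lowest row, then column) during suppression.
- Integrated intensity is the pixel sum in a disc of radius
  $3\sigma$ (98.9% of a Gaussian's mass) minus the median of a
  $[\sigma\ldots 2\sigma]$-scaled annulus times the disc area. Near the
  frame border the disc is clipped rather than dropped, so border spots
  keep a (slightly underestimated) intensity instead of vanishing.
- Detection is 2D; z-stacks are expected to be maximum-projected first
  (`max_project()`).

## Tracking and metrics

Linking is greedy global-nearest-neighbour per frame pair: all candidate
links within `max_link_dist` are sorted by ascending distance (ties by
track id, then spot order) and accepted one at a time. Gaps up to
`max_gap` frames are closed with linearly interpolated virtual spots
flagged `interpolated`; these participate in geometric metrics but carry
no intensity. Greedy GNN is deterministic and adequate for the sparse
fields this assay produces; it is not a multi-hypothesis tracker and will
switch identities in dense crossings.

MSD uses the overlapping time-average estimator; at a track's maximal lag
there is a single window, so full-lifetime MSD equals the squared net
displacement — the identity the classifier's MSD anchor relies on.
Ensemble curves average per-track curves with equal weight per track. VAC
is normalized by the mean squared velocity (so $\mathrm{VAC}(0) = 1$); the
unnormalized covariance is available via `normalize = FALSE`. All-zero
velocity tracks return a zero curve with $\mathrm{VAC}(0)$ defined as 1,
and zero-path-length tracks get linearity 0; both cases are messaged.

## Classification

The duration filter keeps tracks strictly longer than 2.5 s. At 6.66 fps
the implied minimum frame count is computed as
$\lceil \text{duration} \times \text{rate} \rceil$ (plus one if the
product is integral, preserving strictness), giving the familiar 17-frame
rule; `filter_by_duration()` itself tests `(n-1)\Delta t >` threshold
directly, so the two agree on which tracks survive in all non-degenerate
cases.

Classification uses strict inequalities — displacement $> 4\ \mu m$ *and*
linearity $> 0.7$ — with boundary ties resolved to short/diffuse, because
the thresholds are defined as exceedances over a control distribution.
`derive_thresholds()` formalizes the control comparison: given metrics
from a depolymerized control, each threshold is set so that at most a
`target_fpr` fraction of control tracks strictly exceeds it. Marginal
quantiles are used rather than a joint 2D frontier; since a directed call
requires exceeding *both* cuts, the joint control false-positive rate is
also bounded by `target_fpr`. A joint frontier would be strictly more
powerful and is noted as future work.

## Peripheral Distribution Index

The PDI implemented here is the second-moment ratio

$$\mathrm{PDI} = \frac{\sum_i w_i d_i^2/\sum_i w_i}{\overline{d_p^2}},$$

with distances from the **nucleus centroid** and the denominator averaged
over cytoplasm pixels (cell minus nucleus). This is the unique simple
statistic with the three defining behaviours: exactly 1 for uniform
cytoplasmic signal, below 1 for perinuclear and above 1 for peripheral
distributions, and 0 when all signal sits at the centroid. It is invariant
under rigid motions and uniform dilation, and strictly increases when any
weight moves farther from the centroid. Both spot-count and
intensity-weighted modes are provided, since FISH-style data can be
quantified either way; unit spot weights are the default.

## Cluster analysis

Spot-intensity histograms use half-open bins anchored at zero. Cluster
calling is a strict intensity exceedance; multiplicity is
`round(intensity / reference)` with a floor of 1. Because absolute
intensity units are camera-specific, the package calibrates the cut from
the data: the single-molecule peak is the argmax of a Gaussian KDE of the
intensity sample, and the threshold defaults to 3× that mode — above the
single-molecule distribution's practical support, below the six-mer
regime typical of multimeric RNA clusters. With a multimodal KDE the
lowest mode is used (the single-molecule peak is always the lowest), with
a warning. Fixed absolute thresholds remain available for data with a
stable calibration.

## Cotransport

Two-channel tracks are paired by mean per-frame Euclidean distance over
their common frames: pairs with at least `min_overlap` common frames and
mean distance at most `max_sep` (default $0.3\ \mu m$, about the
diffraction limit — the scale below which two colocalized emitters cannot
be distinguished) become candidate events, accepted greedily by ascending
mean distance with each track used at most once. Event distance and speed
are measured on the mRNA channel over the overlap window; for true pairs
the channel choice changes nothing beyond localization noise. Channels
are treated as simultaneous; sequential two-colour excitation introduces a
sub-frame offset that is ignored here and would bias pair distances only
at the highest speeds.

Kymographs sample each frame by bilinear interpolation along a polyline
discretized at one-pixel arc steps, taking the maximum across
`line_width` perpendicular offsets.

## Problem sizes and determinism

Every stochastic operation takes an explicit `seed` and uses one RNG
stream per call, restoring the caller's stream afterwards; identical
seeds give identical outputs through the whole pipeline (the run manifest
records md5 hashes to make this checkable). The validation suite uses
ensembles of 500 tracks × 100 frames for closed-form MSD/VAC checks,
$10^4$ spots for PDI anchors, and 256-px rendered cells with 100 spots
for detection/cluster checks — sizes chosen so each property is measured
well inside its tolerance while the whole suite runs in a couple of
minutes on a laptop.

## Known limitations

- 2D only; no 3D tracking or astigmatic localization.
- Greedy linking has no motion model; dense fields need a LAP/Kalman
  tracker upstream, whose CSV output this package can consume.
- The intensity model is Gaussian; real single-molecule intensity
  distributions are right-skewed, which shifts KDE modes slightly.
- Segmentation is out of scope: cell and nucleus masks are inputs
  (or synthetic).
- Within-track motion-state segmentation (run/pause HMMs) is not
  attempted; classification is whole-track.
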