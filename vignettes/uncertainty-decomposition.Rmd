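---
title: "Decomposing contour-propagation uncertainty: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing contour-propagation uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contourvar)
```

## The measurement problem

When a deformable image registration (DIR) propagates organ contours from
one CT study to another — for adaptive re-planning or atlas-based automatic
segmentation — the propagated contour carries two entangled uncertainties:
the residual error of the registration itself, and the ordinary variability
of human delineation. `contourvar` implements the analysis that separates
them.

The design uses two observers and two CT studies per patient. Writing
$ROI_{ij}$ for the contour drawn by observer $i$ on study $j$, and
$ROI_{iD}$ for observer $i$'s CT2 contour propagated back to CT1:

* **Interobserver variation** $V_{IO}$: distance between $ROI_{11}$ and
  $ROI_{21}$ (one value per patient).
* **Total variation** $V_T$: distance between $ROI_{i1}$ and $ROI_{iD}$
  (one value per patient per observer — hence twice the interobserver
  sample size).
* **Intraobserver variation** $V_{IA}$: distance between $ROI_{i1}$ and a
  later recontouring session $ROI_{iA}$, measured on a patient subset
  (default 5, giving $n = 10$ with two observers).

If registration and recontouring were perfect, $V_T$ would be zero. In
practice $V_T$ mixes the registration residual with intraobserver
variation; treating the two as independent population-like components they
separate in quadrature,

$$E_{def} = \sqrt{V_T^2 - V_{IA}^2},$$

and the margin that would cover both the registration error and
interobserver variation is the quadrature sum

$$m = \sqrt{E_{def}^2 + V_{IO}^2}.$$

All distances are the *directed mean surface distance* (a mean-Hausdorff
adaptation): for every sampled point of the primary surface, the Euclidean
distance to the nearest point of the secondary surface, averaged over
primary points.

## The distance statistic

`sample_surface()` resamples each contour polygon's perimeter at uniform
arc length (default step 0.5 mm — an order of magnitude below the smallest
organ-level variation we care about, about 0.9 mm) and keeps points on
their original planes: contours are rings, not meshed surfaces, matching
the planar structure-set data the statistic is defined on. No end caps and
no inter-slice interpolation are added; this is a documented dialect
choice, since commercial implementations do not publish their surface
model.

`directed_mean_surface_distance()` is deliberately **directed**, with the
CT1 original contour always primary: every comparison in the schema
originates at a CT1 contour, and fixing the direction globally removes a
silent asymmetry (the directed distance from a point to a segment is zero;
the reverse is not). A symmetric mode exists for sensitivity checks.
Distances are point-to-point, never approximate: the kd-tree search is
exact and is tested for equality against an all-pairs reference, and the
refinement-stability test bounds the discretization error of the
point-sampled statistic (halving the step moves the statistic by < 2% on
smooth phantoms).

Numerical edge cases: empty clouds are precondition errors; identical
clouds give exactly zero; the statistic is invariant under rigid motion to
1e-9 and independent of point order.

### The flat-limit calibration

The synthetic noise model leans on one closed form: if a surface is
displaced along its normal by zero-mean Gaussian offsets with SD
$\sigma$, the directed mean distance to the displaced surface tends to the
half-normal mean $\sigma\sqrt{2/\pi} \approx 0.80\,\sigma$ as the surface
grows. This is asserted directly (a 100 × 100 point plane) and again
through the delineation simulator.

## Smooth fields, not registrations

The package never optimizes a registration. The commercial optimizer whose
behaviour motivated this analysis is closed; what the *analysis* needs is
propagated contours with a controllable, known residual error. So
"DIR error" is an injected smooth displacement field:

* `bspline_field()` — a cubic tensor-product B-spline lattice (the
  standard free-form-deformation representation), zero outside a support
  box plus a smooth taper band. Partition of unity, support containment
  and linearity in the coefficients are tested, and the interpolation is
  verified against a naive 64-term basis sum.
* `random_smooth_field()` — seeded Gaussian coefficients rescaled so the
  RMS displacement *magnitude* over a probe grid inside the support equals
  the requested amplitude exactly (the rescale is linear). Note the
  magnitude convention: an isotropic field of RMS magnitude $\sigma_{def}$
  has a surface-normal component of SD $\sigma_{def}/\sqrt{3}$, and only
  that component moves the surface-distance statistic. The recovery tests
  therefore compare the recovered $E_{def}$ against the *measured*
  ground-truth propagation distance, not against $\sigma_{def}$ itself —
  both sides see the same projection.
* `focused_second_pass()` — the second, organ-focused registration pass is
  modelled as what it is reported to achieve: a local attenuation of the
  residual (scale $1 - r$ inside the focus organ's bounding box, smoothly
  blended outside). The recovered percent reduction tracks the injected
  $r$ to a few points.

Deformed contours are kept planar by re-projecting each contour onto the
plane of its mean displaced $z$; the maximum projection distance is
recorded on the result rather than silently dropped. For smooth fields the
induced error is second order.

## What the synthetic cohorts emulate

`simulate_cohort()` realizes the full two-observer, two-CT schema per
patient with three seeded noise sources (`noise_spec()`):

* **Observer bias** — a persistent smooth scalar field per observer
  (pointwise SD `sigma_inter_mm`), displacing vertices along the in-plane
  outward normal. Because the bias is persistent, it cancels within
  observer and survives between observers, so $V_{IA} < V_{IO}$ emerges
  structurally rather than by fiat.
* **Session noise** — a fresh smooth field per delineation session
  (SD `sigma_intra_mm`). Smoothness (correlation length ~20 mm) reflects
  that human delineation error is spatially coherent, and keeps polygons
  simple.
* **Propagation residual** — a `random_smooth_field()` of RMS
  `sigma_def_mm` applied to the contour that the exact inverse of the
  anatomical warp would return. The CT2 contour is *constructed* as the
  forward warp of a CT1-frame delineation, so the exact inverse is known
  by construction and the injected residual is exactly the difference
  between the propagated contour and its residual-free reference (stored
  per patient as ground truth for the recovery tests). One consequence:
  observer bias is evaluated at CT1-frame coordinates for both sessions,
  i.e. the bias is consistent across studies.

Noise fields are random-Fourier-feature Gaussian processes (squared
exponential kernel), whose pointwise SD is exact by construction — this is
what makes the half-normal calibrations quantitative.

Per-patient position jitter (±25 mm) and size jitter (±10%) make each
patient sample a different region of the persistent bias fields, so
cohort-level averages converge. Inward displacement is clamped at 60% of
the vertex-to-centroid distance: without it, noise with SD ~2 mm
occasionally collapses optic-nerve-calibre slices, which no human observer
would do; the clamp touches only the extreme inward tail, and all
quantitative calibrations use large-radius tubes where it never triggers.

Two presets mirror the study arms: `preset_head_neck()` (30 patients, 10
organ phantoms — ellipsoids, tubes and crescents standing in for
brainstem, cord, oral cavity, larynx, parotids, optic nerves and eyes) and
`preset_pelvis()` (20 patients; prostate, bladder, rectum; focused
second-pass subsets of 7 and 4 patients). The default noise magnitudes
(head-neck 1.8 / 1.0 / 2.2 mm, pelvis 2.0 / 1.5 / 2.8 mm for
inter / intra / residual) were chosen once so that the measured
$V_{IO}$, $V_{IA}$ and $E_{def}$ land in the published per-organ ranges;
they are tuning constants of the emulation, not estimates inferred from
data.

What the generator does **not** emulate: image content (no CTs are
synthesized), anatomically structured disagreement (observers differ by
smooth random fields, not by systematic boundary ambiguities at specific
interfaces), time trends beyond the single CT1→CT2 deformation, and any
dependence of registration error on image quality. Passing tests certify
the pipeline's arithmetic and statistical behaviour under the stated noise
model — they do not certify any particular clinical registration
algorithm.

## Decomposition and statistics

`edef_per_sample()` applies the quadrature subtraction per total-variation
sample using the organ-level *mean* intraobserver variation — the only
construction available when recontours exist for a subset of patients, and
the one that gives the registration-error column the same sample size and
a spread comparable to total variation. A negative discriminant (sample
below the intraobserver mean) is clamped to zero and *counted*; clamp
counts travel to the report manifest.

`combined_margin()` feeds unrounded means into the quadrature sum; every
rounding in the package is presentation-only, half away from zero to one
decimal (`round_half_away()`), matching how the published tables print.
Where both registration passes exist, the margin uses the second-pass
error by default (configurable) — `reproduce_tables()` shows this rule
reproduces the published bladder margin while the rectum row matches the
first-pass value, one of several printed rows that cannot be rebuilt
exactly from their own rounded inputs (the optic-nerve margins being the
clearest cases); these are flagged, never patched.

`two_sample_t()` wraps the classic pooled Student test (Welch available —
with 60-vs-30 samples of unequal spread the choice is material, so both
are computed) and `classify_comparison()` issues the three-way verdict
(`edef_less` / `not_different` / `edef_greater`) at α = 0.05,
uncorrected, with a clearly-labelled Holm-adjusted column as supplementary
output.

## Reproducibility and problem sizes

Every random draw derives from one master seed through a documented
stream-splitting scheme (`seed_stream()`), so a cohort, and hence an
entire report bundle, is byte-reproducible. The test suite runs the
quantitative recovery checks at the sizes a single-CPU desk run supports
comfortably: oracle equivalence on clouds of up to a few hundred points,
flat-limit calibration at 10⁴ points, quadrature recovery on a
30-patient single-organ cohort, second-pass recovery at 20 patients, and
one full-size run of both default presets (which is what fixes the
published N bookkeeping of 60 / 30 / 10 per organ). The analysis scripts
under `analysis/` rerun the full presets end to end.

## Known limitations

* The directed statistic with CT1 primary is a convention; the published
  implementation's directionality is unknown. Symmetric mode quantifies
  the sensitivity.
* Point-to-point distances over ring-sampled surfaces bound, rather than
  equal, true surface separation; the refinement-stability test bounds
  the gap.
* The quadrature model assumes independence of intraobserver variation
  and registration residual; the generator enforces it, real data need
  not.
* DICOM RT-STRUCT I/O is not provided; the canonical interchange format
  is the package's JSON dialect (`write_structure_set()` /
  `read_structure_set()`).
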