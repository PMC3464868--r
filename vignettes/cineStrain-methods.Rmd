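---
title: "Global myocardial strain from cine images: methods and design"
author: "cineStrain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global myocardial strain from cine images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cineStrain)
```

## The measurement problem

Global myocardial strain summarises how much the endocardial border of a
ventricle shortens between end-diastole and end-systole. On cine imaging
(SSFP MRI movies of one slice across the cardiac cycle, typically 25
phases, ~1 mm in-plane resolution, 30–40 ms per phase) two routes lead to
it:

* **Endocardial border delineation (EBD).** An operator clicks a handful
  of border points on every frame; the software densifies them by
  piecewise cubic Hermite interpolation, measures the border length
  \(L_t\) as the sum of Euclidean distances between points, and applies
  the Lagrangian strain definition
  \[
    \varepsilon_t \;=\; 100\% \cdot \frac{L_t - L_0}{L_0},
  \]
  with \(L_0\) the maximal border length over the cycle. The reported
  global strain is the absolute value at the minimal length,
  \(100\,(L_0 - L_{\min})/L_0\). Nothing here requires tracking
  individual tissue points — only the overall border length.

* **Feature tracking (FT).** The operator delineates the border once, on
  a single frame; an algorithm follows it automatically through the
  cycle by combining 2-D template matching on brightness inhomogeneity
  (trabeculation-like features) with 1-D edge tracking perpendicular to
  the border, plus spatial smoothing across adjacent tracking points.
  Global strain again comes from the tracked border lengths;
  longitudinal strain uses the open four-chamber border, circumferential
  the closed short-axis border, and radial strain the mean relative
  displacement of border points toward the cavity centroid.

Patient data for which both methods were designed are not distributable,
so the package ships a deforming phantom generator with analytically
known strain: every claim the test suite makes is checked against that
ground truth or against closed-form oracles.

## Choice of reference length

\(L_0\) is the *maximal* border length over the cycle, not the length on
frame 0. Cine acquisitions are ECG-triggered at arbitrary phases; keying
the reference to the observed end-diastole makes the strain estimate
independent of the trigger phase. A constant-length sequence yields a
valid all-zero curve. Internally strain is signed (shortening negative);
reported peaks are absolute values, the convention of the clinical
literature.

## Border densification

`interpolateBorder()` interpolates x and y separately against the
cumulative chord-length parameter with monotone (Fritsch–Carlson)
Hermite tangents, via `stats::splinefun(method = "monoH.FC")`. Monotone
tangents cannot overshoot, which matters for sparse, unevenly clicked
manual points: a classical cubic spline can loop between distant
anchors, and a loop inflates the border length. Closed contours are
wrap-padded with three neighbouring anchors on each side before fitting,
so the seam sees the same local stencil as every interior point and the
interpolant is effectively periodic; the closing span is part of the
parameterisation. Output points are uniformly spaced in the parameter;
requesting exactly the anchor count returns the anchors themselves (the
interpolant passes through its nodes). The default of 200 output points
keeps the length error from discretising anatomical curvature at 1 mm
resolution below 0.1%; on phantom truth, doubling it moves the recovered
peak by well under 0.05 strain-points because interpolation commutes
with the uniform scaling of the truth deformation.

## The feature tracker

`trackContour()` advances the contour frame by frame:

1. **2-D matching.** A square template (half-width 5 px) centred on each
   point's current position is matched in the next frame by maximising
   normalised cross-correlation (NCC) over integer displacements within
   a 5 px radius, with parabolic sub-pixel interpolation of the peak.
   NCC is the maximum-likelihood matcher under Gaussian intensity noise
   with unknown gain. A weak quadratic motion prior (0.002 per px²) is
   subtracted from the NCC surface: at 1 mm / 30–40 ms resolution the
   true inter-frame motion is a small fraction of the search range, and
   gain-normalised matching cannot distinguish the endocardial
   (blood–myocardium) from the epicardial (myocardium–background) edge —
   both are step-down edges — so without the prior an equally good far
   match can capture a run of points.
2. **Spatial coherence.** The raw displacement field is moving-averaged
   over 5 adjacent contour points (periodic for closed contours), and
   one Laplacian pass pulls each moved point halfway toward the midpoint
   of its neighbours. Per-point matching carries no tangential
   information along feature-poor border stretches (the aperture
   problem); without these passes the point chain develops a zigzag
   random walk whose polyline length diverges. Flat (zero-variance)
   templates contribute no match and inherit the smoothed neighbourhood
   displacement.
3. **1-D border refinement.** Each point then slides along the local
   contour normal to the intensity-gradient maximum within ±2 px
   (sampled at 0.25 px, parabolic peak interpolation, profiles averaged
   over five tangentially offset lines — the edge is locally straight,
   so the averaging suppresses noise without biasing the edge position).
   These offsets are applied *unsmoothed*: this is the step that removes
   per-point radial error, and averaging opposite-signed corrections
   across neighbours would cancel exactly the re-locking it provides. A
   final light Laplacian pass restores coherence.
4. **Drift compensation.** Cardiac motion is cyclic, so after the last
   frame the tracker takes one wrap-around step back onto frame 0; the
   residual against the initial contour is accumulated drift and is
   removed by linear redistribution across the cycle. (This step is
   meaningless for non-cyclic motion such as a rigid translation sweep,
   and is switched off in that check.)

Tracking is fully deterministic. The defaults (template half-width 5 px,
search radius 5 px, smoothing window 5 points, both refinement and drift
compensation on) assume ~1 mm pixels and a few px of inter-frame motion;
all are exposed through `trackingParams()`.

## Segmental strain

`ftSegmentalStrain()` partitions the reference contour into segments of
equal arc length (default 6) and assigns every border *edge* to a
segment by the arc-length fraction of its midpoint, so segment lengths
sum exactly to the global border length on every frame. Per-segment
strain is evaluated between the global end-diastolic (maximal total
length) and end-systolic (minimal total length) frames. This choice is
deliberate: with a common frame pair, the mean of segment strains
weighted by segment reference length equals the global strain exactly
(additivity of polyline lengths), which is the property the validation
checks. Letting each segment pick its own temporal extremes inflates
segment peaks under measurement noise — extreme-value bias — and breaks
additivity by over a strain-point on tracked phantoms. Homogeneously
deforming phantoms make global and segmental truth coincide, which is
also why the phantom deforms by pure similarity scaling.

## The phantom generator

`makePhantom()` renders an SSFP-like scene — bright blood pool (1.0),
darker myocardium (0.5), dim background (0.1) — for two geometries: a
short-axis ring (closed border, default end-diastolic endocardial radius
30 mm, wall 8 mm) and a four-chamber "U" (open border, default arc
length 160 mm: two straight arms joined by a semicircle, a stylised
single-ventricle long-axis cavity). The whole scene is scaled about its
centre per frame by
\(s(t) = 1 - a\,w(t)\), where \(a\) is the prescribed peak shortening
and \(w\) a raised-cosine waveform rising from 0 to 1 at
`round(phaseCount/3)` (a physiologically plausible systolic timing) and
returning to 0 at the implied end of the cycle. Similarity scaling makes
the ground truth exact and homogeneous: border length, segment lengths
and radii all scale by \(s(t)\).

Interfaces are blended over 1.5 px with a smoothstep profile, giving the
intensity gradient a unique maximum exactly on the border — edge
localisation is then a well-posed sub-pixel problem, as it is on real
band-limited MRI magnitude images (a hard pixel edge would leave the
gradient flat across the blend and the edge position undefined at
sub-pixel scale). Forty dark Gaussian blobs (SD 1 mm, amplitude 0.25)
are embedded at seeded material positions in the mid-wall and move with
the deformation, mimicking the trabeculation-like brightness features
the 2-D matching step exploits. Per-pixel Gaussian noise (default SD
0.05 relative to the 0.5 blood–myocardium contrast) is added last; the
intensity scene is clipped to [0, 1] before noise, as magnitude images
are non-negative. The same seed reproduces every pixel; the analytic
truth track never touches the RNG, so changing only the noise level
leaves it untouched.

What the phantom does *not* emulate: wall thickening (the wall scales
with the cavity instead), torsion and through-plane motion in the
rendered images, deformation heterogeneity, coil shading, and SSFP
banding. Passing the recovery tests therefore shows that the pipeline
measures a known homogeneous deformation correctly at realistic noise —
not that it is robust to every property of patient images.

## Out-of-plane circumferential strain bias

`simulateOutOfPlane()` models the ventricle as a truncated cone whose
cavity radius falls linearly from base (default 40 mm) to apex (20 mm)
over a long axis of default 80 mm (a typical ventricular long axis; the
analytic model needs an explicit length to convert millimetres of
displacement into a radius change). A fixed imaging plane at fraction
\(f\) of the long axis sees radius \(r_0\) at end-diastole. During
systole the tissue moves a distance \(d\) toward the apex, so the plane
now intersects tissue that at end-diastole lay more basally, with the
larger radius \(r_d\). If that tissue's true material circumferential
shortening is CS, the measured value from in-plane circumferences,
\(100\,( \text{diastolic} - \text{systolic})/\text{diastolic}\), becomes
\[
  \text{CS}_{\text{meas}} \;=\; 100\left(1 - (1 - \text{CS}/100)\,
  \frac{r_d}{r_0}\right) \;\le\; \text{CS},
\]
with equality iff \(d = 0\), and strictly decreasing in \(d\) on a
base-over-apex taper: measured circumferential strain is falsely reduced,
the more so the larger the longitudinal excursion. For the default cone
with CS 15% and \(d = 10\) mm the measured value is 7.9%.

## Agreement statistics

`blandAltman()` reports the bias (mean of paired differences) and limits
of agreement at bias ± 2 SD of the differences — the factor is exactly
2, not 1.96, and the SD uses the sample (n−1) denominator, the small-n
convention of observer-agreement studies. `covVariability()` is
100 · SD(differences) / |grand mean of all values|, the coefficient of
variability used in the CMR reproducibility literature; it is
scale-invariant and zero iff the two series agree exactly, and undefined
(an error) when the grand mean is zero.

## The validation workflow

`runValidate()` operationalises the EBD-vs-FT comparison on phantoms.
The default suite is 20 phantoms crossing strains {10, 15, 20, 25}% with
noise SDs {0, 0.05, 0.1}, alternating ring (circumferential FT) and U
(longitudinal FT) geometries, 25 phases each, with a fixed seed list
derived from one master seed. The strain range spans what ventricles
show on routine cine imaging. For each phantom, FT runs from the frame-0
truth contour on the rendered images, while EBD runs on every 10th truth
point per frame — a sparse-anchor simulation of manual clicking that
honestly exercises the Hermite densification — and the suite-level
summary reports truth-recovery errors, Bland–Altman bias/limits and the
EBD-vs-FT coefficient of variability. Every run is reproducible from the
resolved configuration it writes alongside its outputs.

Problem sizes throughout the package's own checks — 120-point truth
contours, 20-phantom suites, 25 phases, images of roughly 100×100 px —
were chosen as the smallest that exercise the geometry faithfully;
recovery results are insensitive to moderate increases in any of them.

## Numerical choices and degenerate inputs

* Coordinates are physical millimetres, 0-based, origin at the top-left
  pixel centre, x along columns — one convention everywhere, because
  strain is a physical length ratio and mixed pixel/mm conventions are
  the classic failure mode.
* Closed contours never repeat their first point; the closing segment is
  added explicitly in every length computation.
* DICOM phase ordering prefers trigger time and falls back to instance
  number; series mixing slice positions, lacking phase information, or
  with >1% pixel-spacing anisotropy are rejected with the offending file
  named.
* Coincident consecutive anchors, empty contour lists, topology /
  direction mismatches, and tracking points leaving the image all fail
  loudly rather than degrade silently.
* Parabolic sub-sample refinement falls back to the discrete peak when
  the three-point stencil is not concave; gradient refinement skips
  points with no reliable edge (peak gradient < 0.02) rather than follow
  noise.

## Known limitations

The tracker is validated on homogeneous similarity deformations; strong
regional dyskinesis would interact with its spatial smoothing. Radial
strain from an endocardium-only track is a surrogate for wall
thickening, not a measurement of it. The U geometry is a stylised
four-chamber cavity, not patient anatomy. The out-of-plane model is
analytic only — the rendered phantoms are strictly 2-D. DICOM support
covers uncompressed little-endian single-frame cine exports, which is
what scanner cine exports of the kind modelled here contain.
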