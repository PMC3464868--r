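# cineStrain

Global myocardial Lagrangian strain from cine cardiac image sequences,
by two complementary routes, with a synthetic deforming phantom that
makes both testable against analytic ground truth.

Ventricular function on cine MRI (SSFP movies of one slice across the
cardiac cycle) is increasingly summarised by *global strain*: the
relative shortening of the endocardial border between end-diastole and
end-systole,

    ε = 100% · (L − L₀) / L₀

with L₀ the maximal (end-diastolic) border length and L the border
length on any other frame; the reported global strain is the absolute
value at the minimal length. The package is written for image-analysis
methodologists and CMR researchers who need a transparent, testable
implementation of:

* **EBD (endocardial border delineation)** — sparse manually clicked
  border points per frame, densified by monotone piecewise cubic Hermite
  interpolation over a chord-length parameter, border length as the sum
  of Euclidean point distances, strain from maximal/minimal length
  (`interpolateBorder()`, `borderLength()`, `ebdStrain()`).
* **FT (feature tracking)** — automatic propagation of a single
  delineated contour through the cycle: normalised cross-correlation
  template matching on brightness inhomogeneity, 1-D refinement
  perpendicular to the border to the intensity-gradient maximum, spatial
  smoothing across adjacent tracking points, cyclic drift compensation;
  global longitudinal/circumferential/radial and segmental strain
  (`trackContour()`, `ftGlobalStrain()`, `ftSegmentalStrain()`).
* **Agreement statistics** — Bland–Altman bias with limits at mean ± 2 SD
  of the paired differences, and the coefficient of variability
  100·SD(differences)/grand mean (`blandAltman()`, `covVariability()`).
* **Synthetic phantoms** — deforming short-axis ring and four-chamber
  "U" scenes with analytically known strain, moving intramural texture
  features, and seeded noise (`phantomSpec()`, `makePhantom()`), plus an
  analytic truncated-cone model of the circumferential-strain
  underestimation caused by systolic through-plane motion
  (`simulateOutOfPlane()`).
* **An end-to-end validation workflow** (`runValidate()`) and a thin
  command-line front end (`exec/cinestrain` with subcommands `phantom`,
  `ebd`, `track`, `agree`, `validate`).

I/O covers single-slice cine DICOM series (trigger-time or
instance-number ordering, calibration from metadata), multi-frame TIFF /
RDS image stacks, and plain CSV for contours and strain curves.

## Worked example

Generate a contracting short-axis phantom with 20% prescribed border
shortening, track it, and compare FT with EBD run on sparse anchors from
the ground truth:

```r
library(cineStrain)

ph <- makePhantom(phantomSpec(truePeakStrain = 20, noiseSd = 0.05, seed = 3L))
ph
#> PhantomOutput
#>   PhantomSpec (short_axis_ring): size 30.0 mm, wall 8.0 mm, strain 20.0%,
#>     25 phases, noise 0.05, seed 3
#>   CineSequence 'phantom_short_axis_ring_seed3': 25 phases of 109x109 px,
#>     1 mm/px, 40 ms/frame
#>   StrainCurve (border): 25 frames, reference frame 0, peak 20.00%

trk <- trackContour(phantomSequence(ph), contours(truthTrack(ph))[[1]])
ftGlobalStrain(trk, "circumferential")
#> StrainCurve (circumferential): 25 frames, reference frame 0, peak 19.83%

dense <- lapply(contours(truthTrack(ph)), function(ct) {
    anchors <- coords(ct)[seq(1, 120, by = 10), ]   # 12 "manual clicks"
    interpolateBorder(anchors, topology(ct), 200L, frameIndex(ct))
})
ebdStrain(dense)
#> StrainCurve (border): 25 frames, reference frame 0, peak 20.00%
```

The tracker recovers the prescribed 20% to 19.83% from noisy rendered
images; EBD recovers it exactly because Hermite densification commutes
with the phantom's similarity deformation. The out-of-plane model shows
why in-plane circumferential strain under-reports material shortening
when the heart moves through a fixed imaging plane:

```r
simulateOutOfPlane(outOfPlaneSpec())  # base 40 mm, apex 20 mm, mid slice,
                                      # true CS 15%, 10 mm displacement
#> $trueCs
#> [1] 15
#> $measuredCs
#> [1] 7.916667
```

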