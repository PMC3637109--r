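# bmlseg — semi-automated bone marrow lesion segmentation for knee MRI

Bone marrow lesions (BMLs) are ill-defined regions of high signal
intensity inside the femur and tibia on sagittal fat-suppressed knee MRI.
Their volume — and especially its change over time — is a structural
marker of knee osteoarthritis progression, but manual volumetry is slow
and reader-dependent. `bmlseg` implements a semi-automated measurement for
researchers running reader studies or longitudinal cohorts: the reader
only marks coarse bone boundaries; bone refinement, lesion detection,
false-positive elimination and regional volumetry are automatic and
deterministic.

## Method

Three stages per scan:

1. **Bone segmentation.** Sparse manually marked boundary points per slice
   (with the articular, joint-facing points flagged) are interpolated by a
   closed periodic spline, rasterized, and refined by edge-based curve
   evolution — a geodesic active contour with edge-stopping function
   `g = 1 / (1 + |∇(G_σ * I)|²)`. The central 9 sagittal slices (2.7 cm)
   are excluded from analysis.
2. **BML segmentation** (fully automatic, run twice). A Gaussian null
   (mean, SD) is fitted to the bone-interior intensities; upper-tail
   p-values `p = 1 − Φ((I − μ̂)/σ̂)` are thresholded by Benjamini–Hochberg
   at FDR `q = 0.05`; the thresholded voxels seed region-based
   (piecewise-constant, Chan–Vese-type) curve evolution with boundary
   length penalty `μ = 0.28`, minimizing
   `Σ_in (I−c₁)² + Σ_out (I−c₂)² + μ·L`. A second pass refits the null
   excluding first-pass lesions to capture dimmer lesions; the final
   candidate set is the union.
3. **Refinement and quantification.** 3D connected components
   (26-connectivity) are kept only if within 10 mm of the articular
   surface and spanning more than one slice, then assigned to the four
   regions (medial/lateral × femur/tibia) and reported as volumes in mm³,
   with paired follow-up − baseline change for longitudinal pairs.

Because no clinical images can ship with the package, a seeded phantom
generator (`generate_phantom()`) builds sagittal knee-like volumes with
known bone geometry, planted lesions at stated contrast, and decoys that
exercise every false-positive rule — the package's entire validation bench
runs on it. Intraclass correlations for reader studies (`icc()`, models
2,1 and 3,1) are included.

## Worked example

```r
library(bmlseg)

ph  <- generate_phantom(phantom_spec(seed = 7))   # SNR-5 phantom, 2 BMLs + 3 decoys
run <- run_segmentation(ph$volume, ph$contours)   # full three-stage pipeline
print(run)
#> <bml_run> bones: femur, tibia | 14.9 s
#> <bml_report>
#>   bone        region n_components volume_mm3
#>  femur  medial femur            0     0.0000
#>  femur lateral femur            1   588.8744
#>  tibia  medial tibia            1   431.8047
#>  tibia lateral tibia            0     0.0000
#>   total BML volume: 1020.68 mm3 (2 component(s))

run$components[, c("bone", "region", "volume_mm3", "slice_span",
                   "min_articular_dist_mm", "pass")]
#>    bone        region volume_mm3 slice_span min_articular_dist_mm pass
#> 1 femur lateral femur   588.8744          4              4.941794    1
#> 2 tibia  medial tibia   431.8047          3              3.125847    1
```

The phantom's truth table plants a 597.6 mm³ lateral-femur lesion and a
435.1 mm³ medial-tibia lesion (recovered above within 1.5% and 0.8%),
plus a deep decoy (> 10 mm from the articular surface), a single-slice
decoy and an extra-osseous blob — all three correctly absent from the
report. `pass = 1` records that both lesions were found in the first
thresholding–evolution pass; dim lesions masked by bright ones surface
with `pass = 2`. Reader agreement on repeated measurements:

```r
X <- cbind(r1 = c(597.6, 435.1,  0.0, 812.4),
           r2 = c(602.1, 430.9, 12.3, 798.0))
icc(X, "3,1")
#> [1] 0.9994273
```

A thin CLI wraps the same functions
(`inst/cli/bmlseg segment|quantify|longitudinal|phantom|icc`); volumes and
masks travel as NIfTI, marked contours and parameters as JSON, reports as
CSV.

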