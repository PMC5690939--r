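# contourvar

Uncertainty decomposition for contour propagation in adaptive
radiotherapy.

When organ-at-risk contours are propagated between CT studies by
deformable image registration (DIR) — for adaptive re-planning or
atlas-based automatic segmentation — the propagated contour carries both
the registration's residual error and ordinary human delineation
variability. `contourvar` measures both with a directed mean
surface-distance statistic, separates them in quadrature, synthesizes the
planning-margin expansion that would cover them, and tests which source
dominates per organ.

With two observers and two CTs per patient (contour `ROIij` = observer
*i*, study *j*; `ROIiD` = observer *i*'s CT2 contour propagated to CT1):

- interobserver variation `VIO = d(ROI11, ROI21)`,
- total variation `VT = d(ROIi1, ROIiD)` (two samples per patient),
- intraobserver variation `VIA = d(ROIi1, ROIiA)` on a recontour subset,

where `d` is the mean over primary-surface points of the distance to the
nearest secondary-surface point (a mean-Hausdorff adaptation). Treating
registration error and recontouring variability as independent
population-like components:

    Edef = sqrt(VT^2 - VIA^2)          # residual registration error
    margin = sqrt(Edef^2 + VIO^2)      # combined quadrature expansion

Because no clinical cohort ships with the package, a seeded synthetic
generator realizes the full two-observer / two-CT schema over analytic
organ phantoms, with persistent per-observer bias fields, smooth
per-session delineation noise, and a known injected B-spline propagation
residual — so every downstream stage is testable against ground truth.

## Worked example

A ten-patient cohort of a cord-like tube phantom, with 1.5 mm observer
bias, 0.8 mm session noise and a 1.8 mm RMS propagation residual:

```r
library(contourvar)

spec   <- phantom_spec("cord", "tube", list(radius = 8, length = 90), c(0, -40, 0))
noise  <- noise_spec(sigma_inter_mm = 1.5, sigma_intra_mm = 0.8,
                     sigma_def_mm = 1.8, seed = 7)
bundle <- simulate_cohort(list(spec), noise, n_patients = 10, n_recontour = 5)

records <- compute_all_records(bundle)
summarize_records(records)
#> # A tibble: 4 x 6
#>   roi   quantity      n mean_mm sd_mm n1_flag
#> 1 cord  VDEF_TRUE    20   1.20  0.142 FALSE
#> 2 cord  VIA          10   0.886 0.326 FALSE
#> 3 cord  VIO          10   1.54  0.556 FALSE
#> 4 cord  VT           20   1.43  0.269 FALSE
```

`VT` (20 samples: 10 patients x 2 observers) exceeds `VIA` because it
also contains the injected registration residual. The decomposition
recovers that residual and builds the margin:

```r
dec <- decompose_records(records)
#> Edef 1.10 mm (ground truth VDEF_TRUE 1.20 mm), margin 1.90 mm

compare_error_sources(dec, records)[, c("n_edef", "n_vio", "t_stat", "p_value", "verdict")]
#>   n_edef n_vio t_stat p_value verdict
#> 1     20    10  -2.67  0.0126 edef_less
```

So at these settings the registration error (1.1 mm) is significantly
smaller than interobserver variation (1.5 mm) — the margin 1.9 mm is
their quadrature sum.

## The analysis workflow

The numbered scripts under `analysis/` run the full study-shaped
analysis over the two built-in presets (head-and-neck: 30 patients x 10
organs; male pelvis: 20 patients x 3 organs with focused second
registration passes), writing tables under `results/`:

1. `01_simulate_cohorts.R` — generate and cache both cohorts,
2. `02_measure_variation.R` — all per-contour-pair distances,
3. `03_decompose_margins.R` — per-organ summary and margin tables,
4. `04_compare_error_sources.R` — t-test verdicts and figures,
5. `05_printed_table_checks.R` — cross-check of the published per-organ
   tables against their own arithmetic (several printed rows cannot be
   rebuilt from their own rounded inputs; they are flagged, not patched).

`run_pipeline(run_config(...))` performs the same chain in one call and
writes a byte-reproducible report bundle with a YAML manifest.

## Documentation

The methods vignette
(`vignettes/uncertainty-decomposition.Rmd`) describes the distance
statistic and its conventions, the B-spline deformation model, what the
synthetic cohorts do and do not emulate, the decomposition's clamping and
rounding rules, and the package's known limitations.
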