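# tractwmh

Tract-level white-matter-hyperintensity burden and regional amyloid-PET SUVr
in the default mode network.

## What it does and for whom

White matter hyperintensities (WMH) on FLAIR MRI are the radiological
signature of cerebral small vessel disease. For researchers studying how
vascular injury inside specific fiber tracts relates to amyloid-beta
deposition in the cortical regions those tracts project to, `tractwmh`
provides a complete, testable analysis chain over co-registered NIfTI
volumes:

1. **WMH segmentation** — a Gaussian is fit to the histogram of
   FLAIR intensities inside the white-matter mask (least squares on
   Freedman–Diaconis bins, robust to the hyperintense lesion tail) and
   voxels above `mu + k*sigma` (default `k = 3`) are labelled WMH;
   26-connected components below a minimum size are removed as a
   deterministic stand-in for manual artifact editing.
2. **Tract volumetrics** — the WMH mask is intersected with each binary
   fiber-tract mask (cingulum → PCC, cingulum–hippocampus → MTL,
   superior longitudinal fasciculus → IPL, inferior fronto-occipital
   fasciculus → MPFC) and the per-tract volume (mL) is log10-transformed;
   zero-volume subjects drop out of that tract's model by default.
3. **SUVr quantification** — mean PET uptake in each composite DMN cortical
   ROI (assembled from parcellation labels) divided by mean uptake in the
   whole cerebellum, with an amyloid-positivity floor (default 1.17) applied
   per region.
4. **Association analysis** — for each tract-region pair, OLS of

   `SUVr = b0 + b1 * log10(WMH volume) + bX * (age, sex, ApoE e4 count, ICV) + e`

   reporting the standardized beta `b1*sd(x)/sd(y)`, two-sided p, 95% CI,
   adjusted R² and Cohen's `f = sqrt(adjR2/(1-adjR2))`, with Bonferroni
   control over the 4-test family (`p < .0125` at alpha = .05).

A synthetic phantom-cohort generator (`build_phantom_space()`,
`simulate_cohort()`) produces images, masks and covariates with known ground
truth — lesion blobs of exact voxel-quantized volume inside the tracts, PET
uptake generated from the same linear model the analysis estimates — so
every stage is verifiable end to end without any subject data. See the
methods vignette (`vignettes/tract-wmh-methods.Rmd`) for the model details
and design choices.

## Worked example

Run the demo pipeline (40-subject phantom cohort, 64³ grid at 1×1×1.2 mm,
generative slope `b1 = 0.3` for every region):

```r
library(tractwmh)
res <- run_pipeline(system.file("extdata", "demo_config.yaml",
                                package = "tractwmh"))
print(res$results, digits = 3)
#>   region      tract    b1 std_beta p_value adj_r2  ci_low ci_high cohens_f
#> 1    PCC       CING 0.399    0.946 0.00390  0.516  0.1694   0.628    1.032
#> 2    MTL CING_Hippo 0.212    0.256 0.61608 -0.205 -0.7698   1.194    0.000
#> 3    IPL        SLF 0.230    0.481 0.00572  0.262  0.0727   0.387    0.595
#> 4   MPFC       IFOF 0.279    0.367 0.03677  0.277  0.0187   0.540    0.619
#>   n_used significant
#> 1     14        TRUE
#> 2     12       FALSE
#> 3     33        TRUE
#> 4     29       FALSE
```

Each row is one tract-region model. `b1` is the slope of region SUVr on
log10 tract-WMH volume (true value 0.3 in this simulation); `std_beta`
expresses it in SD units; `n_used` differs by pair because only subjects
with WMH in a tract enter that tract's model (the cingulum tracts have
lesion prevalence 25/72 versus 55/72 for SLF/IFOF, so their estimates rest
on far fewer subjects); `significant` applies the Bonferroni threshold
.0125. The SLF→IPL pair — the best-powered one — recovers the slope
(0.23, CI [0.07, 0.39]) and is flagged significant. `run_pipeline(cfg,
out_dir = ...)` additionally writes `wmh_volumes.csv`, `tract_volumes.csv`,
`suvr.csv`, `results.csv`/`results.json` and a reproducibility manifest
(config hash + seed); rerunning the same config reproduces every file
byte-identically.

A thin command-line front end with per-stage subcommands (`simulate`,
`segment`, `tract-volumes`, `suvr`, `associate`, `run-all`) is installed at
`inst/cli/tractwmh.R`.

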