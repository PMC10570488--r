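---
title: "Methods: tract-level WMH burden and regional amyloid SUVr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tract-level WMH burden and regional amyloid SUVr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tractwmh)
```

## The scientific question and the pipeline

Cerebral small vessel disease manifests on FLAIR MRI as white matter
hyperintensities (WMH). One mechanistic hypothesis for its interplay with
Alzheimer-type pathology is retrograde: axonal injury inside a fiber tract
may upregulate amyloid-beta production in the cortical region the tract
projects to. Testing this at the level of individual default-mode-network
(DMN) pathways requires four quantitative stages, each of which this package
implements as a separately testable unit:

1. **WMH segmentation** of a FLAIR-like image restricted to a white-matter
   (WM) mask, by fitting a Gaussian to the WM intensity histogram and
   thresholding at the mean plus `k` standard deviations (default `k = 3`);
2. **tract volumetrics**: the WMH mask is intersected with each binary fiber
   tract mask (cingulum, cingulum–hippocampus, superior longitudinal
   fasciculus, inferior fronto-occipital fasciculus) and the intersection
   volume, in mL, is log-transformed;
3. **SUVr quantification**: mean PET uptake in each composite DMN cortical
   ROI (PCC, MTL, IPL, MPFC, assembled from parcellation labels) divided by
   mean uptake in the whole cerebellum;
4. **association analysis**: for each of the four tract-region pairs, an
   ordinary-least-squares model

   `SUVr_region = b0 + b1 * log10(WMH volume in tract) + bX * (age, sex, ApoE e4 count, ICV) + e`

   reporting the standardized beta `b1 * sd(x)/sd(y)`, the two-sided t-test
   p-value for `b1`, its 95% CI, the model's adjusted R², and Cohen's
   `f = sqrt(adjR2 / (1 - adjR2))`, with family-wise control at
   `alpha / 4 = .0125` (Bonferroni).

Real inputs (co-registered NIfTI volumes and a covariate CSV) can be fed to
every stage; the package also ships a synthetic phantom-cohort generator so
that the full chain is verifiable against known ground truth without any
subject data.

## The phantom generator: what it emulates, and what it does not

`build_phantom_space()` lays out parametric solids on one common grid
(default 64×64×64 voxels at 1×1×1.2 mm, the voxel geometry of a 3D FLAIR
acquisition): a WM block, four cortical blocks in the corner quadrants of a
slab sitting directly on the WM (each split into its parcellation
sub-labels), four 11×11-voxel tract tubes running through the WM and ending
face-adjacent to their paired cortical block, and a cerebellum block below.
Because every mask lives on the same grid, co-registration holds by
construction — registration is a toolchain stage, not part of the
computation under test.

Subject-level generation proceeds in three steps:

* **Covariates** are drawn from the reference cohort's marginals: age
  ~ N(74.96, 8.13) years, intracranial volume ~ N(1455.26, 132.46) mL,
  P(male) = .493, ApoE e4 allele count with P(1 copy) = .099 and
  P(2 copies) = .366.
* **Lesions**: per tract, a subject has any WMH with the cohort's per-tract
  prevalence (55/72 for SLF and IFOF, 25/72 for the two cingulum tracts);
  when present, the target volume is log10-normal with the cohort's
  per-tract log-scale SDs (.66, .65, .94, .74). The log10 locations are
  placed at phantom scale (−1.38 to −1.58, i.e. medians of a few dozen
  voxels) rather than at the cohort's mL scale, because a 64³ demo phantom
  tract (~5.5 mL) cannot hold 10-mL lesions. Only the log-scale location
  shifts; the SD and prevalence pattern — which drive the regression
  geometry — are preserved, and the location shift is absorbed by the
  intercept of the coupling model. A lesion is grown as one 6-connected blob
  by breadth-first search from a random tract voxel, so the achieved volume
  is within one voxel volume of the target and the recorded truth is the
  achieved, voxel-quantized volume.
* **Rendering**: FLAIR-like WM voxels ~ N(mu, sigma) (default 100, 10) with
  lesion voxels offset by `k_contrast * sigma` (default 6, comfortably above
  the 3-sigma segmentation rule; `k_contrast <= 3` produces designed-to-fail
  fixtures for threshold tests). PET-like region uptake is constant per
  region at the coupling model's linear predictor plus one subject-level
  noise draw, with the cerebellum held at the reference value — so with
  `noise_sd = 0` the measured SUVr equals the linear predictor exactly and
  the generative slope is recoverable to machine precision through the whole
  image pipeline.

The phantom deliberately omits realistic anatomy, bias fields, partial
voluming at mask borders, registration error and scanner effects. Passing
tests therefore demonstrate the correctness of the computation — threshold
rule, mask algebra, normalization, estimator — not robustness to real-world
acquisition artifacts.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `k` (threshold) | 3 | NAWM SDs | the segmentation rule is literally mu + 3·sigma |
| `min_component_size` | 3 | voxels | deterministic stand-in for manual artifact editing; removes isolated noise voxels, which at a 3-sigma threshold occur at ~0.13% of WM voxels but almost never form 26-connected triples |
| `fit_method` | `histogram_ls` | — | least-squares Gaussian on Freedman–Diaconis bins stays on the dominant NAWM mode when a hyperintense lesion tail is present; `moments` is the documented fallback and is biased upward by the tail |
| `prob_threshold` | 0 | probability | any nonzero atlas membership counts; configurable for probabilistic atlases |
| log base | 10 | — | cohort-scale log-WMH magnitudes (~1) are consistent with log10 of mL volumes; natural log available |
| `zero_policy` | exclude | — | subjects with no WMH in a tract cannot be log-transformed and drop out of that tract's model, mirroring per-tract cohort Ns; an epsilon offset mode exists for sensitivity analyses |
| SUVr `floor` | 1.17 | ratio | amyloid-positivity inclusion rule, applied per region (per-region Ns differ in the reference cohort); the boundary value is kept |
| `b0`, `b1` | 1.93, 0.3 | uptake | with the phantom-scale volume locations, `b0 = 1.93` places mean IPL SUVr at the cohort's 1.52 |
| `noise_sd` | 0.33 | uptake | calibrated once so the adjusted five-predictor model at n = 60 explains ≈ 20% of SUVr variance, matching the strongest reported pair |
| `zero_volume_floor` | 1e-3 | mL | value substituted inside the log10 when rendering PET for a zero-lesion subject (≈ one voxel); such subjects never enter the regression under the default exclusion policy, so the floor only affects cosmetic image values. Setting it to `NA` makes a zero-volume subject an explicit error |

## Numerical and design choices

* **Strict inequality at the threshold**: a voxel is WMH iff its intensity
  is strictly greater than mu + k·sigma. The choice is arbitrary but fixed
  and documented; ties have measure zero for continuous intensities.
* **Degenerate inputs**: a constant WM intensity distribution is rejected as
  degenerate (no histogram spread to fit); sampling with `nawm_sigma = 0`
  warns, since the lesion contrast `k·sigma` collapses to zero. Exactness
  tests instead use the renderer's noise-free mode, where each tissue class
  is set to its mean exactly and the threshold comes from a nominal
  `gaussian_fit(mu, sigma)`.
* **Connectivity**: 26-connectivity for component cleanup (any shared face,
  edge or corner), implemented as an offset-matched adjacency graph; the
  test suite checks it against an explicit flood-fill oracle.
* **Standardized beta** is computed as `b1 * sd(x)/sd(y)` over the analyzed
  rows rather than refitting on z-scored data; the two are identical for OLS.
* **Negative adjusted R²** (possible under the null) is reported as-is but
  clamped to 0 inside Cohen's f, keeping the effect size real-valued.
* **ApoE coding**: e4 allele count (0/1/2) as a single numeric covariate,
  matching copy-count cohort reporting; sex is a 0/1 indicator; the volume
  covariate is total intracranial volume.
* **Two-sided p-values** for the slope; 95% CI from the t distribution with
  n − p − 1 df. The association table always reports `ci_low <= ci_high`.
* **Effect-size rounding**: recomputing `f = sqrt(a/(1−a))` from a
  two-decimal adjusted R² reproduces a two-decimal printed f only up to the
  rounding of the adjusted R² itself; the acceptance checks therefore
  propagate the half-ulp interval of the printed adjusted R² rather than
  assuming the printed value is exact.
* **Determinism**: every stochastic operation takes an explicit seed; cohort
  generation derives per-subject child seeds from one master seed, so a
  pipeline rerun with the same configuration is byte-identical. The run
  manifest records the configuration hash and seed.

## Problem sizes used by the test and acceptance suites

The suites are sized for a single CPU: exactness checks run on one 64³
phantom (voxel-exact recovery of a 1000-voxel lesion; 20 noisy phantoms
within 5% of truth); oracle-equivalence checks use ≤ 14³ grids where triple
loops are fast; estimator behaviour is measured on 200 replicate cohorts of
n = 60 for slope recovery and CI coverage and 500 replicates for the type-I
error, generated at the tabular level by `simulate_association_table()` —
which reuses the image renderer's exact covariate sampler, lesion-volume
sampler and region linear predictor, so the replicate study measures the
same generative model the voxel pipeline implements. The end-to-end image
pipeline itself is exercised on 8–40-subject cohorts.

## Known limitations

* The phantom's blocks-and-tubes geometry gives clean mask boundaries;
  partial-volume effects and mask misregistration are out of scope.
* The segmentation model assumes a unimodal NAWM histogram plus a
  well-separated hyperintense tail; pathologies that blur the two modes
  (e.g. diffuse leukoaraiosis) would need a different fit.
* At demo cohort sizes (n ≤ 40) the two cingulum pairs are often not
  estimable at the reference prevalence (25/72) once the 5-predictor model
  requires n > 6 — the family runner reports these pairs as not estimable
  rather than failing the run.
* The amyloid-positivity floor is a selection on the outcome; the replicate
  studies of estimator bias and coverage disable it, and it is tested as a
  filter in its own right.

## A worked example

```{r example, eval = FALSE}
library(tractwmh)
res <- run_pipeline(system.file("extdata", "demo_config.yaml",
                                package = "tractwmh"),
                    out_dir = "demo_out")
res$results
```

The output table has one row per tract-region pair with the standardized
beta, p-value, adjusted R², CI limits, Cohen's f, the number of analyzed
subjects and the Bonferroni significance flag at p < .0125.
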