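# Demo pipeline configuration: 40-subject synthetic phantom cohort on a
# 64x64x64 grid at 1 x 1 x 1.2 mm, segmented at the mean + 3*SD threshold,
# log10 tract volumes, cerebellum-normalized SUVr without the positivity
# floor (the demo cohort is simulated on an arbitrary uptake scale).
cohort:
  "n": 40
  grid_shape: [64, 64, 64]
  voxel_size: [1.0, 1.0, 1.2]
  coupling:
    b0: 1.93
    b1: 0.3
    noise_sd: 0.33
    lesion_contrast_k: 6
segmentation:
  k: 3
  min_component_size: 3
  fit_method: histogram_ls
tracts:
  prob_threshold: 0
  log_base: 10
  zero_policy: exclude
suvr:
  floor: 0
stats:
  alpha: 0.05
  covariates: [age, sex, apoe_e4_count, icv]
seed: 11
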