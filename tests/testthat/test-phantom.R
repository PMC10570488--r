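test_that("phantom space satisfies its geometric invariants and is deterministic", {
  sp1 <- build_phantom_space(seed = 7)
  sp2 <- build_phantom_space(seed = 7)
  expect_identical(sp1, sp2)

  wm <- sp1$wm_mask
  for (tr in names(sp1$tract_masks))
    expect_equal(sum(sp1$tract_masks[[tr]] & !wm), 0)

  excl <- c(list(wm, sp1$cerebellum_mask), sp1$gm_region_masks)
  overlap <- Reduce(`+`, lapply(excl, function(m) m + 0L))
  expect_lte(max(overlap), 1L)

  masks <- c(excl, sp1$tract_masks)
  expect_true(all(vapply(masks, any, logical(1))))

  # each tract touches its paired region one slice above the WM
  pair <- dmn_pairings()
  for (i in seq_len(nrow(pair))) {
    tr <- sp1$tract_masks[[pair$tract[i]]]
    gm <- sp1$gm_region_masks[[pair$region[i]]]
    shifted <- array(FALSE, dim = dim(tr))
    shifted[, , -1] <- tr[, , -dim(tr)[3]]
    expect_true(any(shifted & gm))
  }
})

test_that("a grid too small to hold the masks is a configuration error", {
  expect_error(build_phantom_space(c(8, 8, 8)), "configuration error")
  expect_error(build_phantom_space(c(64, 64, 16)), "configuration error")
})

test_that("covariate sampling reproduces the cohort marginals", {
  cov <- sample_covariates(5000, seed = 1)
  expect_equal(nrow(cov), 5000)
  expect_lt(abs(mean(cov$age) - 74.96), 0.4)
  expect_lt(abs(mean(cov$icv) - 1455.26), 132.46 * 3 / sqrt(5000) + 1e-9)
  expect_lt(abs(mean(cov$sex) - 0.493), 0.03)
  # fraction with at least one e4 allele: .099 + .366
  expect_lt(abs(mean(cov$apoe_e4_count >= 1) - 0.465), 0.02)
  expect_true(all(cov$icv > 0))

  one <- sample_covariates(1, seed = 2)
  expect_equal(nrow(one), 1)
  expect_false(anyNA(one))
  expect_error(sample_covariates(0), "positive")
})

test_that("lesion blobs are voxel-quantized, connected and tract-contained", {
  sp <- build_phantom_space()
  les <- simulate_lesions(sp, c(CING = 0, CING_Hippo = 0, SLF = 1.2, IFOF = 0.3),
                          seed = 7)
  # 1.2 mL at 1.2 mm^3 voxels is exactly 1000 voxels
  expect_length(les$tract_lesion_voxels$SLF, 1000)
  expect_equal(les$achieved_volumes_ml[["SLF"]], 1.2)
  expect_length(les$tract_lesion_voxels$CING, 0)
  expect_equal(les$achieved_volumes_ml[["CING"]], 0)

  # every lesion voxel lies inside its tract (brute-force scan)
  outside <- les$lesion_mask & !(sp$tract_masks$SLF | sp$tract_masks$IFOF)
  expect_equal(loop_mask_count(outside), 0L)

  # one 26-connected component per seeded tract
  comp <- label_components_26(les$lesion_mask)
  expect_equal(comp$n_components, 2L)

  expect_error(
    simulate_lesions(sp, c(CING = 50, CING_Hippo = 0, SLF = 0, IFOF = 0)),
    "placement error")
  expect_error(
    simulate_lesions(sp, c(CING = -1, CING_Hippo = 0, SLF = 0, IFOF = 0)),
    ">= 0")
})

test_that("FLAIR rendering has the requested intensity structure", {
  sp <- build_phantom_space()
  les <- simulate_lesions(sp, c(CING = 0, CING_Hippo = 0, SLF = 1, IFOF = 0),
                          seed = 3)
  fl1 <- render_flair(sp, les, nawm_mu = 100, nawm_sigma = 10, seed = 5)
  fl2 <- render_flair(sp, les, nawm_mu = 100, nawm_sigma = 10, seed = 5)
  expect_identical(fl1$data, fl2$data)

  nawm <- sp$wm_mask & !les$lesion_mask
  expect_gt(sum(nawm), 1e4)
  expect_lt(abs(mean(fl1$data[nawm]) - 100), 0.5)
  lesion_vox <- fl1$data[les$lesion_mask]
  expect_lt(abs(mean(lesion_vox) - 160), 3)

  expect_warning(render_flair(sp, les, nawm_sigma = 0, seed = 1), "degenerate")

  # noise-free rendering puts every class exactly at its mean
  fl0 <- render_flair(sp, les, nawm_mu = 100, nawm_sigma = 10,
                      lesion_contrast_k = 6, noise = FALSE)
  expect_true(all(fl0$data[nawm] == 100))
  expect_true(all(fl0$data[les$lesion_mask] == 160))
})

test_that("PET rendering follows the coupling model", {
  sp <- build_phantom_space()
  cov <- data.frame(subject_id = "S1", age = 75, sex = 1,
                    apoe_e4_count = 1, icv = 1450)
  vols <- c(CING = 0.5, CING_Hippo = 0.5, SLF = 0.5, IFOF = 0.5)

  # b1 = 0, noise_sd = 0: identical uptake whatever the lesion volumes
  cp0 <- coupling_config(b1 = 0, noise_sd = 0)
  p1 <- render_pet(sp, vols, cp0, cov)
  p2 <- render_pet(sp, vols * 4 + 0.1, cp0, cov)
  expect_identical(p1$data, p2$data)

  # b1 > 0, noise_sd = 0: region mean strictly increasing in tract volume
  cp <- coupling_config(b1 = 0.3, noise_sd = 0)
  vgrid <- c(0.05, 0.2, 0.8, 2)
  means <- vapply(vgrid, function(v) {
    img <- render_pet(sp, c(CING = 0.1, CING_Hippo = 0.1, SLF = v, IFOF = 0.1),
                      cp, cov)
    region_mean_uptake(img, sp$gm_region_masks$IPL)
  }, numeric(1))
  expect_true(all(diff(means) > 0))

  # cerebellum uniform at the reference value
  expect_true(all(p1$data[sp$cerebellum_mask] == cp0$reference_value))

  # zero volume without a floor policy is an explicit error
  cpna <- coupling_config(noise_sd = 0, zero_volume_floor = NA)
  expect_error(
    render_pet(sp, c(CING = 0, CING_Hippo = 1, SLF = 1, IFOF = 1), cpna, cov),
    "policy error")
})

test_that("noiseless tabular cohort lets OLS recover the generative slope", {
  cp <- coupling_config(b1 = 0.3, noise_sd = 0)
  tab <- simulate_association_table(80, seed = 9, coupling = cp)
  d <- merge(merge(tab$tracts[tab$tracts$tract_name == "SLF" & tab$tracts$included,
                              c("subject_id", "log_volume")],
                   tab$suvr[tab$suvr$region_name == "IPL",
                            c("subject_id", "suvr")], by = "subject_id"),
             tab$covariates, by = "subject_id")
  # closed-form OLS via the normal equations
  X <- cbind(1, d$log_volume)
  beta <- ols_normal_equations(X, d$suvr)
  expect_equal(beta[2], 0.3, tolerance = 1e-7)
  expect_equal(beta[1], cp$b0, tolerance = 1e-7)

  res <- suppressWarnings(fit_adjusted_model(d, "suvr", "log_volume"))
  expect_equal(res$b1, 0.3, tolerance = 1e-7)
})

test_that("cohort files round-trip bit-exactly and the manifest is complete", {
  sp <- build_phantom_space(c(32, 32, 32), c(1, 1, 1.2))
  cp <- coupling_config(noise_sd = 0)
  lm_small <- lesion_model(log10_mean = c(CING = -1.8, CING_Hippo = -1.8,
                                          SLF = -1.6, IFOF = -1.6))
  co <- simulate_cohort(3, seed = 4, space = sp, coupling = cp,
                        lesions = lm_small)
  dir <- withr::local_tempdir()
  mf <- write_cohort(co, dir)
  expect_equal(length(mf$subjects), 3)
  expect_true(all(file.exists(file.path(dir, vapply(mf$subjects, `[[`,
                                                    character(1), "flair")))))
  expect_true(all(file.exists(file.path(dir, vapply(mf$subjects, `[[`,
                                                    character(1), "pet")))))

  back <- read_volume(file.path(dir, mf$subjects[[1]]$flair))
  expect_identical(back$data, co$subjects[[1]]$flair$data)
  expect_equal(back$voxel_size, c(1, 1, 1.2))

  truth <- read.csv(file.path(dir, "truth.csv"))
  expect_equal(length(unique(truth$subject_id)), 3)
  expect_equal(nrow(truth), 3 * 4)

  rt <- read_cohort(dir)
  expect_identical(rt$space$wm_mask, sp$wm_mask)
  expect_identical(rt$subjects[[2]]$pet$data, co$subjects[[2]]$pet$data)
})
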