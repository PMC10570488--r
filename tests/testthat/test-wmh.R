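make_wm_image <- function(x, d = c(50, 50, 40)) {
  stopifnot(length(x) <= prod(d))
  arr <- array(0, dim = d)
  wm <- array(FALSE, dim = d)
  wm[seq_along(x)] <- TRUE
  arr[seq_along(x)] <- x
  list(flair = vol3d(arr, c(1, 1, 1)), wm = wm)
}

test_that("both fit methods recover a clean Gaussian WM mode", {
  set.seed(11)
  x <- rnorm(1e5, 100, 10)
  im <- make_wm_image(x)
  for (m in c("histogram_ls", "moments")) {
    fit <- fit_wm_gaussian(im$flair, im$wm, method = m)
    expect_lt(abs(fit$mu - 100), 0.2)
    expect_lt(abs(fit$sigma - 10), 0.2)
    expect_equal(fit$n_voxels, 1e5)
  }
})

test_that("histogram fit stays on the main mode under a hyperintense tail", {
  set.seed(12)
  x <- c(rnorm(95000, 100, 10), rnorm(5000, 160, 5))
  im <- make_wm_image(x)
  # trimmed-moment oracle for the main mode: moments of the clean component
  expect_lt(abs(mean(x[1:95000]) - 100), 0.2)
  hist_fit <- fit_wm_gaussian(im$flair, im$wm, method = "histogram_ls")
  mom_fit <- fit_wm_gaussian(im$flair, im$wm, method = "moments")
  expect_lt(abs(hist_fit$mu - 100), 1)
  expect_gt(mom_fit$mu, 101)
})

test_that("degenerate WM intensity distributions are rejected", {
  im <- make_wm_image(rep(100, 5000))
  expect_error(fit_wm_gaussian(im$flair, im$wm), "degenerate-distribution")
  im2 <- make_wm_image(rnorm(50, 100, 10))
  expect_error(fit_wm_gaussian(im2$flair, im2$wm), "mask error")
})

test_that("threshold is mu + k*sigma and strictly monotone in both", {
  expect_equal(wmh_threshold(gaussian_fit(100, 10)), 130)
  expect_equal(wmh_threshold(gaussian_fit(0, 1)), 3)
  expect_equal(wmh_threshold(gaussian_fit(85.2, 7.4)), 107.4)
  expect_equal(wmh_threshold(gaussian_fit(100, 10), k = 6), 160)

  mus <- seq(50, 150, by = 7)
  expect_true(all(diff(vapply(mus, function(m)
    wmh_threshold(gaussian_fit(m, 5)), numeric(1))) > 0))
  sigmas <- seq(0.5, 20, by = 1.3)
  expect_true(all(diff(vapply(sigmas, function(s)
    wmh_threshold(gaussian_fit(100, s)), numeric(1))) > 0))
})

test_that("segmentation is exact on noise-free lesions and respects contrast", {
  sp <- build_phantom_space()
  les <- simulate_lesions(sp, c(CING = 0, CING_Hippo = 0, SLF = 0.24, IFOF = 0),
                          seed = 2)
  expect_length(les$tract_lesion_voxels$SLF, 200)

  fl6 <- render_flair(sp, les, 100, 10, lesion_contrast_k = 6, noise = FALSE)
  w <- segment_wmh(fl6, sp$wm_mask, wmh_threshold(gaussian_fit(100, 10)))
  expect_equal(sum(w$mask), 200)
  expect_identical(which(w$mask), sort(les$tract_lesion_voxels$SLF))

  # lesion contrast below the threshold rule finds nothing
  fl2 <- render_flair(sp, les, 100, 10, lesion_contrast_k = 2, noise = FALSE)
  w2 <- segment_wmh(fl2, sp$wm_mask, wmh_threshold(gaussian_fit(100, 10)))
  expect_equal(sum(w2$mask), 0)
  expect_equal(w2$total_volume_ml, 0)
})

test_that("small components are removed and counted", {
  d <- c(20, 20, 20)
  arr <- array(100, dim = d)
  wm <- array(TRUE, dim = d)
  # one 50-voxel block and one 2-voxel pair, both hyperintense
  arr[2:6, 2:6, 2:3] <- 160            # 50 voxels
  arr[15, 15, 15] <- 160; arr[15, 15, 16] <- 160
  w <- segment_wmh(vol3d(arr, c(1, 1, 1)), wm, 130, min_component_size = 3)
  expect_equal(sum(w$mask), 50)
  expect_equal(w$n_components_removed, 1L)
  # with the filter off both components survive
  w0 <- segment_wmh(vol3d(arr, c(1, 1, 1)), wm, 130, min_component_size = 0)
  expect_equal(sum(w0$mask), 52)
})

test_that("segmentation is idempotent", {
  set.seed(30)
  d <- c(24, 24, 24)
  wm <- array(TRUE, dim = d)
  arr <- array(rnorm(prod(d), 100, 10), dim = d)
  arr[5:10, 5:10, 5:10] <- rnorm(216, 170, 5)
  w1 <- segment_wmh(vol3d(arr, c(1, 1, 1)), wm, 130)
  # re-segment the image restricted to the recovered mask
  arr2 <- array(0, dim = d)
  arr2[w1$mask] <- arr[w1$mask]
  w2 <- segment_wmh(vol3d(arr2, c(1, 1, 1)), w1$mask, 130)
  expect_identical(w2$mask, w1$mask)
})

test_that("segmentation equals the per-voxel loop oracle on small grids", {
  for (seed in c(1, 2)) {
    set.seed(seed)
    d <- c(12, 12, 12)
    wm <- random_mask(d, 0.7, seed + 100)
    arr <- array(rnorm(prod(d), 100, 25), dim = d)
    flair <- vol3d(arr, c(1, 1, 1))
    expected_raw <- loop_threshold_mask(arr, wm, 130)
    w_raw <- segment_wmh(flair, wm, 130, min_component_size = 0)
    expect_identical(w_raw$mask, expected_raw)
    expected_clean <- oracle_clean_mask(expected_raw, 3)
    w_clean <- segment_wmh(flair, wm, 130, min_component_size = 3)
    expect_identical(w_clean$mask, expected_clean)
  }
})

test_that("26-component labelling agrees with the flood-fill oracle", {
  for (seed in c(5, 6)) {
    d <- c(10, 10, 10)
    mask <- random_mask(d, 0.25, seed)
    comp <- label_components_26(mask)
    oracle <- oracle_components_26(mask)
    expect_equal(comp$n_components, max(oracle))
    # same partition: sorted component sizes match and labels are consistent
    expect_equal(sort(tabulate(comp$labels)), sort(tabulate(oracle[oracle > 0])))
    relabel <- oracle[comp$voxels]
    expect_equal(length(unique(paste(comp$labels, relabel))),
                 comp$n_components)
  }
})

test_that("noisy recovery stays within 5% of truth across seeds", {
  sp <- build_phantom_space()
  target <- c(CING = 0, CING_Hippo = 0, SLF = 0.72, IFOF = 0)  # 600 voxels
  errs <- vapply(1:20, function(s) {
    les <- simulate_lesions(sp, target, seed = s)
    fl <- render_flair(sp, les, 100, 10, lesion_contrast_k = 6, seed = 1000 + s)
    fit <- fit_wm_gaussian(fl, sp$wm_mask)
    w <- segment_wmh(fl, sp$wm_mask, wmh_threshold(fit), min_component_size = 3)
    abs(w$total_volume_ml - 0.72) / 0.72
  }, numeric(1))
  expect_lt(max(errs), 0.05)
})

test_that("total volume is count times voxel volume", {
  d <- c(20, 20, 20)
  mask <- array(FALSE, dim = d)
  mask[seq_len(1000)] <- TRUE
  expect_equal(total_wmh_volume(mask, c(1, 1, 1.2)), 1.2)
  expect_equal(total_wmh_volume(array(FALSE, d), c(1, 1, 1.2)), 0)
  rmask <- random_mask(d, 0.3, 77)
  expect_equal(total_wmh_volume(rmask, c(0.9, 1.1, 1.3)),
               loop_mask_count(rmask) * 0.9 * 1.1 * 1.3 / 1000)
})
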