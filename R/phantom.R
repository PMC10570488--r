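#' Build the phantom head space
#'
#' Constructs a deterministic geometric stand-in for a registered brain: a
#' white-matter block, four cortical DMN regions (each split into its
#' parcellation sub-labels), four fiber-tract tubes running through the white
#' matter up to the cortical slab, and a cerebellum reference block, all on a
#' single common voxel grid so that every volume of a subject is co-registered
#' by construction. Regions, tracts and the cerebellum are pairwise disjoint;
#' each tract tube ends face-adjacent to its paired cortical region.
#'
#' @param grid_shape Integer length-3, voxels per axis (each >= 32).
#' @param voxel_size Numeric length-3, voxel edge lengths in mm.
#' @param seed Unused (the geometry is deterministic); accepted so that all
#'   generator entry points share one signature.
#' @return An object of class `phantom_space`: list with `grid_shape`,
#'   `voxel_size`, `wm_mask`, `gm_region_masks` (named list over regions),
#'   `tract_masks` (named list over tracts), `cerebellum_mask`,
#'   `parcellation` (integer label array) and `labels` (name -> integer).
#' @export
build_phantom_space <- function(grid_shape = c(64, 64, 64),
                                voxel_size = c(1, 1, 1.2),
                                seed = NULL) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(is.na(grid_shape)))
    stop("`grid_shape` must be three integers", call. = FALSE)
  if (any(grid_shape < 32L))
    stop("configuration error: grid_shape must be >= 32 on every axis to ",
         "place all masks disjointly", call. = FALSE)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("`voxel_size` must be three positive numbers (mm)", call. = FALSE)

  d <- grid_shape
  rng <- function(lo, hi, n) seq.int(max(1L, round(lo * n)), min(n, round(hi * n)))
  blk <- function(xr, yr, zr) {
    m <- array(FALSE, dim = d)
    m[xr, yr, zr] <- TRUE
    m
  }

  z_cb <- rng(0.04, 0.12, d[3])
  z_wm <- rng(0.22, 0.80, d[3])
  gm_lo <- max(z_wm) + 1L                      # cortex sits directly on the WM
  gm_hi <- min(d[3], gm_lo + max(2L, round(0.09 * d[3])))
  if (gm_hi < gm_lo + 1L)
    stop("configuration error: no room for the cortical slab above the WM block",
         call. = FALSE)
  z_gm <- seq.int(gm_lo, gm_hi)

  xa <- rng(0.1875, 0.375, d[1]);  xb <- rng(0.625, 0.8125, d[1])
  ya <- rng(0.1875, 0.375, d[2]);  yb <- rng(0.625, 0.8125, d[2])
  x_wm <- rng(0.15, 0.85, d[1]);   y_wm <- rng(0.15, 0.85, d[2])
  x_cb <- rng(0.30, 0.70, d[1]);   y_cb <- rng(0.30, 0.70, d[2])

  wm_mask <- blk(x_wm, y_wm, z_wm)
  cerebellum_mask <- blk(x_cb, y_cb, z_cb)

  region_xy <- list(
    MPFC = list(x = xa, y = ya),
    PCC  = list(x = xb, y = ya),
    IPL  = list(x = xa, y = yb),
    MTL  = list(x = xb, y = yb)
  )
  gm_region_masks <- lapply(region_xy, function(q) blk(q$x, q$y, z_gm))

  inset <- function(r) r[-c(1L, length(r))]
  pair <- dmn_pairings()
  tract_masks <- stats::setNames(lapply(seq_len(nrow(pair)), function(i) {
    q <- region_xy[[pair$region[i]]]
    blk(inset(q$x), inset(q$y), z_wm)
  }), pair$tract)

  # integer parcellation: split each region's y-range into its sub-labels
  composition <- dmn_composition()
  parcellation <- array(0L, dim = d)
  labels <- integer(0)
  next_id <- 1L
  for (reg in names(composition)) {
    labs <- composition[[reg]]
    q <- region_xy[[reg]]
    grp <- if (length(labs) == 1L) rep(1L, length(q$y))
           else cut(seq_along(q$y), length(labs), labels = FALSE)
    cuts <- split(q$y, grp)
    for (j in seq_along(labs)) {
      parcellation[q$x, cuts[[j]], z_gm] <- next_id
      labels[labs[j]] <- next_id
      next_id <- next_id + 1L
    }
  }
  parcellation[cerebellum_mask] <- next_id
  labels["cerebellum_cortex"] <- next_id

  space <- structure(list(
    grid_shape = d, voxel_size = voxel_size,
    wm_mask = wm_mask, gm_region_masks = gm_region_masks,
    tract_masks = tract_masks, cerebellum_mask = cerebellum_mask,
    parcellation = parcellation, labels = labels
  ), class = "phantom_space")
  validate_phantom_space(space)
  space
}

validate_phantom_space <- function(space) {
  masks <- c(list(wm = space$wm_mask, cerebellum = space$cerebellum_mask),
             space$gm_region_masks, space$tract_masks)
  if (any(vapply(masks, function(m) sum(m) == 0L, logical(1))))
    stop("configuration error: an empty mask was produced", call. = FALSE)
  for (tr in names(space$tract_masks))
    if (any(space$tract_masks[[tr]] & !space$wm_mask))
      stop(sprintf("configuration error: tract %s leaves the WM mask", tr),
           call. = FALSE)
  excl <- c(list(space$wm_mask, space$cerebellum_mask), space$gm_region_masks)
  tot <- Reduce(`+`, lapply(excl, function(m) m + 0L))
  if (max(tot) > 1L)
    stop("configuration error: WM, cerebellum and cortical regions overlap",
         call. = FALSE)
  pair <- dmn_pairings()
  for (i in seq_len(nrow(pair))) {
    tr <- space$tract_masks[[pair$tract[i]]]
    gm <- space$gm_region_masks[[pair$region[i]]]
    shifted <- array(FALSE, dim = dim(tr))
    shifted[, , -1] <- tr[, , -dim(tr)[3]]       # tract shifted one slice up
    if (!any(shifted & gm))
      stop(sprintf("configuration error: tract %s is not adjacent to region %s",
                   pair$tract[i], pair$region[i]), call. = FALSE)
  }
  invisible(space)
}

#' @export
print.phantom_space <- function(x, ...) {
  cat(sprintf("<phantom_space> %s voxels, %s mm; WM %d vox; tracts: %s\n",
              paste(x$grid_shape, collapse = "x"),
              paste(signif(x$voxel_size, 3), collapse = "x"),
              sum(x$wm_mask),
              paste(sprintf("%s=%d", names(x$tract_masks),
                            vapply(x$tract_masks, sum, numeric(1))),
                    collapse = ", ")))
  invisible(x)
}

#' Cohort covariate marginals
#'
#' Defaults reproduce the reference cohort: age ~ N(74.96, 8.13) years,
#' intracranial volume ~ N(1455.26, 132.46) mL, P(male) = .493, and ApoE e4
#' allele count with P(1 copy) = .099 and P(2 copies) = .366.
#'
#' @param age_mean,age_sd,icv_mean,icv_sd Normal marginals for age (years) and
#'   intracranial volume (mL).
#' @param sex_p_male Probability of the male (1) code.
#' @param apoe_p Length-3 probabilities of 0, 1 and 2 e4 copies (sums to 1).
#' @return Named list of marginal parameters.
#' @export
cohort_marginals <- function(age_mean = 74.96, age_sd = 8.13,
                             icv_mean = 1455.26, icv_sd = 132.46,
                             sex_p_male = 0.493,
                             apoe_p = c(0.535, 0.099, 0.366)) {
  apoe_p <- as.numeric(apoe_p)
  if (length(apoe_p) != 3L || any(apoe_p < 0) || abs(sum(apoe_p) - 1) > 1e-8)
    stop("`apoe_p` must be three non-negative probabilities summing to 1",
         call. = FALSE)
  if (age_sd < 0 || icv_sd < 0 || sex_p_male < 0 || sex_p_male > 1)
    stop("invalid covariate marginals", call. = FALSE)
  list(age_mean = age_mean, age_sd = age_sd, icv_mean = icv_mean,
       icv_sd = icv_sd, sex_p_male = sex_p_male, apoe_p = apoe_p)
}

#' Sample subject covariates
#'
#' @param n Number of subjects (>= 1).
#' @param seed Integer seed; the draw is deterministic given `seed`.
#' @param marginals Output of [cohort_marginals()].
#' @return data.frame with `subject_id`, `age` (years), `sex` (0/1, 1 = male),
#'   `apoe_e4_count` (0/1/2) and `icv` (mL).
#' @export
sample_covariates <- function(n, seed = NULL, marginals = cohort_marginals()) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop("`n` must be a positive integer", call. = FALSE)
  n <- as.integer(n)
  with_local_seed(seed, {
    data.frame(
      subject_id = sprintf("S%04d", seq_len(n)),
      age  = stats::rnorm(n, marginals$age_mean, marginals$age_sd),
      sex  = stats::rbinom(n, 1L, marginals$sex_p_male),
      apoe_e4_count = sample(0:2, n, replace = TRUE, prob = marginals$apoe_p),
      icv  = stats::rnorm(n, marginals$icv_mean, marginals$icv_sd),
      stringsAsFactors = FALSE
    )
  })
}

#' Lesion burden model for the phantom cohort
#'
#' Per tract: the probability that a subject has any WMH in the tract, and the
#' log10 mean/SD (mL) of the lesion volume when present. Presence
#' probabilities and log-scale SDs follow the reference cohort's per-tract
#' counts and spreads; the log10 locations are placed at phantom scale (see
#' the methods vignette) so lesions fit inside the tract tubes. Sampled
#' targets are capped at `cap_fraction` of the tract volume.
#'
#' @param presence Named per-tract probabilities of nonzero WMH.
#' @param log10_mean,log10_sd Named per-tract log10-volume (mL) parameters.
#' @param cap_fraction Cap on a target as a fraction of tract volume.
#' @return Named list of lesion-model parameters.
#' @export
lesion_model <- function(presence = c(CING = 25 / 72, CING_Hippo = 25 / 72,
                                      SLF = 55 / 72, IFOF = 55 / 72),
                         log10_mean = c(CING = -1.58, CING_Hippo = -1.55,
                                        SLF = -1.38, IFOF = -1.36),
                         log10_sd = c(CING = 0.94, CING_Hippo = 0.74,
                                      SLF = 0.66, IFOF = 0.65),
                         cap_fraction = 0.5) {
  for (v in list(presence, log10_mean, log10_sd))
    if (!all(TRACT_NAMES %in% names(v)))
      stop("lesion model parameters must be named for every tract", call. = FALSE)
  if (any(presence < 0 | presence > 1) || any(log10_sd < 0) ||
      cap_fraction <= 0 || cap_fraction > 1)
    stop("invalid lesion model parameters", call. = FALSE)
  list(presence = presence[TRACT_NAMES], log10_mean = log10_mean[TRACT_NAMES],
       log10_sd = log10_sd[TRACT_NAMES], cap_fraction = cap_fraction)
}

#' Sample per-subject, per-tract target lesion volumes
#'
#' @param n Number of subjects.
#' @param seed Integer seed.
#' @param model Output of [lesion_model()].
#' @param tract_capacity_ml Optional named per-tract volumes (mL) used to cap
#'   targets at `cap_fraction` of the tract.
#' @return n x 4 numeric matrix (mL), columns named by tract; 0 = no lesion.
#' @export
sample_lesion_targets <- function(n, seed = NULL, model = lesion_model(),
                                  tract_capacity_ml = NULL) {
  n <- as.integer(n)
  with_local_seed(seed, {
    out <- matrix(0, nrow = n, ncol = length(TRACT_NAMES),
                  dimnames = list(NULL, TRACT_NAMES))
    for (tr in TRACT_NAMES) {
      present <- stats::rbinom(n, 1L, model$presence[[tr]]) == 1L
      vols <- 10^stats::rnorm(n, model$log10_mean[[tr]], model$log10_sd[[tr]])
      if (!is.null(tract_capacity_ml))
        vols <- pmin(vols, model$cap_fraction * tract_capacity_ml[[tr]])
      out[, tr] <- ifelse(present, vols, 0)
    }
    out
  })
}

#' Place lesion blobs inside the fiber tracts
#'
#' For each tract with a positive target volume, grows one 6-connected blob
#' from a random tract voxel (breadth-first) until the blob's voxel count
#' times the voxel volume is within one voxel volume of the target. The
#' recorded true volume is the achieved, voxel-quantized volume.
#'
#' @param space A [build_phantom_space()] result.
#' @param target_volumes_ml Named numeric, target lesion volume per tract (mL,
#'   >= 0, each at most half the tract volume).
#' @param seed Integer seed for the blob placement.
#' @return List with `lesion_mask` (logical array, union over tracts),
#'   `tract_lesion_voxels` (named list of linear voxel indices) and
#'   `achieved_volumes_ml` (named numeric, mL).
#' @export
simulate_lesions <- function(space, target_volumes_ml, seed = NULL) {
  stopifnot(inherits(space, "phantom_space"))
  tv <- target_volumes_ml[TRACT_NAMES]
  if (any(is.na(tv)))
    stop("`target_volumes_ml` must be named for every tract", call. = FALSE)
  if (any(tv < 0)) stop("target volumes must be >= 0", call. = FALSE)
  vox_ml <- voxel_volume_ml(space$voxel_size)
  d <- space$grid_shape

  lesion_mask <- array(FALSE, dim = d)
  voxels <- list()
  achieved <- stats::setNames(numeric(length(TRACT_NAMES)), TRACT_NAMES)
  with_local_seed(seed, {
    for (tr in TRACT_NAMES) {
      tract <- space$tract_masks[[tr]]
      cap <- sum(tract) * vox_ml
      if (tv[[tr]] > 0.5 * cap + 1e-12)
        stop(sprintf(
          "placement error: target %.3g mL exceeds half the %s tract capacity (%.3g mL)",
          tv[[tr]], tr, cap), call. = FALSE)
      n_vox <- round(tv[[tr]] / vox_ml)
      if (n_vox == 0L) {
        voxels[[tr]] <- integer(0)
        next
      }
      start <- sample(which(tract), 1L)
      blob <- grow_blob(tract, start, n_vox, d)
      lesion_mask[blob] <- TRUE
      voxels[[tr]] <- blob
      achieved[[tr]] <- length(blob) * vox_ml
    }
  })
  list(lesion_mask = lesion_mask, tract_lesion_voxels = voxels,
       achieved_volumes_ml = achieved)
}

# breadth-first growth of a 6-connected blob of n voxels inside `inside`
grow_blob <- function(inside, start, n, d) {
  visited <- array(FALSE, dim = d)
  visited[start] <- TRUE
  queue <- integer(n)
  queue[1L] <- start
  head <- 1L; tail <- 1L
  nxy <- d[1] * d[2]
  while (head <= tail && tail < n) {
    v <- queue[head]; head <- head + 1L
    v0 <- v - 1L
    i <- v0 %% d[1]; j <- (v0 %/% d[1]) %% d[2]; k <- v0 %/% nxy
    nb <- c(if (i > 0L) v - 1L, if (i < d[1] - 1L) v + 1L,
            if (j > 0L) v - d[1], if (j < d[2] - 1L) v + d[1],
            if (k > 0L) v - nxy, if (k < d[3] - 1L) v + nxy)
    for (u in nb) {
      if (tail >= n) break
      if (inside[u] && !visited[u]) {
        visited[u] <- TRUE
        tail <- tail + 1L
        queue[tail] <- u
      }
    }
  }
  queue[seq_len(tail)]
}

#' Render a FLAIR-like intensity volume
#'
#' Normal-appearing white matter voxels are drawn from
#' `Normal(nawm_mu, nawm_sigma)`; lesion voxels from
#' `Normal(nawm_mu + lesion_contrast_k * nawm_sigma, nawm_sigma * lesion_sd_frac)`.
#' Non-WM classes get distinct constant-mean values (cosmetic: downstream
#' stages only read voxels inside the WM mask). With `noise = FALSE`, every
#' voxel is set to its class mean exactly — `nawm_sigma` then only sets the
#' lesion contrast scale — which is the configuration used by the exact
#' volume-recovery checks.
#'
#' @param space A `phantom_space`.
#' @param lesions A [simulate_lesions()] result (or NULL for no lesions).
#' @param nawm_mu,nawm_sigma NAWM intensity mean and SD (>= 0).
#' @param lesion_contrast_k Lesion mean offset in NAWM-sigma units.
#' @param lesion_sd_frac Lesion SD as a fraction of `nawm_sigma`.
#' @param noise If FALSE, render class means without sampling noise.
#' @param seed Integer seed.
#' @return A [vol3d].
#' @export
render_flair <- function(space, lesions = NULL, nawm_mu = 100, nawm_sigma = 10,
                         lesion_contrast_k = 6, lesion_sd_frac = 0.5,
                         noise = TRUE, seed = NULL) {
  stopifnot(inherits(space, "phantom_space"))
  if (nawm_sigma < 0) stop("`nawm_sigma` must be >= 0", call. = FALSE)
  if (noise && nawm_sigma == 0)
    warning("degenerate nawm_sigma = 0: the WM histogram has no spread and the ",
            "lesion contrast offset k*sigma is 0", call. = FALSE)
  d <- space$grid_shape
  gm_all <- Reduce(`|`, space$gm_region_masks)
  lesion_idx <- if (is.null(lesions)) integer(0) else which(lesions$lesion_mask)
  with_local_seed(seed, {
    img <- array(0.3 * nawm_mu, dim = d)            # CSF/background
    soft <- gm_all | space$cerebellum_mask
    img[soft] <- 0.7 * nawm_mu                       # GM-like classes
    wm_idx <- which(space$wm_mask)
    if (noise) {
      img[wm_idx] <- stats::rnorm(length(wm_idx), nawm_mu, nawm_sigma)
      if (length(lesion_idx))
        img[lesion_idx] <- stats::rnorm(length(lesion_idx),
                                        nawm_mu + lesion_contrast_k * nawm_sigma,
                                        nawm_sigma * lesion_sd_frac)
    } else {
      img[wm_idx] <- nawm_mu
      if (length(lesion_idx))
        img[lesion_idx] <- nawm_mu + lesion_contrast_k * nawm_sigma
    }
    vol3d(img, space$voxel_size)
  })
}

#' Coupling between tract lesion burden and regional PET uptake
#'
#' Defines the generative linear model tying each DMN region's uptake to the
#' log10 lesion volume of its paired tract:
#' `uptake = b0 + b1 * log10(max(V, zero_volume_floor)) + bX . covariates + e`,
#' `e ~ Normal(0, noise_sd)`, with the cerebellum held at `reference_value` so
#' that SUVr equals uptake divided by `reference_value`.
#'
#' @param b0 Baseline regional uptake.
#' @param b1 Slope per unit log10-volume; scalar or named per-region vector.
#' @param covariate_effects Named effects for age, sex, apoe_e4_count, icv.
#' @param noise_sd Subject-level uptake noise SD (>= 0).
#' @param lesion_contrast_k FLAIR lesion contrast passed to the renderer
#'   (> 3 keeps lesions above the segmentation threshold).
#' @param reference_value Constant cerebellum uptake (> 0).
#' @param zero_volume_floor Volume floor (mL) substituted inside the log for
#'   zero-lesion subjects; set to `NA` to make a zero-volume subject an error.
#' @param seed Optional default seed carried with the config.
#' @return Named list of class `coupling_config`.
#' @export
coupling_config <- function(b0 = 1.93, b1 = 0.3,
                            covariate_effects = c(age = 0, sex = 0,
                                                  apoe_e4_count = 0, icv = 0),
                            noise_sd = 0.33, lesion_contrast_k = 6,
                            reference_value = 1, zero_volume_floor = 1e-3,
                            seed = NULL) {
  b1 <- unlist(b1)
  covariate_effects <- unlist(covariate_effects)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (reference_value <= 0) stop("`reference_value` must be > 0", call. = FALSE)
  if (length(b1) == 1L && is.null(names(b1)))
    b1 <- stats::setNames(rep(as.numeric(b1), length(REGION_NAMES)), REGION_NAMES)
  if (!all(REGION_NAMES %in% names(b1)))
    stop("`b1` must be a scalar or named for every DMN region", call. = FALSE)
  cov_names <- c("age", "sex", "apoe_e4_count", "icv")
  if (!all(cov_names %in% names(covariate_effects)))
    stop("`covariate_effects` must name age, sex, apoe_e4_count and icv",
         call. = FALSE)
  structure(list(b0 = b0, b1 = b1[REGION_NAMES],
                 covariate_effects = covariate_effects[cov_names],
                 noise_sd = noise_sd, lesion_contrast_k = lesion_contrast_k,
                 reference_value = reference_value,
                 zero_volume_floor = zero_volume_floor, seed = seed),
            class = "coupling_config")
}

# noiseless linear predictor of one region's uptake for one subject
region_linear_predictor <- function(coupling, region, volume_ml, covariates) {
  if (volume_ml <= 0) {
    if (is.na(coupling$zero_volume_floor))
      stop("policy error: zero lesion volume with no zero_volume_floor set",
           call. = FALSE)
    volume_ml <- coupling$zero_volume_floor
  }
  bx <- coupling$covariate_effects
  coupling$b0 + coupling$b1[[region]] * log10(volume_ml) +
    bx[["age"]] * covariates$age + bx[["sex"]] * covariates$sex +
    bx[["apoe_e4_count"]] * covariates$apoe_e4_count +
    bx[["icv"]] * covariates$icv
}

#' Render a PET-like uptake volume for one subject
#'
#' Each DMN region is filled with a constant uptake value drawn from the
#' coupling model (linear predictor plus one subject-level noise draw per
#' region), so with `noise_sd = 0` the region mean equals the linear predictor
#' exactly. The cerebellum is held uniform at the reference value.
#'
#' @param space A `phantom_space`.
#' @param truth Named numeric, true (achieved) lesion volume in mL per tract.
#' @param coupling A [coupling_config()].
#' @param covariates One-row data.frame with age, sex, apoe_e4_count, icv.
#' @param seed Integer seed for the per-region noise draws.
#' @return A [vol3d].
#' @export
render_pet <- function(space, truth, coupling, covariates, seed = NULL) {
  stopifnot(inherits(space, "phantom_space"), inherits(coupling, "coupling_config"))
  pair <- dmn_pairings()
  with_local_seed(seed, {
    img <- array(0.05 * coupling$reference_value, dim = space$grid_shape)
    img[space$wm_mask] <- 0.25 * coupling$reference_value
    img[space$cerebellum_mask] <- coupling$reference_value
    for (i in seq_len(nrow(pair))) {
      mu <- region_linear_predictor(coupling, pair$region[i],
                                    truth[[pair$tract[i]]], covariates)
      val <- mu + stats::rnorm(1L, 0, coupling$noise_sd)
      img[space$gm_region_masks[[pair$region[i]]]] <- val
    }
    vol3d(img, space$voxel_size)
  })
}

#' Simulate a full phantom cohort
#'
#' Samples covariates and per-tract lesion targets, places lesions, and
#' renders one FLAIR-like and one PET-like volume per subject, all on the
#' shared phantom grid. Deterministic given `seed`.
#'
#' @param n Number of subjects.
#' @param seed Integer master seed.
#' @param space A `phantom_space` (built with defaults if omitted).
#' @param coupling A [coupling_config()].
#' @param marginals A [cohort_marginals()].
#' @param lesions A [lesion_model()].
#' @param flair Named list of renderer settings: `nawm_mu`, `nawm_sigma`,
#'   `lesion_sd_frac`, `noise`.
#' @return List of class `phantom_cohort`: `space`, `covariates` (data.frame),
#'   `truth` (data.frame subject_id, tract, true_volume_ml), `subjects`
#'   (per-subject list with `flair`, `pet`, `lesions`).
#' @export
simulate_cohort <- function(n, seed = 1L, space = NULL,
                            coupling = coupling_config(),
                            marginals = cohort_marginals(),
                            lesions = lesion_model(),
                            flair = list(nawm_mu = 100, nawm_sigma = 10,
                                         lesion_sd_frac = 0.5, noise = TRUE)) {
  if (is.null(space)) space <- build_phantom_space()
  vox_ml <- voxel_volume_ml(space$voxel_size)
  capacity <- vapply(space$tract_masks, function(m) sum(m) * vox_ml, numeric(1))
  seeds <- derive_seeds(seed, 2L + 3L * n)
  covariates <- sample_covariates(n, seed = seeds[1L], marginals = marginals)
  targets <- sample_lesion_targets(n, seed = seeds[2L], model = lesions,
                                   tract_capacity_ml = capacity)
  subjects <- vector("list", n)
  truth_rows <- vector("list", n)
  for (i in seq_len(n)) {
    les <- simulate_lesions(space, targets[i, ], seed = seeds[2L + 3L * i - 2L])
    fl <- render_flair(space, les, nawm_mu = flair$nawm_mu,
                       nawm_sigma = flair$nawm_sigma,
                       lesion_contrast_k = coupling$lesion_contrast_k,
                       lesion_sd_frac = flair$lesion_sd_frac,
                       noise = isTRUE(flair$noise),
                       seed = seeds[2L + 3L * i - 1L])
    pet <- render_pet(space, les$achieved_volumes_ml, coupling,
                      covariates[i, ], seed = seeds[2L + 3L * i])
    subjects[[i]] <- list(flair = fl, pet = pet, lesions = les)
    truth_rows[[i]] <- data.frame(
      subject_id = covariates$subject_id[i],
      tract = TRACT_NAMES,
      true_volume_ml = as.numeric(les$achieved_volumes_ml[TRACT_NAMES]),
      stringsAsFactors = FALSE)
  }
  structure(list(space = space, covariates = covariates,
                 truth = do.call(rbind, truth_rows),
                 subjects = stats::setNames(subjects, covariates$subject_id),
                 coupling = coupling),
            class = "phantom_cohort")
}

#' Simulate the cohort at the tabular level
#'
#' Draws covariates, per-tract lesion volumes and region SUVr directly from
#' the same generative model used by the image renderer (identical covariate
#' sampler, lesion-volume sampler and region linear predictor), skipping voxel
#' rendering. This is the generator used by replicate-heavy statistical
#' studies of the estimators; the image route is exercised by the voxel-level
#' exactness checks and the end-to-end pipeline.
#'
#' @param n Number of subjects.
#' @param seed Integer seed.
#' @param coupling A [coupling_config()].
#' @param marginals A [cohort_marginals()].
#' @param lesions A [lesion_model()].
#' @param log_base Base of the log transform applied to volumes.
#' @return List with `suvr` (subject_id, region_name, suvr, included),
#'   `tracts` (subject_id, tract_name, wmh_volume_ml, log_volume, included)
#'   and `covariates` data.frames.
#' @export
simulate_association_table <- function(n, seed = 1L,
                                       coupling = coupling_config(),
                                       marginals = cohort_marginals(),
                                       lesions = lesion_model(),
                                       log_base = 10) {
  seeds <- derive_seeds(seed, 3L)
  covariates <- sample_covariates(n, seed = seeds[1L], marginals = marginals)
  vols <- sample_lesion_targets(n, seed = seeds[2L], model = lesions)
  pair <- dmn_pairings()
  suvr_rows <- with_local_seed(seeds[3L], {
    do.call(rbind, lapply(seq_len(nrow(pair)), function(i) {
      mu <- vapply(seq_len(n), function(s)
        region_linear_predictor(coupling, pair$region[i],
                                vols[s, pair$tract[i]], covariates[s, ]),
        numeric(1))
      uptake <- mu + stats::rnorm(n, 0, coupling$noise_sd)
      data.frame(subject_id = covariates$subject_id,
                 region_name = pair$region[i],
                 suvr = uptake / coupling$reference_value,
                 n_roi_voxels = NA_integer_, included = TRUE,
                 stringsAsFactors = FALSE)
    }))
  })
  tract_rows <- do.call(rbind, lapply(TRACT_NAMES, function(tr)
    data.frame(subject_id = covariates$subject_id, tract_name = tr,
               wmh_volume_ml = vols[, tr], stringsAsFactors = FALSE)))
  tract_rows <- log_transform_volumes(tract_rows, base = log_base)
  list(suvr = suvr_rows, tracts = tract_rows, covariates = covariates)
}

#' Write a phantom cohort to disk
#'
#' Writes per-subject FLAIR and PET NIfTI volumes, the shared masks and
#' parcellation, the ground-truth and covariate CSV tables, and a JSON
#' manifest. A write/read round trip reproduces every array bit-exactly.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param out_dir Output directory (created if missing).
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop(sprintf("cannot create output directory: %s", out_dir), call. = FALSE)
  space <- cohort$space
  vs <- space$voxel_size
  wv <- function(arr, name) {
    write_volume(vol3d(arr + 0, vs), file.path(out_dir, name))
    name
  }
  masks <- c(
    wv(space$wm_mask, "wm_mask.nii.gz"),
    wv(space$cerebellum_mask, "cerebellum_mask.nii.gz"),
    wv(space$parcellation, "parcellation.nii.gz"),
    vapply(names(space$tract_masks), function(tr)
      wv(space$tract_masks[[tr]], sprintf("tract_%s.nii.gz", tr)), character(1))
  )
  jsonlite::write_json(as.list(space$labels), file.path(out_dir, "labels.json"),
                       auto_unbox = TRUE)
  subj_files <- lapply(names(cohort$subjects), function(id) {
    fl <- sprintf("flair_%s.nii.gz", id)
    pt <- sprintf("pet_%s.nii.gz", id)
    write_volume(cohort$subjects[[id]]$flair, file.path(out_dir, fl))
    write_volume(cohort$subjects[[id]]$pet, file.path(out_dir, pt))
    list(subject_id = id, flair = fl, pet = pt)
  })
  utils::write.csv(cohort$truth, file.path(out_dir, "truth.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$covariates, file.path(out_dir, "covariates.csv"),
                   row.names = FALSE)
  manifest <- list(
    n_subjects = length(cohort$subjects),
    grid_shape = space$grid_shape, voxel_size = vs,
    masks = as.list(masks), subjects = subj_files,
    truth = "truth.csv", covariates = "covariates.csv",
    labels = "labels.json")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
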