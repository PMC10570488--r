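#' Binarize a probabilistic tract map
#'
#' @param prob_map 3D array (or [vol3d]) of tract membership probabilities in
#'   \[0, 1\].
#' @param prob_threshold Voxels with probability strictly greater than this
#'   are kept. The default 0 keeps any nonzero membership.
#' @return Logical array.
#' @export
binarize_tract <- function(prob_map, prob_threshold = 0) {
  p <- if (inherits(prob_map, "vol3d")) prob_map$data else prob_map
  if (!is.numeric(p) && !is.logical(p))
    stop("`prob_map` must be numeric", call. = FALSE)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("input error: probabilities must lie in [0, 1]", call. = FALSE)
  p > prob_threshold
}

#' WMH volume inside one tract
#'
#' Voxelwise intersection (logical AND) of the WMH mask with the tract mask,
#' scaled by the voxel volume.
#'
#' @param wmh_mask Logical/numeric array, `vol3d`, or a `wmh_mask` object.
#' @param tract_mask Logical/numeric array or `vol3d`.
#' @param voxel_size Voxel edge lengths in mm.
#' @return Intersection volume in mL.
#' @export
tract_wmh_volume <- function(wmh_mask, tract_mask, voxel_size) {
  if (inherits(wmh_mask, "wmh_mask")) wmh_mask <- wmh_mask$mask
  a <- as_mask_array(wmh_mask)
  b <- as_mask_array(tract_mask)
  assert_same_grid(a, b, "wmh_mask and tract_mask")
  sum(a & b) * voxel_volume_ml(voxel_size)
}

#' Log-transform per-tract WMH volumes
#'
#' Adds `log_volume` and `included` columns to a tract-burden table. Tract
#' WMH volumes are strongly right-skewed, so the regression predictor is the
#' log volume. Zero-volume records cannot be log-transformed; under the
#' default `"exclude"` policy they are flagged `included = FALSE` (mirroring a
#' cohort in which only subjects with lesions in a tract enter that tract's
#' model), while the `"epsilon"` policy adds a small offset before the log for
#' sensitivity analyses.
#'
#' @param records data.frame with columns `subject_id`, `tract_name`,
#'   `wmh_volume_ml`.
#' @param base Log base (default 10).
#' @param zero_policy `"exclude"` or `"epsilon"`.
#' @param epsilon Offset (mL) added under the `"epsilon"` policy.
#' @return The table with `log_volume` and `included` columns.
#' @export
log_transform_volumes <- function(records, base = 10,
                                  zero_policy = c("exclude", "epsilon"),
                                  epsilon = 1e-3) {
  zero_policy <- match.arg(zero_policy)
  need <- c("subject_id", "tract_name", "wmh_volume_ml")
  if (!all(need %in% names(records)))
    stop("`records` must have columns subject_id, tract_name, wmh_volume_ml",
         call. = FALSE)
  v <- records$wmh_volume_ml
  if (any(v < 0, na.rm = TRUE))
    stop("input error: negative WMH volume", call. = FALSE)
  if (zero_policy == "epsilon") {
    records$log_volume <- log(v + epsilon, base = base)
    records$included <- !is.na(v)
  } else {
    records$log_volume <- ifelse(v > 0, log(v, base = base), NA_real_)
    records$included <- !is.na(v) & v > 0
  }
  records
}
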