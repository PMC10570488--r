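#' Build composite DMN region masks from a parcellation
#'
#' Each region mask is the union of the voxels of its parcellation labels.
#'
#' @param parcellation Integer-label 3D array (or [vol3d]).
#' @param labels Named integer vector (or list) mapping label names to the
#'   integer codes used in `parcellation`.
#' @param composition Named list region -> character vector of label names
#'   (default [dmn_composition()]).
#' @return Named list of logical region masks.
#' @export
composite_dmn_rois <- function(parcellation, labels,
                               composition = dmn_composition()) {
  parc <- if (inherits(parcellation, "vol3d")) parcellation$data else parcellation
  labels <- unlist(labels)
  if (is.null(names(labels)))
    stop("`labels` must be a named label -> integer dictionary", call. = FALSE)
  lapply(composition, function(labs) {
    if (!length(labs)) stop("mapping error: empty label list", call. = FALSE)
    miss <- setdiff(labs, names(labels))
    if (length(miss))
      stop(sprintf("mapping error: label(s) not in parcellation dictionary: %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    array(parc %in% labels[labs], dim = dim(parc))
  })
}

#' Mean uptake inside a region of interest
#'
#' @param pet A [vol3d] uptake image.
#' @param roi_mask Logical/numeric array or `vol3d`.
#' @return Arithmetic mean of the uptake over ROI voxels.
#' @export
region_mean_uptake <- function(pet, roi_mask) {
  stopifnot(inherits(pet, "vol3d"))
  roi <- as_mask_array(roi_mask)
  assert_same_grid(pet, roi, "pet and roi_mask")
  if (!any(roi)) stop("mask error: empty ROI", call. = FALSE)
  mean(pet$data[roi])
}

#' Regional SUVr against a reference region
#'
#' Standardized uptake value ratio: mean uptake in the target ROI divided by
#' mean uptake in the reference region (here the whole cerebellum).
#'
#' @param pet A [vol3d] uptake image.
#' @param roi_mask Target ROI mask.
#' @param reference_mask Reference region mask.
#' @return List with `suvr`, `roi_mean`, `reference_mean`, `n_roi_voxels`.
#' @export
compute_suvr <- function(pet, roi_mask, reference_mask) {
  roi_mean <- region_mean_uptake(pet, roi_mask)
  ref <- as_mask_array(reference_mask)
  if (!any(ref)) stop("mask error: empty reference region", call. = FALSE)
  ref_mean <- region_mean_uptake(pet, ref)
  if (ref_mean <= 0)
    stop("reference error: non-positive reference mean uptake", call. = FALSE)
  list(suvr = roi_mean / ref_mean, roi_mean = roi_mean,
       reference_mean = ref_mean, n_roi_voxels = sum(as_mask_array(roi_mask)))
}

#' Apply the amyloid-positivity SUVr floor
#'
#' Records with SUVr strictly below the floor are flagged excluded for that
#' region's analysis; a record exactly at the floor is kept. The default floor
#' of 1.17 reflects the amyloid-positivity inclusion rule applied per region.
#'
#' @param records data.frame with columns `subject_id`, `region_name`, `suvr`.
#' @param floor SUVr floor (>= 0); 0 keeps every record.
#' @return The table with an updated logical `included` column.
#' @export
apply_suvr_floor <- function(records, floor = 1.17) {
  if (floor < 0) stop("`floor` must be >= 0", call. = FALSE)
  need <- c("subject_id", "region_name", "suvr")
  if (!all(need %in% names(records)))
    stop("`records` must have columns subject_id, region_name, suvr",
         call. = FALSE)
  keep <- !is.na(records$suvr) & records$suvr >= floor
  records$included <- if ("included" %in% names(records))
    records$included & keep else keep
  records
}

#' Per-subject regional SUVr table
#'
#' Convenience wrapper: builds the composite DMN ROIs and computes one SUVr
#' record per region for one subject's PET image.
#'
#' @param pet A [vol3d].
#' @param parcellation Integer-label array (or `vol3d`).
#' @param labels Named label dictionary.
#' @param reference_mask Reference (cerebellum) mask.
#' @param subject_id Subject identifier for the output rows.
#' @param composition Region composition (default [dmn_composition()]).
#' @return data.frame with `subject_id`, `region_name`, `suvr`,
#'   `n_roi_voxels`, `included` (TRUE; apply [apply_suvr_floor()] downstream).
#' @export
subject_suvr_table <- function(pet, parcellation, labels, reference_mask,
                               subject_id, composition = dmn_composition()) {
  rois <- composite_dmn_rois(parcellation, labels, composition)
  rows <- lapply(names(rois), function(reg) {
    s <- compute_suvr(pet, rois[[reg]], reference_mask)
    data.frame(subject_id = subject_id, region_name = reg, suvr = s$suvr,
               n_roi_voxels = s$n_roi_voxels, included = TRUE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
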