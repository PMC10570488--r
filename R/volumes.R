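#' Construct a volumetric image
#'
#' A `vol3d` is the package's in-memory representation of one co-registered
#' 3D scalar volume: a numeric array plus physical voxel dimensions in mm.
#' All volumes belonging to one subject share the same grid, so voxelwise
#' operations (masking, intersection) need no resampling.
#'
#' @param data 3D numeric array.
#' @param voxel_size Numeric length-3, voxel edge lengths in mm (all > 0).
#' @return An object of class `vol3d`.
#' @export
vol3d <- function(data, voxel_size = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("`voxel_size` must be three positive numbers (mm)", call. = FALSE)
  structure(list(data = data, voxel_size = voxel_size), class = "vol3d")
}

#' @export
print.vol3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<vol3d> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' @export
dim.vol3d <- function(x) dim(x$data)

#' Volume of one voxel in millilitres
#'
#' @param voxel_size Numeric length-3 voxel edge lengths in mm, or a `vol3d`.
#' @return Voxel volume in mL (1 mL = 1000 mm^3).
#' @export
voxel_volume_ml <- function(voxel_size) {
  if (inherits(voxel_size, "vol3d")) voxel_size <- voxel_size$voxel_size
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("`voxel_size` must be three positive numbers (mm)", call. = FALSE)
  prod(voxel_size) / 1000
}

#' Read a NIfTI-1 volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [vol3d] with the array data and voxel dimensions from the header.
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop(sprintf("volume file not found: %s", path), call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop(sprintf("not a readable NIfTI file: %s (%s)",
                                 path, conditionMessage(e)), call. = FALSE))
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop(sprintf("expected a 3D volume, got %d dims: %s",
                 length(dim(arr)), path), call. = FALSE)
  arr <- array(as.numeric(arr), dim = dim(arr))   # drop header attributes
  # pixdim is float32 in the header; recover the intended decimal value
  vol3d(arr, signif(RNifti::pixdim(img)[1:3], 6))
}

#' Write a volume as NIfTI-1
#'
#' Data are stored as float64 so a write/read round trip reproduces the array
#' bit-exactly.
#'
#' @param vol A [vol3d].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "vol3d"))
  img <- RNifti::asNifti(vol$data + 0,  # force numeric storage
                         reference = list(pixdim = c(-1, vol$voxel_size, 1, 1, 1, 1)))
  ok <- tryCatch({ RNifti::writeNifti(img, path, datatype = "double"); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok))
    stop(sprintf("failed to write volume to %s: %s", path,
                 conditionMessage(ok)), call. = FALSE)
  invisible(path)
}

# shared internal checks ----------------------------------------------------

assert_same_grid <- function(a, b, what = "masks") {
  da <- if (inherits(a, "vol3d")) dim(a$data) else dim(a)
  db <- if (inherits(b, "vol3d")) dim(b$data) else dim(b)
  if (!identical(da, db))
    stop(sprintf("%s are on different grids: %s vs %s", what,
                 paste(da, collapse = "x"), paste(db, collapse = "x")),
         call. = FALSE)
  invisible(TRUE)
}

as_mask_array <- function(mask) {
  if (inherits(mask, "vol3d")) mask <- mask$data
  if (is.logical(mask)) return(mask)
  if (is.numeric(mask)) return(mask != 0)
  stop("mask must be a logical or numeric array", call. = FALSE)
}
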