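#' Construct a Gaussian fit of the normal-appearing-WM intensity mode
#'
#' @param mu,sigma Mean and SD of the NAWM intensity mode (sigma >= 0).
#' @param n_voxels Number of WM voxels the fit is based on.
#' @param fit_method `"histogram_ls"` or `"moments"` (or `"nominal"` for a fit
#'   supplied directly rather than estimated).
#' @return Object of class `gaussian_fit`.
#' @export
gaussian_fit <- function(mu, sigma, n_voxels = NA_integer_,
                         fit_method = "nominal") {
  if (!is.finite(mu) || !is.finite(sigma) || sigma < 0)
    stop("`mu` must be finite and `sigma` finite and >= 0", call. = FALSE)
  structure(list(mu = mu, sigma = sigma, n_voxels = n_voxels,
                 fit_method = fit_method),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("<gaussian_fit> mu = %.4g, sigma = %.4g (%s, n = %s)\n",
              x$mu, x$sigma, x$fit_method,
              ifelse(is.na(x$n_voxels), "?", x$n_voxels)))
  invisible(x)
}

#' Fit a Gaussian to the WM intensity histogram
#'
#' Estimates the normal-appearing-WM intensity mode from the FLAIR intensities
#' inside the WM mask. The default `histogram_ls` method bins the intensities
#' with Freedman-Diaconis binning and least-squares fits a Gaussian density
#' (free amplitude) to the normalized histogram, which keeps the location and
#' scale of the dominant mode robust to the hyperintense lesion tail. The
#' `moments` method uses the sample mean and SD of all WM voxels.
#'
#' @param flair A [vol3d] FLAIR-like image.
#' @param wm_mask Logical/numeric array (or `vol3d`), the WM mask.
#' @param method `"histogram_ls"` (default) or `"moments"`.
#' @param min_voxels Minimum WM voxel count required for a fit.
#' @return A [gaussian_fit()].
#' @export
fit_wm_gaussian <- function(flair, wm_mask, method = c("histogram_ls", "moments"),
                            min_voxels = 100L) {
  method <- match.arg(method)
  stopifnot(inherits(flair, "vol3d"))
  wm <- as_mask_array(wm_mask)
  assert_same_grid(flair, wm, "flair and wm_mask")
  x <- flair$data[wm]
  if (length(x) < min_voxels)
    stop(sprintf("mask error: WM mask has %d voxels, need >= %d",
                 length(x), min_voxels), call. = FALSE)
  if (any(!is.finite(x)))
    stop("flair intensities inside the WM mask must be finite", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0)
    stop("degenerate-distribution error: WM intensities have zero variance",
         call. = FALSE)
  if (method == "moments")
    return(gaussian_fit(mean(x), s, length(x), "moments"))

  h <- graphics::hist(x, breaks = "FD", plot = FALSE)
  mids <- h$mids
  dens <- h$density
  mu0 <- mids[which.max(dens)]
  a0 <- max(dens)
  s0 <- min(s, stats::mad(x))
  if (s0 <= 0) s0 <- s
  fit <- tryCatch(
    minpack.lm::nlsLM(
      dens ~ a * exp(-(mids - mu)^2 / (2 * sg^2)),
      start = list(a = a0, mu = mu0, sg = s0),
      lower = c(a = 0, mu = min(mids), sg = diff(range(mids)) * 1e-6),
      upper = c(a = Inf, mu = max(mids), sg = diff(range(mids))),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("histogram least-squares fit failed to converge; ",
            "falling back to sample moments", call. = FALSE)
    return(gaussian_fit(mean(x), s, length(x), "moments"))
  }
  cf <- stats::coef(fit)
  gaussian_fit(unname(cf["mu"]), unname(cf["sg"]), length(x), "histogram_ls")
}

#' WMH intensity threshold from a Gaussian fit
#'
#' The lesion threshold is the NAWM mean plus `k` standard deviations
#' (default k = 3).
#'
#' @param fit A [gaussian_fit()].
#' @param k Multiplier on sigma.
#' @return Intensity threshold `mu + k * sigma`.
#' @export
wmh_threshold <- function(fit, k = 3) {
  stopifnot(inherits(fit, "gaussian_fit"))
  fit$mu + k * fit$sigma
}

#' Segment white matter hyperintensities
#'
#' Voxels inside the WM mask with intensity strictly greater than the
#' threshold are labelled WMH; 26-connected components smaller than
#' `min_component_size` voxels are then removed (a deterministic stand-in for
#' manual artifact editing).
#'
#' @param flair A [vol3d].
#' @param wm_mask WM mask array (or `vol3d`).
#' @param threshold Intensity threshold (from [wmh_threshold()]).
#' @param min_component_size Minimum surviving component size in voxels.
#' @return Object of class `wmh_mask`: list with `mask` (logical array),
#'   `threshold_used`, `n_components_removed` and `total_volume_ml`.
#' @export
segment_wmh <- function(flair, wm_mask, threshold, min_component_size = 3L) {
  stopifnot(inherits(flair, "vol3d"))
  if (!is.finite(threshold)) stop("`threshold` must be finite", call. = FALSE)
  if (min_component_size < 0) stop("`min_component_size` must be >= 0", call. = FALSE)
  wm <- as_mask_array(wm_mask)
  assert_same_grid(flair, wm, "flair and wm_mask")
  mask <- wm & (flair$data > threshold)
  removed <- 0L
  if (min_component_size > 1L && any(mask)) {
    comp <- label_components_26(mask)
    sizes <- tabulate(comp$labels)
    drop <- which(sizes < min_component_size)
    if (length(drop)) {
      removed <- length(drop)
      kill <- comp$voxels[comp$labels %in% drop]
      mask[kill] <- FALSE
    }
  }
  structure(list(mask = mask, threshold_used = threshold,
                 n_components_removed = removed,
                 total_volume_ml = sum(mask) * voxel_volume_ml(flair)),
            class = "wmh_mask")
}

#' @export
print.wmh_mask <- function(x, ...) {
  cat(sprintf("<wmh_mask> %d voxels (%.4g mL), threshold %.4g, %d small component%s removed\n",
              sum(x$mask), x$total_volume_ml, x$threshold_used,
              x$n_components_removed, ifelse(x$n_components_removed == 1, "", "s")))
  invisible(x)
}

#' Total WMH volume in millilitres
#'
#' @param mask A `wmh_mask` (from [segment_wmh()]) or a logical/numeric array.
#' @param voxel_size Voxel edge lengths in mm (ignored for a `wmh_mask`
#'   carrying its own volume when omitted).
#' @return Volume in mL: voxel count times voxel volume.
#' @export
total_wmh_volume <- function(mask, voxel_size = NULL) {
  if (inherits(mask, "wmh_mask")) {
    if (is.null(voxel_size)) return(mask$total_volume_ml)
    mask <- mask$mask
  }
  m <- as_mask_array(mask)
  if (is.null(voxel_size))
    stop("`voxel_size` is required for a bare mask", call. = FALSE)
  sum(m) * voxel_volume_ml(voxel_size)
}

#' 26-connected component labelling of a 3D mask
#'
#' Builds the adjacency graph of mask voxels over the 26-neighborhood
#' (faces, edges and corners) and labels its connected components.
#'
#' @param mask Logical 3D array.
#' @return List with `voxels` (linear indices of mask voxels), `labels`
#'   (integer component id per mask voxel, 1..n_components) and
#'   `n_components`.
#' @export
label_components_26 <- function(mask) {
  mask <- as_mask_array(mask)
  d <- dim(mask)
  vox <- which(mask)
  if (!length(vox))
    return(list(voxels = integer(0), labels = integer(0), n_components = 0L))
  co <- arrayInd(vox, d)
  inside <- array(0L, dim = d)
  inside[vox] <- seq_along(vox)
  offsets <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offsets <- offsets[offsets$dx != 0 | offsets$dy != 0 | offsets$dz != 0, ]
  offsets <- offsets[with(offsets, dz > 0 | (dz == 0 & dy > 0) |
                            (dz == 0 & dy == 0 & dx > 0)), ]  # 13 forward shifts
  edges_from <- integer(0)
  edges_to <- integer(0)
  for (r in seq_len(nrow(offsets))) {
    ni <- co[, 1] + offsets$dx[r]
    nj <- co[, 2] + offsets$dy[r]
    nk <- co[, 3] + offsets$dz[r]
    ok <- ni >= 1L & ni <= d[1] & nj >= 1L & nj <= d[2] & nk >= 1L & nk <= d[3]
    if (!any(ok)) next
    nlin <- (nk[ok] - 1L) * d[1] * d[2] + (nj[ok] - 1L) * d[1] + ni[ok]
    hit <- inside[nlin]
    keep <- hit > 0L
    if (any(keep)) {
      edges_from <- c(edges_from, which(ok)[keep])
      edges_to <- c(edges_to, hit[keep])
    }
  }
  g <- igraph::make_empty_graph(n = length(vox), directed = FALSE)
  if (length(edges_from))
    g <- igraph::add_edges(g, rbind(edges_from, edges_to))
  comp <- igraph::components(g)
  list(voxels = vox, labels = as.integer(comp$membership),
       n_components = comp$no)
}
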