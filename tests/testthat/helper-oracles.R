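# Brute-force oracles, written independently of the package internals:
# explicit per-voxel loops and normal-equations algebra only.

loop_intersection_count <- function(a, b) {
  d <- dim(a)
  n <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    if (a[i, j, k] && b[i, j, k]) n <- n + 1L
  n
}

loop_mask_count <- function(a) {
  d <- dim(a)
  n <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    if (a[i, j, k]) n <- n + 1L
  n
}

loop_mean <- function(img, mask) {
  d <- dim(img)
  s <- 0; n <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    if (mask[i, j, k]) { s <- s + img[i, j, k]; n <- n + 1L }
  s / n
}

loop_threshold_mask <- function(flair, wm, thr) {
  d <- dim(flair)
  out <- array(FALSE, dim = d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    if (wm[i, j, k] && flair[i, j, k] > thr) out[i, j, k] <- TRUE
  out
}

# 26-connected component labelling by explicit flood fill
oracle_components_26 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, dim = d)
  cur <- 0L
  for (i0 in seq_len(d[1])) for (j0 in seq_len(d[2])) for (k0 in seq_len(d[3])) {
    if (!mask[i0, j0, k0] || lab[i0, j0, k0] > 0L) next
    cur <- cur + 1L
    stack <- list(c(i0, j0, k0))
    lab[i0, j0, k0] <- cur
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
        if (di == 0 && dj == 0 && dk == 0) next
        i <- v[1] + di; j <- v[2] + dj; k <- v[3] + dk
        if (i < 1 || i > d[1] || j < 1 || j > d[2] || k < 1 || k > d[3]) next
        if (mask[i, j, k] && lab[i, j, k] == 0L) {
          lab[i, j, k] <- cur
          stack[[length(stack) + 1L]] <- c(i, j, k)
        }
      }
    }
  }
  lab
}

# remove components smaller than min_size using the oracle labelling
oracle_clean_mask <- function(mask, min_size) {
  lab <- oracle_components_26(mask)
  if (max(lab) == 0L) return(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_size)
  array(lab %in% keep, dim = dim(mask))
}

# OLS through the normal equations
ols_normal_equations <- function(X, y) {
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

random_mask <- function(d, p, seed) {
  set.seed(seed)
  array(runif(prod(d)) < p, dim = d)
}
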