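#' Build the qualified-voxel mask for connectivity-density mapping
#'
#' A voxel qualifies if it lies in the gray-matter mask and its temporal-mean
#' intensity exceeds `snr_fraction` of the gray-matter grand mean intensity.
#' This screens out susceptibility-related signal-loss regions before
#' connection counting.
#'
#' @param series a [bold_series()] (unfiltered intensities; the signal
#'   criterion is meaningless on demeaned data).
#' @param gm_mask logical 3D gray-matter mask on the series grid.
#' @param snr_fraction fraction of the gray-matter mean intensity a voxel must
#'   exceed (default 0.5, i.e. a signal/noise criterion of >50%).
#' @return a [qualified_mask()] whose provenance records the parameters.
#' @export
build_qualified_mask <- function(series, gm_mask, snr_fraction = 0.5) {
  stopifnot(inherits(series, "bold_series"))
  if (!identical(dim(gm_mask), dim(series$data)[1:3])) {
    stop("gray-matter mask grid does not match the series grid")
  }
  if (!any(gm_mask)) stop("gray-matter mask is empty")
  if (!(snr_fraction > 0 && snr_fraction < 1)) {
    stop("'snr_fraction' must lie in (0, 1)")
  }
  mean_int <- rowMeans(series_matrix(series))
  gm_idx <- which(gm_mask)
  cutoff <- snr_fraction * mean(mean_int[gm_idx])
  q <- array(FALSE, dim(gm_mask))
  q[gm_idx] <- mean_int[gm_idx] > cutoff
  if (!any(q)) {
    stop("no voxel passes the signal criterion; review 'snr_fraction' or the input intensities")
  }
  qualified_mask(q, provenance = list(
    snr_fraction = snr_fraction,
    gm_voxels = length(gm_idx),
    qualified_voxels = sum(q),
    intensity_cutoff = cutoff))
}

#' Global functional connectivity density (raw connection counts)
#'
#' For every qualified voxel x0, counts the other qualified voxels whose time
#' course has Pearson correlation strictly greater than `r_threshold` with x0
#' (by default only positive correlations count; set `absolute_r = TRUE` to
#' count |r| exceedances). Self-correlation is never counted, so values lie in
#' [0, V-1] for V qualified voxels and the count matrix is symmetric.
#'
#' Computation is blocked: time courses are standardized once, then the
#' correlation matrix is formed block-by-block as a cross-product, which is
#' algebraically identical to the naive pairwise loop.
#'
#' @param series a preprocessed [bold_series()] with at least 3 frames.
#' @param mask a [qualified_mask()].
#' @param r_threshold correlation defining a functional connection
#'   (default 0.6; the inequality is strict).
#' @param absolute_r if `TRUE`, count connections on |r| rather than r.
#' @param block_size number of voxels per block of the cross-product.
#' @return a [gfcd_map()] at stage `"raw_count"`.
#' @export
compute_gfcd <- function(series, mask, r_threshold = 0.6,
                         absolute_r = FALSE, block_size = 1024L) {
  stopifnot(inherits(series, "bold_series"), inherits(mask, "qualified_mask"))
  if (!identical(dim(mask$mask), dim(series$data)[1:3])) {
    stop("qualified mask grid does not match the series grid")
  }
  nt <- n_frames(series)
  if (nt < 3L) stop("connectivity density needs at least 3 frames")
  idx <- which(mask$mask)
  M <- series_matrix(series)[idx, , drop = FALSE]
  ctr <- M - rowMeans(M)
  ss <- sqrt(rowSums(ctr^2))
  if (any(ss == 0)) {
    stop("zero-variance qualified voxel(s) at linear indices: ",
         paste(utils::head(idx[ss == 0], 20), collapse = ", "))
  }
  Z <- t(ctr / ss)  # time x voxels, unit-norm columns; crossprod = correlation
  V <- length(idx)
  counts <- integer(V)
  for (start in seq(1L, V, by = block_size)) {
    cols <- start:min(start + block_size - 1L, V)
    R <- crossprod(Z, Z[, cols, drop = FALSE])
    if (absolute_r) R <- abs(R)
    counts[cols] <- .colSums(R > r_threshold, V, length(cols)) - 1L
  }
  out <- array(0, dim(mask$mask))
  out[idx] <- counts
  gfcd_map(out, stage = "raw_count", r_threshold = r_threshold, mask = mask,
           affine = series$affine)
}

# Independent reference: naive O(V^2) double loop over qualified voxel pairs.
# Used by the test-suite and acceptance checks as the oracle for compute_gfcd.
#' @rdname compute_gfcd
#' @export
compute_gfcd_naive <- function(series, mask, r_threshold = 0.6,
                               absolute_r = FALSE) {
  idx <- which(mask$mask)
  M <- series_matrix(series)[idx, , drop = FALSE]
  V <- length(idx)
  counts <- integer(V)
  for (i in seq_len(V - 1)) {
    for (j in (i + 1):V) {
      r <- stats::cor(M[i, ], M[j, ])
      if (absolute_r) r <- abs(r)
      if (r > r_threshold) {
        counts[i] <- counts[i] + 1L
        counts[j] <- counts[j] + 1L
      }
    }
  }
  out <- array(0, dim(mask$mask))
  out[idx] <- counts
  gfcd_map(out, stage = "raw_count", r_threshold = r_threshold, mask = mask,
           affine = series$affine)
}

#' Grand-mean scaling of a connectivity-density map
#'
#' Divides every qualified voxel's value by the mean value over qualified
#' voxels, fixing the qualified mean at 1. This improves the normality of the
#' across-subject value distribution before group statistics.
#'
#' @param map a [gfcd_map()] at stage `"raw_count"`.
#' @return a [gfcd_map()] at stage `"scaled"` with qualified-voxel mean 1.
#' @export
grand_mean_scale <- function(map) {
  stopifnot(inherits(map, "gfcd_map"))
  if (map$stage != "raw_count") {
    stop("grand-mean scaling expects a 'raw_count' stage map, got '", map$stage, "'")
  }
  idx <- which(map$mask$mask)
  m <- mean(map$data[idx])
  if (m <= 0) stop("qualified-voxel mean is not positive; cannot scale an all-zero map")
  out <- map$data
  out[idx] <- out[idx] / m
  gfcd_map(out, stage = "scaled", r_threshold = map$r_threshold,
           mask = map$mask, affine = map$affine)
}

# Sampled, discretely normalized 1D Gaussian kernel (sd in voxel units).
gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Separable Gaussian smoothing of a 3D array with edge renormalization:
# each axis is convolved with a row-normalized banded operator, so constants
# are preserved exactly and interior impulses reproduce the sampled kernel.
smooth_gaussian <- function(arr, sigma_vox) {
  d <- dim(arr)
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    k <- gaussian_kernel_1d(s)
    n <- d[axis]
    r <- (length(k) - 1L) / 2L
    S <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- max(1L, i - r):min(n, i + r)
      w <- k[j - i + r + 1L]
      S[i, j] <- w / sum(w)
    }
    perm <- c(axis, setdiff(1:3, axis))
    a <- aperm(arr, perm)
    a <- array(S %*% matrix(a, n), dim = d[perm])
    arr <- aperm(a, order(perm))
  }
  arr
}

#' Gaussian spatial smoothing of a connectivity-density map
#'
#' Smooths with a separable Gaussian kernel of the given full width at half
#' maximum per axis (mm), converted to voxel units via the map's affine.
#' A FWHM of zero on every axis returns the input unchanged.
#'
#' @param map a [gfcd_map()] at stage `"scaled"`.
#' @param fwhm_mm numeric length-3 FWHM in mm (default `c(6, 6, 6)`).
#' @return a [gfcd_map()] at stage `"smoothed"`.
#' @export
smooth_map <- function(map, fwhm_mm = c(6, 6, 6)) {
  stopifnot(inherits(map, "gfcd_map"))
  if (map$stage != "scaled") {
    stop("smoothing expects a 'scaled' stage map, got '", map$stage, "'")
  }
  if (length(fwhm_mm) == 1) fwhm_mm <- rep(fwhm_mm, 3)
  if (any(fwhm_mm < 0)) stop("'fwhm_mm' must be non-negative")
  if (all(fwhm_mm == 0)) {
    return(gfcd_map(map$data, "smoothed", map$r_threshold, map$mask, map$affine))
  }
  sigma_vox <- fwhm_to_sigma(fwhm_mm) / voxel_sizes(map$affine)
  gfcd_map(smooth_gaussian(map$data, sigma_vox), stage = "smoothed",
           r_threshold = map$r_threshold, mask = map$mask, affine = map$affine)
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Full per-subject connectivity-density chain
#'
#' Convenience wrapper running [compute_gfcd()], [grand_mean_scale()] and
#' [smooth_map()] in the stated order.
#'
#' @inheritParams compute_gfcd
#' @inheritParams smooth_map
#' @return a [gfcd_map()] at stage `"smoothed"`.
#' @export
gfcd_chain <- function(series, mask, r_threshold = 0.6, fwhm_mm = c(6, 6, 6),
                       absolute_r = FALSE) {
  raw <- compute_gfcd(series, mask, r_threshold, absolute_r = absolute_r)
  smooth_map(grand_mean_scale(raw), fwhm_mm = fwhm_mm)
}
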