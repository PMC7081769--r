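#' Discard initial volumes of a BOLD series
#'
#' Resting-state acquisitions need a few frames to reach magnetization
#' equilibrium; those frames are dropped before any further processing.
#'
#' @param series a [bold_series()].
#' @param n_discard number of leading frames to remove (default 10, the usual
#'   choice for a 140-volume TR = 3 s acquisition, leaving 130 frames).
#' @return the trimmed [bold_series()]; the spatial grid is unchanged.
#' @export
discard_initial <- function(series, n_discard = 10) {
  stopifnot(inherits(series, "bold_series"))
  nt <- n_frames(series)
  if (n_discard < 0 || n_discard != round(n_discard)) {
    stop("'n_discard' must be a non-negative integer")
  }
  if (n_discard >= nt) {
    stop(sprintf("cannot discard %d frames from a %d-frame series", n_discard, nt))
  }
  if (n_discard == 0) return(series)
  bold_series(series$data[, , , (n_discard + 1):nt, drop = FALSE],
              affine = series$affine, tr_seconds = series$tr_seconds)
}

#' Framewise displacement from rigid-body motion parameters
#'
#' Power-style framewise displacement: the sum of absolute frame-to-frame
#' changes of the three translations (mm) plus the three rotations converted
#' to arc length on a sphere of the given radius. The first frame is defined
#' as zero displacement.
#'
#' @param motion numeric matrix with one row per frame and 6 columns
#'   (translations x, y, z in mm; rotations about x, y, z in radians).
#' @param sphere_radius_mm radius used to convert rotations to displacement
#'   (default 50 mm, the conventional adult head radius).
#' @return list of class `fd_series` with elements `fd` (per-frame mm, first
#'   element 0) and `mean_fd`.
#' @export
compute_fd <- function(motion, sphere_radius_mm = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stop("'motion' must have 6 columns")
  if (nrow(motion) < 2L) stop("framewise displacement needs at least 2 frames")
  assert_scalar_number(sphere_radius_mm, "sphere_radius_mm", lo = 0)
  d <- abs(diff(motion))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            sphere_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
  structure(list(fd = fd, mean_fd = mean(fd),
                 sphere_radius_mm = sphere_radius_mm),
            class = "fd_series")
}

# In-band Fourier frequencies for an n-sample series at sampling interval tr.
# Returns, for bins k = 1..floor(n/2), the frequency k/(n*tr).
fourier_freqs <- function(n, tr) (seq_len(n %/% 2)) / (n * tr)

# Nuisance basis spanning {intercept, linear ramp, out-of-band Fourier modes}.
bandpass_nuisance_basis <- function(n, tr, low_hz, high_hz) {
  t_c <- seq_len(n) - (n + 1) / 2
  ks <- seq_len(n %/% 2)
  f <- ks / (n * tr)
  out <- f < low_hz - 1e-12 | f > high_hz + 1e-12
  cols <- list(rep(1, n), t_c)
  ang <- 2 * pi * outer(seq_len(n) - 1, ks[out]) / n
  if (any(out)) {
    cosines <- cos(ang)
    sines <- sin(ang)
    # drop numerically null sine columns (Nyquist bin when n is even)
    keep <- colSums(sines^2) > 1e-8
    cols <- c(cols, list(cosines), list(sines[, keep, drop = FALSE]))
  }
  do.call(cbind, cols)
}

#' Joint linear detrending and ideal band-pass filtering
#'
#' Removes the temporal mean, the linear trend, and every Fourier component
#' outside `[low_hz, high_hz]` in a single orthogonal projection: each voxel's
#' time course is residualized against the span of the intercept, the centred
#' linear ramp, and the out-of-band discrete Fourier modes. Realizing the
#' filter as one projection makes the operation exactly idempotent. A
#' zero-phase Butterworth alternative (order 2, forward-backward) is available
#' for users who prefer a smooth transition band.
#'
#' @param series a [bold_series()].
#' @param low_hz,high_hz pass-band edges in Hz (defaults 0.01 and 0.1, the
#'   conventional resting-state band). Must satisfy
#'   `0 <= low_hz < high_hz <= 1/(2 * tr)`.
#' @param method `"projection"` (default, exact Fourier-domain filter) or
#'   `"butterworth"` (requires the \pkg{signal} package).
#' @return a [bold_series()] whose voxel time courses have zero temporal mean.
#' @export
detrend_and_bandpass <- function(series, low_hz = 0.01, high_hz = 0.1,
                                 method = c("projection", "butterworth")) {
  stopifnot(inherits(series, "bold_series"))
  method <- match.arg(method)
  nyq <- 1 / (2 * series$tr_seconds)
  if (!(low_hz >= 0 && low_hz < high_hz && high_hz <= nyq + 1e-12)) {
    stop(sprintf("band [%g, %g] Hz must lie within [0, Nyquist = %g] Hz",
                 low_hz, high_hz, nyq))
  }
  nt <- n_frames(series)
  M <- t(series_matrix(series))  # time x voxels
  if (method == "projection") {
    N <- bandpass_nuisance_basis(nt, series$tr_seconds, low_hz, high_hz)
    out <- qr.resid(qr(N), M)
  } else {
    if (!requireNamespace("signal", quietly = TRUE)) {
      stop("method = 'butterworth' requires the 'signal' package")
    }
    detr <- qr.resid(qr(cbind(1, seq_len(nt))), M)
    bf <- signal::butter(2, c(low_hz, high_hz) / nyq, type = "pass")
    out <- apply(detr, 2, function(v) signal::filtfilt(bf, v))
    out <- sweep(out, 2, colMeans(out))
  }
  bold_series(array(t(out), dim = dim(series$data)),
              affine = series$affine, tr_seconds = series$tr_seconds)
}

#' Regress nuisance signals out of a BOLD series
#'
#' Per voxel, returns the residuals of an ordinary least-squares projection of
#' the time course onto an intercept plus the supplied regressors (typically
#' the six rigid-body motion parameters and the white-matter and CSF mean
#' signals). Residuals are exactly orthogonal to every regressor column.
#'
#' @param series a [bold_series()].
#' @param regressors numeric matrix, one row per frame.
#' @return a [bold_series()] of residuals.
#' @export
nuisance_regress <- function(series, regressors) {
  stopifnot(inherits(series, "bold_series"))
  regressors <- as.matrix(regressors)
  nt <- n_frames(series)
  if (nrow(regressors) != nt) {
    stop(sprintf("regressors have %d rows but the series has %d frames",
                 nrow(regressors), nt))
  }
  # all-zero columns carry no signal; drop them instead of flagging the
  # design as collinear with the intercept
  keep <- colSums(abs(regressors)) > 0
  regressors <- regressors[, keep, drop = FALSE]
  X <- cbind(intercept = 1, regressors)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    bad[is.na(bad) | bad == ""] <- "(unnamed)"
    stop("nuisance design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  M <- t(series_matrix(series))
  out <- qr.resid(qx, M)
  bold_series(array(t(out), dim = dim(series$data)),
              affine = series$affine, tr_seconds = series$tr_seconds)
}

#' Mean tissue signal within a mask
#'
#' Frame-wise arithmetic mean of the series over the voxels of a mask,
#' e.g. to obtain white-matter or CSF nuisance signals.
#'
#' @param series a [bold_series()].
#' @param mask logical 3D array (or a [qualified_mask()]) on the series grid.
#' @return numeric vector, one value per frame.
#' @export
extract_tissue_signal <- function(series, mask) {
  stopifnot(inherits(series, "bold_series"))
  if (inherits(mask, "qualified_mask")) mask <- mask$mask
  if (!identical(dim(mask), dim(series$data)[1:3])) {
    stop("mask grid does not match the series grid")
  }
  idx <- which(mask)
  if (length(idx) == 0L) stop("mask is empty")
  colMeans(series_matrix(series)[idx, , drop = FALSE])
}
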