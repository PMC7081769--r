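#' BOLD time-series container
#'
#' A 4D (x, y, z, t) array with its voxel-to-world affine and repetition time.
#' All stages of the preprocessing and connectivity-density code operate on
#' this container.
#'
#' @param data numeric 4D array (x, y, z, t); all values must be finite.
#' @param affine 4x4 voxel-to-world transform in mm; must be invertible.
#' @param tr_seconds repetition time in seconds.
#' @return an object of class `bold_series`.
#' @export
bold_series <- function(data, affine = make_affine(dim = dim(data)[1:3]),
                        tr_seconds = 3) {
  if (length(dim(data)) != 4L) stop("'data' must be a 4D (x,y,z,t) array")
  if (dim(data)[4] < 1L) stop("series must contain at least one frame")
  if (!all(is.finite(data))) stop("'data' contains non-finite values")
  if (!is.matrix(affine) || any(dim(affine) != 4) ||
      abs(det(affine)) < .Machine$double.eps) {
    stop("'affine' must be an invertible 4x4 matrix")
  }
  assert_scalar_number(tr_seconds, "tr_seconds", lo = 1e-6)
  structure(list(data = data, affine = affine, tr_seconds = tr_seconds),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_series> %d x %d x %d grid, %d frames, TR %.3g s\n",
              d[1], d[2], d[3], d[4], x$tr_seconds))
  invisible(x)
}

n_frames <- function(series) dim(series$data)[4]

# Series reshaped to voxels x time.
series_matrix <- function(series) {
  d <- dim(series$data)
  matrix(series$data, prod(d[1:3]), d[4])
}

#' Qualified-voxel mask
#'
#' The set of gray-matter voxels passing the signal criterion, within which
#' connectivity density is both computed and counted. Carries provenance so a
#' map can be traced back to the mask that produced it.
#'
#' @param mask logical 3D array.
#' @param provenance list recording how the mask was built (gray-matter mask
#'   identity, signal-fraction threshold, ...).
#' @return object of class `qualified_mask`.
#' @export
qualified_mask <- function(mask, provenance = list()) {
  if (!is.logical(mask) || length(dim(mask)) != 3L) {
    stop("'mask' must be a logical 3D array")
  }
  if (!any(mask)) stop("qualified mask is empty")
  structure(list(mask = mask, provenance = provenance),
            class = "qualified_mask")
}

#' @export
print.qualified_mask <- function(x, ...) {
  cat(sprintf("<qualified_mask> %s grid, %d qualified voxels\n",
              paste(dim(x$mask), collapse = " x "), sum(x$mask)))
  invisible(x)
}

#' Connectivity-density map
#'
#' A per-subject 3D map with a stage tag tracking its position in the
#' raw count -> grand-mean scaled -> smoothed chain.
#'
#' @param data numeric 3D array; zero outside the qualified mask.
#' @param stage one of `"raw_count"`, `"scaled"`, `"smoothed"`.
#' @param r_threshold the correlation threshold that defined a connection.
#' @param mask the [qualified_mask()] the map was computed in.
#' @param affine 4x4 voxel-to-world transform.
#' @return object of class `gfcd_map`.
#' @export
gfcd_map <- function(data, stage, r_threshold, mask,
                     affine = make_affine(dim = dim(data))) {
  stage <- match.arg(stage, c("raw_count", "scaled", "smoothed"))
  if (length(dim(data)) != 3L) stop("'data' must be a 3D array")
  structure(list(data = data, stage = stage, r_threshold = r_threshold,
                 mask = mask, affine = affine),
            class = "gfcd_map")
}

#' @export
print.gfcd_map <- function(x, ...) {
  cat(sprintf("<gfcd_map> stage '%s', r > %.3g, %d qualified voxels\n",
              x$stage, x$r_threshold, sum(x$mask$mask)))
  invisible(x)
}
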