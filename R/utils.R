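#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a diagonal RAS affine for an isotropic or anisotropic grid
#'
#' Voxel (1,1,1) maps to the negated half-extent so that the grid centre sits
#' near the world origin, mimicking an MNI-style bounding box.
#'
#' @param voxel_mm numeric length-3 voxel edge lengths in mm.
#' @param dim integer length-3 grid dimensions (used to centre the origin).
#' @param origin optional explicit world coordinate of voxel (1,1,1).
#' @return 4x4 voxel-to-world affine matrix.
#' @export
make_affine <- function(voxel_mm = c(3, 3, 3), dim = NULL, origin = NULL) {
  stopifnot(length(voxel_mm) == 3, all(voxel_mm > 0))
  if (is.null(origin)) {
    origin <- if (is.null(dim)) c(0, 0, 0) else -(dim - 1) / 2 * voxel_mm
  }
  aff <- diag(c(voxel_mm, 1))
  aff[1:3, 4] <- origin
  aff
}

# Voxel edge lengths from an affine; errors on shear (non-orthogonal columns).
voxel_sizes <- function(affine) {
  A <- affine[1:3, 1:3]
  G <- crossprod(A)
  offdiag <- G - diag(diag(G))
  if (max(abs(offdiag)) > 1e-6 * max(abs(diag(G)))) {
    stop("affine has shear or oblique axes; only orthogonal voxel grids are supported")
  }
  sqrt(diag(G))
}

# Convert 1-based voxel indices (rows of a matrix) to world mm coordinates.
voxel_to_world <- function(ijk, affine) {
  ijk <- rbind(ijk)  # coerce vector to 1-row matrix
  xyz <- cbind(ijk - 1, 1) %*% t(affine)
  xyz[, 1:3, drop = FALSE]
}

assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    stop(sprintf("'%s' must be a finite number in [%s, %s]", name, lo, hi))
  }
  invisible(x)
}
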