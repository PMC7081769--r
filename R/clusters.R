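# Neighbourhood offsets for 6/18/26-connectivity, positive lexicographic half.
connectivity_offsets <- function(connectivity = 26) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  g <- switch(as.character(connectivity),
              "6"  = g[rowSums(abs(g)) == 1, , drop = FALSE],
              "18" = g[rowSums(abs(g)) <= 2, , drop = FALSE],
              "26" = g,
              stop("'connectivity' must be 6, 18 or 26"))
  # one representative per +/- pair
  keep <- apply(g, 1, function(o) {
    nz <- o[o != 0]
    nz[1] > 0
  })
  g[keep, , drop = FALSE]
}

# Label connected components of a logical 3D array. Returns an integer array
# (0 = background) plus component sizes. Edges are found by shifting the
# array along each neighbourhood offset; components come from igraph.
label_components <- function(above, connectivity = 26) {
  dims <- dim(above)
  idx <- which(above)
  lab <- array(0L, dims)
  if (length(idx) == 0L) return(list(labels = lab, sizes = integer(0)))
  rank <- integer(prod(dims))
  rank[idx] <- seq_along(idx)
  coords <- arrayInd(idx, dims)
  offs <- connectivity_offsets(connectivity)
  edges <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2, offs[k, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
    if (!any(ok)) next
    nb_lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * dims[1] +
      (nb[ok, 3] - 1L) * dims[1] * dims[2]
    hit <- above[nb_lin]
    if (!any(hit)) next
    edges[[k]] <- cbind(rank[idx[ok][hit]], rank[nb_lin[hit]])
  }
  el <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(el) && nrow(el)) g <- igraph::add_edges(g, t(el))
  comp <- igraph::components(g)
  lab[idx] <- comp$membership
  list(labels = lab, sizes = as.integer(comp$csize))
}

#' Estimate the spatial smoothness of residual fields
#'
#' Per-axis Gaussian-field FWHM from the variance of spatial first
#' differences of the standardized residual maps (the classic
#' neighbour-correlation estimator): with neighbour correlation r1 at voxel
#' spacing d, FWHM = d * sqrt(2 ln 2 / (-ln r1)). Estimates are pooled over
#' residual maps; this feeds the Monte-Carlo cluster-extent null, which
#' otherwise needs the smoothness supplied by the user.
#'
#' @param fmaps an `fmap_set` from [fit_voxelwise_ancova()], or a subjects x
#'   voxels residual matrix with `mask` giving the voxel layout.
#' @param mask a [qualified_mask()] (the analysis mask).
#' @param voxel_mm voxel sizes in mm (length 3).
#' @return numeric length-3 per-axis FWHM estimate in mm.
#' @export
estimate_smoothness <- function(fmaps, mask, voxel_mm = c(3, 3, 3)) {
  stopifnot(inherits(mask, "qualified_mask"))
  m <- mask$mask
  dims <- dim(m)
  if (inherits(fmaps, "fmap_set")) {
    R <- fmaps$residuals
    m <- fmaps$analysis_mask
  } else {
    R <- as.matrix(fmaps)
  }
  idx <- which(m)
  if (ncol(R) != length(idx)) stop("residual columns do not match the mask")
  if (nrow(R) < 2) stop("need at least 2 residual maps")
  sds <- apply(R, 1, stats::sd)
  if (any(sds == 0)) stop("constant residual map(s): zero spatial variance")
  R <- R / sds
  fwhm <- numeric(3)
  for (axis in 1:3) {
    if (dims[axis] < 2) stop("mask thinner than 2 voxels along axis ", axis)
    coords <- arrayInd(idx, dims)
    nb <- coords
    nb[, axis] <- nb[, axis] + 1L
    ok <- nb[, axis] <= dims[axis]
    nb_lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * dims[1] +
      (nb[ok, 3] - 1L) * dims[1] * dims[2]
    pair <- m[nb_lin]
    if (sum(pair) < 2) stop("mask too thin along axis ", axis)
    a_cols <- which(ok)[pair]
    b_cols <- match(nb_lin[pair], idx)
    dvals <- R[, a_cols, drop = FALSE] - R[, b_cols, drop = FALSE]
    vvals <- stats::var(as.vector(R))
    vdiff <- mean(dvals^2)
    r1 <- max(1e-4, min(1 - vdiff / (2 * vvals), 1 - 1e-8))
    fwhm[axis] <- voxel_mm[axis] * sqrt(2 * log(2) / (-log(r1)))
  }
  fwhm
}

#' Monte-Carlo cluster-extent threshold for smooth Gaussian null fields
#'
#' Simulates independent standard-normal fields on the mask's grid, smooths
#' them to the stated FWHM, standardizes within the mask, thresholds at the
#' two-tailed |z| quantile matching `voxel_p`, and records the maximum
#' suprathreshold cluster size per iteration. The extent threshold `k_min` is
#' the smallest cluster size whose exceedance fraction across iterations is
#' at most `alpha` (the familywise error target).
#'
#' @param mask a [qualified_mask()].
#' @param fwhm_mm smoothness of the null fields in mm (length 1 or 3).
#' @param voxel_p cluster-forming voxel-level p value.
#' @param alpha cluster-level familywise error target.
#' @param n_iter number of simulated null fields (>= 100).
#' @param connectivity cluster connectivity: 6, 18 or 26 (default 26).
#' @param voxel_mm voxel sizes in mm.
#' @param seed integer seed; results are deterministic given it.
#' @param two_tailed threshold |z| (default) or one-tailed z.
#' @return list of class `extent_threshold`: `k_min` (voxels), the simulated
#'   max-cluster sizes, the z threshold and all parameters.
#' @export
monte_carlo_extent_threshold <- function(mask, fwhm_mm, voxel_p = 0.005,
                                         alpha = 0.001, n_iter = 1000L,
                                         connectivity = 26,
                                         voxel_mm = c(3, 3, 3), seed = 1L,
                                         two_tailed = TRUE) {
  stopifnot(inherits(mask, "qualified_mask"))
  if (!(voxel_p > 0 && voxel_p < 1) || !(alpha > 0 && alpha < 1)) {
    stop("'voxel_p' and 'alpha' must lie in (0, 1)")
  }
  if (n_iter < 100) stop("'n_iter' must be at least 100")
  if (alpha < 1 / n_iter) {
    stop(sprintf("alpha = %g is unresolvable with n_iter = %d (< 1/n_iter)",
                 alpha, n_iter))
  }
  if (length(fwhm_mm) == 1) fwhm_mm <- rep(fwhm_mm, 3)
  zthr <- if (two_tailed) stats::qnorm(1 - voxel_p / 2) else stats::qnorm(1 - voxel_p)
  sigma_vox <- fwhm_to_sigma(fwhm_mm) / voxel_mm
  dims <- dim(mask$mask)
  inmask <- which(mask$mask)
  set.seed(as.integer(seed))
  max_sizes <- integer(n_iter)
  for (i in seq_len(n_iter)) {
    field <- array(stats::rnorm(prod(dims)), dims)
    if (any(sigma_vox > 0)) field <- smooth_gaussian(field, sigma_vox)
    field <- field / stats::sd(field[inmask])
    above <- array(FALSE, dims)
    above[inmask] <- abs(field[inmask]) > zthr
    cs <- label_components(above, connectivity)$sizes
    max_sizes[i] <- if (length(cs)) max(cs) else 0L
  }
  ks <- seq_len(max(max_sizes) + 1L)
  exceed <- vapply(ks, function(k) mean(max_sizes >= k), numeric(1))
  k_min <- ks[which(exceed <= alpha)[1]]
  structure(list(k_min = k_min, max_sizes = max_sizes, z_threshold = zthr,
                 voxel_p = voxel_p, alpha = alpha, n_iter = n_iter,
                 fwhm_mm = fwhm_mm, connectivity = connectivity, seed = seed),
            class = "extent_threshold")
}

#' @export
print.extent_threshold <- function(x, ...) {
  cat(sprintf(
    "<extent_threshold> k_min = %d voxels (voxel p < %g, alpha = %g, %d iterations, NN%s)\n",
    x$k_min, x$voxel_p, x$alpha, x$n_iter,
    c("6" = 1, "18" = 2, "26" = 3)[as.character(x$connectivity)]))
  invisible(x)
}

#' Form suprathreshold clusters from a voxel-wise p map
#'
#' Labels connected components of `{p < voxel_p}` under the chosen
#' connectivity, discards components smaller than `k_min`, and reports sizes
#' (voxels and mm3), peak world coordinates and peak statistics.
#'
#' @param pmap 3D array of voxel p values (NA outside the analysis mask).
#' @param voxel_p cluster-forming threshold.
#' @param k_min minimum cluster extent in voxels (from
#'   [monte_carlo_extent_threshold()] or the user).
#' @param connectivity 6, 18 or 26.
#' @param affine voxel-to-world transform for peak coordinates.
#' @param stat_map optional 3D statistic array (e.g. F); cluster peaks are
#'   located at its within-cluster maximum, otherwise at the p minimum.
#' @return object of class `cluster_report`: a per-cluster data frame
#'   (`label`, `n_voxels`, `size_mm3`, `peak_x/y/z`, `peak_stat`, `peak_p`),
#'   the label array, and the thresholds used. An empty report is valid.
#' @export
form_clusters <- function(pmap, voxel_p = 0.005, k_min = 1L,
                          connectivity = 26,
                          affine = make_affine(dim = dim(pmap)),
                          stat_map = NULL) {
  if (k_min < 1) stop("'k_min' must be at least 1")
  above <- !is.na(pmap) & pmap < voxel_p
  comp <- label_components(above, connectivity)
  keep <- which(comp$sizes >= k_min)
  vox_vol <- prod(voxel_sizes(affine))
  rows <- lapply(seq_along(keep), function(i) {
    lb <- keep[i]
    vox <- which(comp$labels == lb)
    stat <- if (is.null(stat_map)) -pmap[vox] else stat_map[vox]
    pk <- vox[which.max(stat)]
    xyz <- voxel_to_world(arrayInd(pk, dim(pmap)), affine)
    data.frame(label = i, n_voxels = length(vox),
               size_mm3 = length(vox) * vox_vol,
               peak_x = xyz[1], peak_y = xyz[2], peak_z = xyz[3],
               peak_stat = if (is.null(stat_map)) NA_real_ else stat_map[pk],
               peak_p = pmap[pk])
  })
  labels <- array(0L, dim(pmap))
  for (i in seq_along(keep)) labels[comp$labels == keep[i]] <- i
  structure(list(
    table = if (length(rows)) do.call(rbind, rows) else
      data.frame(label = integer(0), n_voxels = integer(0),
                 size_mm3 = numeric(0), peak_x = numeric(0),
                 peak_y = numeric(0), peak_z = numeric(0),
                 peak_stat = numeric(0), peak_p = numeric(0)),
    labels = labels, voxel_p = voxel_p, k_min = as.integer(k_min),
    connectivity = connectivity, affine = affine),
    class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("<cluster_report> %d cluster(s) (p < %g, k >= %d, %d-connectivity)\n",
              nrow(x$table), x$voxel_p, x$k_min, x$connectivity))
  if (nrow(x$table)) print(x$table, row.names = FALSE)
  invisible(x)
}

#' Extract per-subject mean values within each reported cluster
#'
#' @param maps list of [gfcd_map()] objects or a subjects x voxels matrix
#'   over the full grid.
#' @param report a [form_clusters()] result with at least one cluster.
#' @return numeric matrix, subjects x clusters, of within-cluster means.
#' @export
extract_cluster_means <- function(maps, report) {
  stopifnot(inherits(report, "cluster_report"))
  if (nrow(report$table) == 0L) stop("cluster report is empty")
  dims <- dim(report$labels)
  if (is.matrix(maps)) {
    maps <- lapply(seq_len(nrow(maps)), function(i) array(maps[i, ], dims))
  }
  ncl <- nrow(report$table)
  cluster_idx <- lapply(seq_len(ncl), function(l) which(report$labels == l))
  out <- matrix(NA_real_, length(maps), ncl,
                dimnames = list(NULL, paste0("cluster_", report$table$label)))
  for (i in seq_along(maps)) {
    d <- maps[[i]]
    if (inherits(d, "gfcd_map")) d <- d$data
    if (!identical(dim(d), dims)) stop("map grid does not match the cluster report")
    out[i, ] <- vapply(cluster_idx, function(vx) mean(d[vx]), numeric(1))
  }
  out
}
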