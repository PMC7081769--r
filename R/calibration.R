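#' Familywise-error study of the cluster-extent correction on null cohorts
#'
#' Generates fully null synthetic cohorts of smooth subject maps, fits the
#' voxel-wise factorial ANCOVA to each, applies the Monte-Carlo cluster-extent
#' threshold (computed once for the shared mask and smoothness), and reports
#' the fraction of replicates in which any cluster of the chosen effect
#' survives - the empirical familywise error rate, which should not exceed
#' `alpha` up to binomial noise.
#'
#' @param n_replicates number of null cohorts.
#' @param n_per_cell subjects per (diagnosis x genotype) cell.
#' @param grid_shape,voxel_mm map geometry.
#' @param fwhm_mm spatial smoothness of the subject maps (and of the
#'   simulated null).
#' @param voxel_p cluster-forming voxel p.
#' @param alpha cluster-level familywise error target.
#' @param n_iter Monte-Carlo iterations for the extent threshold.
#' @param connectivity cluster connectivity.
#' @param effect which F map to monitor (`"diagnosis"`, `"genotype"` or
#'   `"interaction"`).
#' @param seed integer seed (threshold simulation and replicate r use
#'   `seed` and `seed + r`).
#' @return list with `fwer`, `any_cluster` (logical per replicate), `k_min`
#'   and the study parameters.
#' @export
null_cluster_fwer_study <- function(n_replicates = 200, n_per_cell = 6,
                                    grid_shape = c(20, 20, 20),
                                    voxel_mm = c(3, 3, 3), fwhm_mm = 6,
                                    voxel_p = 0.005, alpha = 0.05,
                                    n_iter = 1000, connectivity = 26,
                                    effect = "diagnosis", seed = 1L) {
  mask <- qualified_mask(array(TRUE, grid_shape),
                         provenance = list(kind = "full-grid study mask"))
  extent <- monte_carlo_extent_threshold(
    mask, fwhm_mm, voxel_p = voxel_p, alpha = alpha, n_iter = n_iter,
    connectivity = connectivity, voxel_mm = voxel_mm, seed = seed)
  any_cluster <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    coh <- generate_gfcd_cohort(n_per_cell, grid_shape, fwhm_mm, voxel_mm,
                                seed = seed + r)
    design <- build_design(coh$phenotypes)
    fm <- fit_voxelwise_ancova(coh$maps, design, coh$mask)
    cl <- form_clusters(fm$p[[effect]], voxel_p, extent$k_min, connectivity,
                        affine = make_affine(voxel_mm, dim = grid_shape))
    any_cluster[r] <- nrow(cl$table) > 0
  }
  list(fwer = mean(any_cluster), any_cluster = any_cluster,
       k_min = extent$k_min, alpha = alpha, voxel_p = voxel_p,
       n_replicates = n_replicates, effect = effect)
}

#' Spatial recovery study for a planted interaction effect
#'
#' Plants a diagnosis x genotype interaction pattern (cell means
#' `d * [[1, 0, -1], [-1, 0, 1]]`) inside a spherical region of otherwise
#' null smooth cohorts, runs the voxel-wise ANCOVA plus cluster-extent
#' correction, and scores the Dice overlap between the surviving interaction
#' clusters and the planted region.
#'
#' @inheritParams null_cluster_fwer_study
#' @param effect_size the cell-mean amplitude `d` in within-cell SD units.
#' @param center,radius sphere of planted voxels (defaults: grid centre,
#'   radius 3 voxels).
#' @return list with `dice` (per replicate), `success_rate`
#'   (fraction with Dice > 0.5), `k_min`.
#' @export
planted_interaction_recovery_study <- function(n_replicates = 25,
                                               effect_size = 1.5,
                                               n_per_cell = 6,
                                               grid_shape = c(20, 20, 20),
                                               voxel_mm = c(3, 3, 3),
                                               fwhm_mm = 6, voxel_p = 0.005,
                                               alpha = 0.05, n_iter = 1000,
                                               connectivity = 26,
                                               center = NULL, radius = 3,
                                               seed = 1L) {
  if (is.null(center)) center <- round(grid_shape / 2)
  pattern <- effect_size * matrix(c(1, 0, -1, -1, 0, 1), 2, 3, byrow = TRUE)
  region <- list(center = center, radius = radius, cell_means = pattern)
  mask <- qualified_mask(array(TRUE, grid_shape))
  extent <- monte_carlo_extent_threshold(
    mask, fwhm_mm, voxel_p = voxel_p, alpha = alpha, n_iter = n_iter,
    connectivity = connectivity, voxel_mm = voxel_mm, seed = seed)
  dice <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    coh <- generate_gfcd_cohort(n_per_cell, grid_shape, fwhm_mm, voxel_mm,
                                effect_regions = list(region),
                                seed = seed + r)
    design <- build_design(coh$phenotypes)
    fm <- fit_voxelwise_ancova(coh$maps, design, coh$mask)
    cl <- form_clusters(fm$p$interaction, voxel_p, extent$k_min,
                        connectivity,
                        affine = make_affine(voxel_mm, dim = grid_shape))
    got <- cl$labels > 0
    dice[r] <- 2 * sum(got & coh$effect_mask) /
      (sum(got) + sum(coh$effect_mask))
  }
  list(dice = dice, success_rate = mean(dice > 0.5), k_min = extent$k_min,
       effect_size = effect_size, n_replicates = n_replicates)
}

#' Coverage study for the bias-corrected bootstrap indirect-effect interval
#'
#' Simulates datasets from the known mediation model `M = aX + e1`,
#' `Y = c'X + bM + e2`, fits each with [fit_mediation()], and reports how
#' often the bias-corrected interval covers the true indirect effect `a*b`.
#' With `a = 0` the complement of coverage of zero is the type-I error rate.
#'
#' @param n_datasets number of simulated datasets.
#' @param n sample size per dataset.
#' @param a,b,c_prime true paths.
#' @param n_boot bootstrap draws per dataset.
#' @param ci_level nominal coverage.
#' @param seed integer seed (dataset r uses `seed + r`).
#' @return list with `coverage`, `covered` (logical), `true_indirect`.
#' @export
mediation_coverage_study <- function(n_datasets = 500, n = 100, a = 0.5,
                                     b = 0.5, c_prime = 0, n_boot = 2000,
                                     ci_level = 0.95, seed = 1L) {
  true_ab <- a * b
  covered <- logical(n_datasets)
  for (r in seq_len(n_datasets)) {
    d <- simulate_mediation_data(n, a, b, c_prime, seed = seed + r)
    f <- fit_mediation(d$x, d$m, d$y, n_boot = n_boot, ci_level = ci_level,
                       seed = seed + r)
    covered[r] <- f$ci_low <= true_ab && true_ab <= f$ci_high
  }
  list(coverage = mean(covered), covered = covered, true_indirect = true_ab,
       n_datasets = n_datasets, n = n, n_boot = n_boot)
}
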