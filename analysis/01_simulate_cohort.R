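#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# Two artifacts come out of this stage:
#   (a) a full-size phenotype manifest (185 screened subjects: the reference
#       cell layout of 177 plus 8 planted exclusions) used by the scalar
#       statistics and the screening bookkeeping, and
#   (b) a desk-scale imaging cohort (6 cells x 4 subjects, 14x14x10 grid,
#       140 volumes at TR 3 s) with planted connectivity hubs, used by the
#       image-processing stages. Full-resolution brains would make the
#       O(V^2) connection counting pointlessly slow for a demonstration.

suppressPackageStartupMessages(library(gfcdkit))
seed <- 20260101L
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

ref <- reference_phenotype_effects()

## (a) full-size phenotype manifest -----------------------------------------
sizes <- reference_cell_sizes()
# n_per_cell follows the (CN e2+, MCI e2+, CN e3e3, ...) cell order
spec_full <- cohort_spec(n_per_cell = unname(sizes), grid_shape = c(6, 6, 4))
eff_full <- effect_spec(cell_means = ref$cell_means, noise_sd = ref$noise_sd,
                        covariate_slopes = ref$covariate_slopes)
full <- generate_cohort(spec_full, eff_full, seed = seed, make_bold = FALSE,
                        motion_amplitude_mm = 0.03, n_poor_signal = 0)
# append 8 screened-out subjects: 3 poor signal, 5 excessive motion
extra <- generate_cohort(cohort_spec(n_per_cell = 2, grid_shape = c(6, 6, 4)),
                         eff_full, seed = seed + 1, make_bold = FALSE)
extra_ph <- extra$phenotypes[1:8, ]
extra_mot <- extra$motion[1:8]
extra_ph$subject_id <- sprintf("sub-x%02d", 1:8)
extra_ph$poor_signal <- c(rep(TRUE, 3), rep(FALSE, 5))
for (i in 4:8) extra_mot[[i]][, 1] <- extra_mot[[i]][, 1] +
  seq(0, 5, length.out = nrow(extra_mot[[i]]))  # drifts past the 3 mm limit
manifest <- rbind(full$phenotypes, extra_ph)
motion_all <- c(full$motion, extra_mot)
write_phenotypes(manifest, "results/01_manifest_screened.tsv")
saveRDS(list(manifest = manifest, motion = motion_all),
        "scratch/01_full_cohort.rds")
message(sprintf("screened manifest: %d subjects (%d flagged poor-signal)",
                nrow(manifest), sum(manifest$poor_signal)))

## (b) desk-scale imaging cohort --------------------------------------------
spec_img <- cohort_spec(n_per_cell = 4, n_volumes = 140, tr_seconds = 3,
                        grid_shape = c(14, 14, 10), voxel_mm = c(3, 3, 3))
ctr <- round(spec_img$grid_shape / 2)
# hub 1: constant strength (a stable hub every group shares)
# hub 2: interaction-patterned strength (stronger coupling in MCI e4+,
#        weaker in MCI e2+), the effect the voxel-wise ANCOVA should find
hub_interaction <- matrix(c(1.0, 1.0, 1.0,
                            1.6, 1.0, 0.4), 2, 3, byrow = TRUE)
eff_img <- effect_spec(
  cell_means = ref$cell_means, noise_sd = ref$noise_sd,
  covariate_slopes = ref$covariate_slopes,
  hub_regions = list(
    list(center = ctr + c(-3, -3, 0), radius = 2, strength = 1.5),
    list(center = ctr + c(3, 3, 1), radius = 2, strength = hub_interaction)),
  mediation_paths = list(a = 0.6, b = 0.6, c_prime = 0.1))
img <- generate_cohort(spec_img, eff_img, seed = seed + 2)
saveRDS(list(spec = spec_img, effects = eff_img, cohort = img),
        "scratch/01_imaging_cohort.rds")
write_phenotypes(img$phenotypes, "results/01_imaging_phenotypes.tsv")
for (i in seq_len(3)) {  # a few example sidecar files in standard formats
  write_motion(img$motion[[i]], sprintf("scratch/01_motion_sub%02d.txt", i))
  write_bold_nifti(img$bold[[i]], sprintf("scratch/01_bold_sub%02d.nii.gz", i))
}
message(sprintf("imaging cohort: %d subjects on a %s grid, %d volumes",
                nrow(img$phenotypes),
                paste(spec_img$grid_shape, collapse = "x"),
                spec_img$n_volumes))
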