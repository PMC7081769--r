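#!/usr/bin/env Rscript
# Stage 2: subject-level quality control and BOLD preprocessing.
#
# QC applies the screening rules (poor rs-fMRI signal; translation > 3 mm or
# rotation > 2 degrees relative to the first frame) to the full manifest.
# The imaging cohort is then conditioned: discard the first 10 volumes,
# joint detrend + 0.01-0.1 Hz band-pass projection, regression of the six
# motion parameters, and framewise displacement on a 50 mm sphere.

suppressPackageStartupMessages(library(gfcdkit))

full <- readRDS("scratch/01_full_cohort.rds")
filt <- apply_participant_filter(full$manifest, full$motion)
qc_tab <- data.frame(stage = c("screened", "poor_signal", "motion", "analyzed"),
                     n = c(filt$n_in, filt$n_poor_signal, filt$n_motion,
                           filt$n_out))
utils::write.table(qc_tab, "results/02_qc_bookkeeping.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
write_phenotypes(filt$kept, "results/02_analyzed_phenotypes.tsv")
message(sprintf("QC: %d screened -> %d analyzed (%d poor signal, %d motion)",
                filt$n_in, filt$n_out, filt$n_poor_signal, filt$n_motion))
stopifnot(filt$n_in == filt$n_out + filt$n_poor_signal + filt$n_motion)

img <- readRDS("scratch/01_imaging_cohort.rds")
n_discard <- 10
pre <- vector("list", nrow(img$cohort$phenotypes))
fd <- numeric(length(pre))
for (i in seq_along(pre)) {
  s <- discard_initial(img$cohort$bold[[i]], n_discard)
  s <- detrend_and_bandpass(s, 0.01, 0.1)
  mot <- img$cohort$motion[[i]][-seq_len(n_discard), , drop = FALSE]
  pre[[i]] <- nuisance_regress(s, mot)
  fd[i] <- compute_fd(mot)$mean_fd
}
pheno <- img$cohort$phenotypes
pheno$mean_fd <- fd
utils::write.table(
  data.frame(subject_id = pheno$subject_id, mean_fd_mm = round(fd, 4)),
  "results/02_mean_fd.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
saveRDS(list(pre = pre, pheno = pheno, gm_mask = img$cohort$gm_mask,
             bold_raw1 = img$cohort$bold[[1]], spec = img$spec,
             effects = img$effects),
        "scratch/02_preprocessed.rds")
message(sprintf("preprocessed %d subjects; %d frames kept; mean FD %.3f mm",
                length(pre), dim(pre[[1]]$data)[4], mean(fd)))
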