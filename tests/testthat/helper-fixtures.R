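# Shared fixture builders: everything is generated in code at test time.

# Wrap a voxels x time matrix into a bold_series on the given 3D grid.
series_from_matrix <- function(M, dims, tr = 3, voxel_mm = c(3, 3, 3)) {
  stopifnot(nrow(M) == prod(dims))
  bold_series(array(M, c(dims, ncol(M))),
              affine = make_affine(voxel_mm, dim = dims), tr_seconds = tr)
}

full_mask <- function(dims) qualified_mask(array(TRUE, dims))

# A small phenotype table with all six cells populated and pure-noise outcome.
noise_pheno <- function(n_per_cell = 4, seed = 1, outcome_sd = 1) {
  set.seed(seed)
  g <- expand.grid(diagnosis = c("CN", "MCI"),
                   genotype = c("e2+", "e3e3", "e4+"),
                   stringsAsFactors = FALSE)
  n <- n_per_cell * 6
  data.frame(
    subject_id = sprintf("s%02d", seq_len(n)),
    diagnosis = rep(g$diagnosis, each = n_per_cell),
    genotype = rep(g$genotype, each = n_per_cell),
    age = rnorm(n, 73, 6),
    sex = sample(c("F", "M"), n, replace = TRUE),
    education = rnorm(n, 16, 2.5),
    mean_fd = abs(rnorm(n, 0.15, 0.05)),
    y = rnorm(n, 0, outcome_sd),
    stringsAsFactors = FALSE)
}

# Brute-force Type-III F via explicit normal equations (independent of the
# package's QR route): residual sums of squares from (X'X)^{-1} X'y.
normal_eq_rss <- function(X, y) {
  beta <- solve(crossprod(X), crossprod(X, y))
  sum((y - X %*% beta)^2)
}

brute_force_ancova_F <- function(X, cols_by_effect, y) {
  rss_full <- normal_eq_rss(X, y)
  df_err <- nrow(X) - ncol(X)
  out <- list()
  for (eff in names(cols_by_effect)) {
    cc <- cols_by_effect[[eff]]
    rss_red <- normal_eq_rss(X[, -cc, drop = FALSE], y)
    out[[eff]] <- ((rss_red - rss_full) / length(cc)) / (rss_full / df_err)
  }
  out
}
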