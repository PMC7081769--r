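#' Cohort geometry and acquisition specification for the synthetic generator
#'
#' Describes the 2x3 (diagnosis x genotype) cell sizes and the acquisition
#' the synthetic BOLD series emulate: 140 volumes at TR = 3 s on a 3 mm
#' isotropic grid by default. Grid volume is guarded because downstream
#' connection counting is O(V^2).
#'
#' @param n_per_cell subjects per cell: a single integer or a length-6 vector
#'   in cell order (CN e2+, CN e3e3, CN e4+, MCI e2+, MCI e3e3, MCI e4+).
#' @param n_volumes frames per series (> 10 so the equilibration discard
#'   leaves a nonempty series).
#' @param tr_seconds repetition time.
#' @param grid_shape 3D grid dimensions.
#' @param voxel_mm voxel edge lengths in mm.
#' @param max_voxels guard on `prod(grid_shape)` (default 50000), configurable
#'   for users who accept the quadratic cost.
#' @return validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_cell = 3, n_volumes = 140, tr_seconds = 3,
                        grid_shape = c(14, 14, 10), voxel_mm = c(3, 3, 3),
                        max_voxels = 50000) {
  if (length(n_per_cell) == 1) n_per_cell <- rep(n_per_cell, 6)
  if (length(n_per_cell) != 6 || any(n_per_cell < 2)) {
    stop("invalid 'n_per_cell': need 1 or 6 integers, all >= 2")
  }
  if (n_volumes <= 10) stop("invalid 'n_volumes': must exceed 10")
  assert_scalar_number(tr_seconds, "tr_seconds", lo = 1e-6)
  if (length(grid_shape) != 3 || any(grid_shape < 1)) {
    stop("invalid 'grid_shape': need 3 positive integers")
  }
  if (prod(grid_shape) > max_voxels) {
    stop(sprintf("invalid 'grid_shape': %d voxels exceeds the O(V^2) guard of %d",
                 prod(grid_shape), max_voxels))
  }
  if (length(voxel_mm) != 3 || any(voxel_mm <= 0)) {
    stop("invalid 'voxel_mm': need 3 positive numbers")
  }
  structure(list(n_per_cell = as.integer(n_per_cell),
                 n_volumes = as.integer(n_volumes),
                 tr_seconds = tr_seconds,
                 grid_shape = as.integer(grid_shape),
                 voxel_mm = voxel_mm),
            class = "cohort_spec")
}

#' Planted-effect specification for the synthetic generator
#'
#' Defines the structure the downstream analysis is meant to recover:
#' per-cell outcome means, covariate slopes, residual noise, connectivity
#' hubs with per-cell strengths, and optional planted mediation paths.
#'
#' Hub construction: each hub carries one latent unit-variance signal; a
#' member voxel's time course is `s * latent + N(0, 1)` where `s` is the
#' cell's strength, so two members correlate at exactly `s^2 / (s^2 + 1)` in
#' expectation.
#'
#' @param cell_means named list; per outcome a 2x3 matrix of cell means
#'   (rows CN/MCI, columns e2+/e3e3/e4+).
#' @param noise_sd named numeric vector of residual SDs per outcome (all > 0).
#' @param covariate_slopes named list; per outcome a numeric vector with
#'   elements `age`, `sex`, `education` (effects per year, per male, per
#'   year). Missing outcomes get zero slopes.
#' @param hub_regions list of hubs, each a list with `center` (voxel index,
#'   length 3), `radius` (voxels, >= 1) and `strength` (a single number or a
#'   2x3 per-cell matrix of connection-strength scalars).
#' @param mediation_paths optional list with elements `a`, `b`, `c_prime`
#'   (and optionally `m_name`, `y_name`) planting a known mediator.
#' @return validated list of class `effect_spec`.
#' @export
effect_spec <- function(cell_means = list(), noise_sd = numeric(),
                        covariate_slopes = list(), hub_regions = list(),
                        mediation_paths = NULL) {
  for (nm in names(cell_means)) {
    m <- cell_means[[nm]]
    if (!is.matrix(m) || any(dim(m) != c(2, 3)) || !all(is.finite(m))) {
      stop("invalid 'cell_means' for outcome '", nm, "': need a finite 2x3 matrix")
    }
  }
  if (any(noise_sd <= 0) || !all(is.finite(noise_sd))) {
    stop("invalid 'noise_sd': all residual SDs must be positive and finite")
  }
  miss_sd <- setdiff(names(cell_means), names(noise_sd))
  if (length(miss_sd)) stop("invalid 'noise_sd': missing outcome(s) ",
                            paste(miss_sd, collapse = ", "))
  for (h in hub_regions) {
    if (is.null(h$center) || length(h$center) != 3) {
      stop("invalid 'hub_regions': each hub needs a length-3 'center'")
    }
    if (is.null(h$radius) || h$radius < 1) {
      stop("invalid 'hub_regions': hub radius must be >= 1 voxel")
    }
    s <- h$strength
    if (is.null(s) || !(length(s) == 1 || all(dim(s) == c(2, 3))) ||
        any(s < 0) || !all(is.finite(s))) {
      stop("invalid 'hub_regions': 'strength' must be a non-negative scalar or 2x3 matrix")
    }
  }
  if (!is.null(mediation_paths)) {
    if (!all(c("a", "b", "c_prime") %in% names(mediation_paths))) {
      stop("invalid 'mediation_paths': need elements a, b, c_prime")
    }
  }
  structure(list(cell_means = cell_means, noise_sd = noise_sd,
                 covariate_slopes = covariate_slopes,
                 hub_regions = hub_regions,
                 mediation_paths = mediation_paths),
            class = "effect_spec")
}

cell_grid <- function() expand.grid(diagnosis = c("CN", "MCI"),
                                    genotype = c("e2+", "e3e3", "e4+"),
                                    stringsAsFactors = FALSE)

#' Cell sizes of the reference MCI/CN genotype cohort
#'
#' The 2x3 table of subject counts used as the generator's realistic
#' unbalanced layout: CN 19/39/18 and MCI 13/46/42 across the
#' e2+/e3e3/e4+ genotype groups (177 subjects in total, 101 of them MCI).
#'
#' @return named integer vector of length 6 in cell order.
#' @export
reference_cell_sizes <- function() {
  g <- cell_grid()
  stats::setNames(c(19L, 13L, 39L, 46L, 18L, 42L),
                  paste(g$diagnosis, g$genotype, sep = "_"))
}

#' Reference cell means and noise SDs for phenotype outcomes
#'
#' Per-outcome 2x3 cell means and pooled residual SDs on the scale of a
#' typical elderly MCI/CN cohort (MMSE points, ADAS13 points, RAVLT scores,
#' seconds for Trail-Making B, ml for volumes). These are the generator's
#' default study conditions.
#'
#' @return list with `cell_means`, `noise_sd` and `covariate_slopes` suitable
#'   for [effect_spec()].
#' @export
reference_phenotype_effects <- function() {
  mk <- function(cn, mci) matrix(c(cn, mci), nrow = 2, byrow = TRUE,
                                 dimnames = list(c("CN", "MCI"),
                                                 c("e2+", "e3e3", "e4+")))
  cell_means <- list(
    MMSE = mk(c(28.63, 28.79, 28.78), c(28.92, 28.10, 27.69)),
    ADAS13 = mk(c(11.89, 9.21, 9.25), c(13.33, 13.81, 15.68)),
    RAVLT_immediate = mk(c(45.47, 43.76, 42.44), c(42.91, 35.37, 37.52)),
    RAVLT_learning = mk(c(5.26, 5.69, 5.88), c(4.91, 4.95, 4.40)),
    RAVLT_forgetting = mk(c(35.31, 39.40, 36.53), c(42.09, 52.71, 64.77)),
    LogicalMemory = mk(c(13.79, 13.76, 13.94), c(6.61, 6.91, 6.71)),
    TrailsB = mk(c(84.52, 72.84, 90.11), c(81.07, 109.93, 105.90)),
    ICV = mk(c(1490, 1570, 1510), c(1510, 1530, 1510)),
    Hippocampus = mk(c(7.32, 7.44, 7.74), c(7.64, 7.43, 7.29)),
    Entorhinal = mk(c(3.64, 3.96, 3.81), c(3.84, 3.71, 3.47)),
    Fusiform = mk(c(17.76, 18.28, 18.07), c(18.23, 17.45, 17.62)))
  noise_sd <- c(MMSE = 1.6, ADAS13 = 5.8, RAVLT_immediate = 10.3,
                RAVLT_learning = 2.4, RAVLT_forgetting = 27.5,
                LogicalMemory = 3.0, TrailsB = 46.0, ICV = 160,
                Hippocampus = 0.9, Entorhinal = 0.7, Fusiform = 2.2)
  covariate_slopes <- list(
    MMSE = c(age = -0.03, sex = 0, education = 0.05),
    ADAS13 = c(age = 0.1, sex = 0.5, education = -0.2),
    RAVLT_immediate = c(age = -0.25, sex = -3, education = 0.5))
  list(cell_means = cell_means, noise_sd = noise_sd,
       covariate_slopes = covariate_slopes)
}

#' Generate a synthetic phenotype table
#'
#' Draws demographics (age ~ N(73, 6), education ~ N(16, 2.5), sex
#' Bernoulli(0.5)) and outcomes as cell mean + covariate slopes x centred
#' covariates + Gaussian noise. If `mediation_paths` are planted, a mediator
#' and outcome column are generated from the ordinally coded genotype with
#' unit-variance noises.
#'
#' @param cohort a [cohort_spec()] (only `n_per_cell` is used here).
#' @param effects an [effect_spec()].
#' @param seed integer seed; identical (specs, seed) give identical tables.
#' @return data frame with `subject_id`, `diagnosis`, `genotype`, `age`,
#'   `sex`, `education` and one column per outcome.
#' @export
generate_phenotypes <- function(cohort, effects, seed = 1L) {
  stopifnot(inherits(cohort, "cohort_spec"), inherits(effects, "effect_spec"))
  set.seed(as.integer(seed))
  g <- cell_grid()
  n <- cohort$n_per_cell
  diagnosis <- rep(g$diagnosis, n)
  genotype <- rep(g$genotype, n)
  N <- length(diagnosis)
  pheno <- data.frame(
    subject_id = sprintf("sub-%03d", seq_len(N)),
    diagnosis = diagnosis, genotype = genotype,
    age = stats::rnorm(N, 73, 6),
    sex = ifelse(stats::rbinom(N, 1, 0.5) == 1, "M", "F"),
    education = stats::rnorm(N, 16, 2.5),
    stringsAsFactors = FALSE)
  ci <- match(paste(diagnosis, genotype),
              paste(g$diagnosis, g$genotype))
  male <- as.numeric(pheno$sex == "M")
  for (oc in names(effects$cell_means)) {
    mu <- effects$cell_means[[oc]]
    sl <- effects$covariate_slopes[[oc]] %||% c(age = 0, sex = 0, education = 0)
    vals <- mu[cbind(match(diagnosis, rownames(mu)),
                     match(genotype, colnames(mu)))] +
      sl[["age"]] * (pheno$age - 73) + sl[["sex"]] * (male - 0.5) +
      sl[["education"]] * (pheno$education - 16) +
      stats::rnorm(N, 0, effects$noise_sd[[oc]])
    pheno[[oc]] <- vals
  }
  if (!is.null(effects$mediation_paths)) {
    mp <- effects$mediation_paths
    xg <- genotype_code(genotype)
    med <- mp$a * xg + stats::rnorm(N)
    pheno[[mp$m_name %||% "planted_mediator"]] <- med
    pheno[[mp$y_name %||% "planted_outcome"]] <-
      mp$c_prime * xg + mp$b * med + stats::rnorm(N)
  }
  pheno
}

#' Generate a rigid-body motion trace as a scaled random walk
#'
#' Six columns (translations mm, rotations radians) built from independent
#' Gaussian random-walk increments; rotation increments are scaled to
#' `amplitude_mm / 50` radians so their arc displacement on a 50 mm sphere
#' matches the translation scale. Zero amplitude gives an exactly zero trace.
#'
#' @param n_volumes number of frames (>= 2).
#' @param amplitude_mm per-step translation increment SD in mm.
#' @param seed integer seed, or `NULL` to draw from the current RNG stream.
#' @return numeric `n_volumes` x 6 matrix.
#' @export
generate_motion <- function(n_volumes, amplitude_mm = 0.05, seed = NULL) {
  if (n_volumes < 2) stop("'n_volumes' must be at least 2")
  if (amplitude_mm < 0) stop("'amplitude_mm' must be non-negative")
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (amplitude_mm == 0) {
    out <- matrix(0, n_volumes, 6)
  } else {
    inc <- cbind(matrix(stats::rnorm(3 * (n_volumes - 1), 0, amplitude_mm),
                        ncol = 3),
                 matrix(stats::rnorm(3 * (n_volumes - 1), 0, amplitude_mm / 50),
                        ncol = 3))
    out <- rbind(0, apply(inc, 2, cumsum))
  }
  colnames(out) <- c("trans_x", "trans_y", "trans_z",
                     "rot_x", "rot_y", "rot_z")
  out
}

#' Ellipsoidal brain-like mask inscribed in a grid
#'
#' @param grid_shape 3 integers.
#' @param shrink fraction of the half-extent used as ellipsoid semi-axes.
#' @return logical 3D array.
#' @export
make_ellipsoid_mask <- function(grid_shape, shrink = 0.95) {
  ctr <- (grid_shape + 1) / 2
  semi <- pmax((grid_shape - 1) / 2 * shrink, 0.5)
  idx <- as.matrix(expand.grid(x = seq_len(grid_shape[1]),
                               y = seq_len(grid_shape[2]),
                               z = seq_len(grid_shape[3])))
  v <- rowSums(sweep(sweep(idx, 2, ctr), 2, semi, "/")^2) <= 1
  array(v, grid_shape)
}

hub_member_indices <- function(center, radius, grid_shape, brain_mask = NULL) {
  idx <- as.matrix(expand.grid(x = seq_len(grid_shape[1]),
                               y = seq_len(grid_shape[2]),
                               z = seq_len(grid_shape[3])))
  inside <- rowSums(sweep(idx, 2, center)^2) <= radius^2
  lin <- which(inside)
  if (!is.null(brain_mask)) lin <- lin[brain_mask[lin]]
  lin
}

#' Generate one subject's synthetic BOLD series with connectivity hubs
#'
#' Background voxels are independent unit-variance Gaussian noise on a
#' constant baseline; each hub's member voxels share a latent signal scaled
#' by the hub strength for the subject's cell (time course
#' `baseline + s * latent + N(0, 1)`), so member pairs correlate at
#' `s^2 / (s^2 + 1)` in expectation.
#'
#' @param cohort a [cohort_spec()].
#' @param hubs hub list as in [effect_spec()].
#' @param diagnosis,genotype the subject's cell (selects the hub strength).
#' @param brain_mask logical 3D array; hub members outside it are dropped and
#'   out-of-mask voxels get baseline-level noise as well.
#' @param baseline constant intensity offset (keeps the signal criterion
#'   meaningful; default 1000).
#' @return a [bold_series()].
#' @export
generate_bold <- function(cohort, hubs, diagnosis, genotype,
                          brain_mask = NULL, baseline = 1000) {
  dims <- cohort$grid_shape
  nt <- cohort$n_volumes
  V <- prod(dims)
  M <- matrix(stats::rnorm(V * nt), V, nt)
  for (h in hubs) {
    s <- h$strength
    if (is.matrix(s)) {
      s <- s[match(diagnosis, c("CN", "MCI")),
             match(genotype, c("e2+", "e3e3", "e4+"))]
    }
    members <- hub_member_indices(h$center, h$radius, dims, brain_mask)
    if (length(members) == 0) {
      stop("hub centred at (", paste(h$center, collapse = ", "),
           ") has no member voxels inside the mask")
    }
    if (s > 0) {
      latent <- stats::rnorm(nt)
      M[members, ] <- M[members, , drop = FALSE] +
        rep(latent * s, each = length(members))
    }
  }
  bold_series(array(M + baseline, c(dims, nt)),
              affine = make_affine(cohort$voxel_mm, dim = dims),
              tr_seconds = cohort$tr_seconds)
}

#' Generate a full synthetic cohort
#'
#' Phenotype table, one BOLD series and one motion trace per subject, plus
#' the gray-matter mask the series were generated in. All draws descend from
#' a single seed, so identical (specs, seed) give identical cohorts.
#'
#' @param cohort a [cohort_spec()].
#' @param effects an [effect_spec()].
#' @param seed integer seed.
#' @param motion_amplitude_mm per-step translation SD for the motion traces;
#'   may be a vector (one value per subject) to plant QC violations.
#' @param n_poor_signal number of subjects flagged `poor_signal` (their
#'   series are generated with near-zero intensity, emulating signal-loss
#'   exclusions).
#' @param make_bold set `FALSE` to skip the (expensive) image generation and
#'   return phenotypes and motion only.
#' @return list with `phenotypes` (including `mean_fd` and `poor_signal`),
#'   `bold` (list of [bold_series()] or `NULL`), `motion` (list of matrices)
#'   and `gm_mask`.
#' @export
generate_cohort <- function(cohort, effects, seed = 1L,
                            motion_amplitude_mm = 0.05,
                            n_poor_signal = 0L, make_bold = TRUE) {
  stopifnot(inherits(cohort, "cohort_spec"), inherits(effects, "effect_spec"))
  gm_mask <- make_ellipsoid_mask(cohort$grid_shape)
  for (h in effects$hub_regions) {
    lin <- h$center[1] + (h$center[2] - 1) * cohort$grid_shape[1] +
      (h$center[3] - 1) * prod(cohort$grid_shape[1:2])
    if (any(h$center < 1) || any(h$center > cohort$grid_shape) || !gm_mask[lin]) {
      stop("invalid 'hub_regions': center (",
           paste(h$center, collapse = ", "), ") is outside the brain mask")
    }
  }
  pheno <- generate_phenotypes(cohort, effects, seed = seed)
  N <- nrow(pheno)
  amp <- rep_len(motion_amplitude_mm, N)
  motion <- lapply(seq_len(N), function(i) generate_motion(cohort$n_volumes, amp[i]))
  pheno$mean_fd <- vapply(motion, function(m) compute_fd(m)$mean_fd, numeric(1))
  pheno$poor_signal <- seq_len(N) <= n_poor_signal
  bold <- NULL
  if (make_bold) {
    bold <- lapply(seq_len(N), function(i) {
      b <- generate_bold(cohort, effects$hub_regions,
                         pheno$diagnosis[i], pheno$genotype[i],
                         brain_mask = gm_mask)
      if (pheno$poor_signal[i]) b$data[] <- b$data * 1e-3
      b
    })
  }
  list(phenotypes = pheno, bold = bold, motion = motion, gm_mask = gm_mask)
}

#' Generate subject-level connectivity-density-like maps directly
#'
#' For statistical calibration at scale (familywise-error and power studies)
#' the expensive image chain is bypassed: each subject's map is smooth
#' unit-variance Gaussian noise (white noise smoothed to `fwhm_mm` and
#' re-standardized) plus per-cell mean effects in the supplied regions. This
#' carries exactly the across-subject statistical structure the voxel-wise
#' ANCOVA assumes.
#'
#' @param n_per_cell scalar or length-6 cell sizes.
#' @param grid_shape 3 integers.
#' @param fwhm_mm spatial smoothness of the subject maps in mm.
#' @param voxel_mm voxel sizes in mm.
#' @param effect_regions list of regions, each a list with `center`, `radius`
#'   and `cell_means` (2x3 matrix added to member voxels by cell).
#' @param seed integer seed.
#' @return list with `maps` (subjects x voxels matrix), `phenotypes`
#'   (factors + covariates incl. `mean_fd`), `mask` (a [qualified_mask()])
#'   and `effect_mask` (logical 3D union of the planted regions).
#' @export
generate_gfcd_cohort <- function(n_per_cell, grid_shape = c(20, 20, 20),
                                 fwhm_mm = 6, voxel_mm = c(3, 3, 3),
                                 effect_regions = list(), seed = 1L) {
  set.seed(as.integer(seed))
  g <- cell_grid()
  if (length(n_per_cell) == 1) n_per_cell <- rep(n_per_cell, 6)
  diagnosis <- rep(g$diagnosis, n_per_cell)
  genotype <- rep(g$genotype, n_per_cell)
  N <- length(diagnosis)
  V <- prod(grid_shape)
  sigma_vox <- fwhm_to_sigma(rep_len(fwhm_mm, 3)) / voxel_mm
  eff_mask <- array(FALSE, grid_shape)
  eff_field <- vector("list", length(effect_regions))
  for (k in seq_along(effect_regions)) {
    er <- effect_regions[[k]]
    members <- hub_member_indices(er$center, er$radius, grid_shape)
    eff_mask[members] <- TRUE
    eff_field[[k]] <- list(members = members, cell_means = er$cell_means)
  }
  maps <- matrix(0, N, V)
  for (i in seq_len(N)) {
    f <- array(stats::rnorm(V), grid_shape)
    if (any(sigma_vox > 0)) f <- smooth_gaussian(f, sigma_vox)
    f <- f / stats::sd(as.vector(f))
    for (ef in eff_field) {
      mu <- ef$cell_means[match(diagnosis[i], c("CN", "MCI")),
                          match(genotype[i], c("e2+", "e3e3", "e4+"))]
      f[ef$members] <- f[ef$members] + mu
    }
    maps[i, ] <- as.vector(f)
  }
  pheno <- data.frame(
    subject_id = sprintf("sub-%03d", seq_len(N)),
    diagnosis = diagnosis, genotype = genotype,
    age = stats::rnorm(N, 73, 6),
    sex = ifelse(stats::rbinom(N, 1, 0.5) == 1, "M", "F"),
    education = stats::rnorm(N, 16, 2.5),
    mean_fd = abs(stats::rnorm(N, 0.15, 0.05)),
    stringsAsFactors = FALSE)
  mask <- qualified_mask(array(TRUE, grid_shape),
                         provenance = list(kind = "synthetic full-grid mask"))
  list(maps = maps, phenotypes = pheno, mask = mask, effect_mask = eff_mask,
       voxel_mm = voxel_mm, grid_shape = grid_shape)
}

#' Simulate data from a known simple-mediation model
#'
#' `X ~ N(0,1)` (or supplied), `M = a X + e1`, `Y = c' X + b M + e2` with
#' unit-variance noises: the generating equations of the mediation module's
#' recovery and coverage checks.
#'
#' @param n sample size.
#' @param a,b,c_prime true path coefficients.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param x optional independent-variable vector (e.g. genotype codes).
#' @return data frame with columns `x`, `m`, `y`.
#' @export
simulate_mediation_data <- function(n, a = 0.5, b = 0.5, c_prime = 0,
                                    seed = NULL, x = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(x)) x <- stats::rnorm(n)
  m <- a * x + stats::rnorm(n)
  y <- c_prime * x + b * m + stats::rnorm(n)
  data.frame(x = x, m = m, y = y)
}
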