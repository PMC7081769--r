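test_that("voxel-wise Type-III F matches the normal-equations oracle and car::Anova", {
  set.seed(31)
  for (rep in 1:5) {
    ph <- noise_pheno(n_per_cell = sample(3:6, 1), seed = rep)
    design <- build_design(ph)
    dims <- c(3, 2, 2); V <- prod(dims)
    Y <- matrix(rnorm(nrow(ph) * V), nrow(ph), V)
    maps <- lapply(seq_len(nrow(ph)), function(i) {
      gfcd_map(array(Y[i, ], dims), "smoothed", 0.6, full_mask(dims))
    })
    fm <- fit_voxelwise_ancova(maps, design, full_mask(dims))
    for (v in c(1, V %/% 2, V)) {
      oracle <- brute_force_ancova_F(design$X, design$cols, Y[, v])
      ijk <- arrayInd(v, dims)
      for (eff in names(oracle)) {
        expect_equal(fm$F[[eff]][ijk], oracle[[eff]], tolerance = 1e-8)
      }
    }
  }
  # cross-check one voxel against car's Type-III table
  ph <- noise_pheno(5, seed = 99)
  a <- scalar_ancova(ph, "y", covariates = c("age", "sex", "education"))
  d <- transform(ph, diagnosis = factor(diagnosis, c("CN", "MCI")),
                 genotype = factor(genotype, c("e2+", "e3e3", "e4+")),
                 sexn = as.numeric(sex == "M"))
  fit <- lm(y ~ diagnosis * genotype + age + sexn + education, data = d,
            contrasts = list(diagnosis = "contr.sum", genotype = "contr.sum"))
  ca <- car::Anova(fit, type = 3)
  expect_equal(unname(a$F),
               ca[c("diagnosis", "genotype", "diagnosis:genotype"), "F value"],
               tolerance = 1e-10)
})

test_that("degenerate constant voxels are excluded and reported", {
  ph <- noise_pheno(3, seed = 7)
  dims <- c(2, 2, 1)
  Y <- matrix(rnorm(nrow(ph) * 4), nrow(ph), 4)
  Y[, 3] <- 0
  maps <- lapply(seq_len(nrow(ph)), function(i) {
    gfcd_map(array(Y[i, ], dims), "smoothed", 0.6, full_mask(dims))
  })
  fm <- fit_voxelwise_ancova(maps, build_design(ph), full_mask(dims))
  expect_equal(fm$excluded_voxels, 3L)
  expect_true(is.na(fm$F$diagnosis[arrayInd(3, dims)]))
  expect_false(fm$analysis_mask[arrayInd(3, dims)])
})

test_that("empty cells and rank problems are rejected with context", {
  ph <- noise_pheno(3, seed = 1)
  ph2 <- ph[!(ph$diagnosis == "MCI" & ph$genotype == "e2+"), ]
  expect_error(build_design(ph2), "MCI.*e2\\+|e2\\+.*MCI")
  ph3 <- ph; ph3$genotype <- "unknown"
  expect_error(build_design(ph3), "level sets")
})

test_that("smoothness estimation recovers known field smoothness", {
  set.seed(41)
  dims <- c(30, 30, 30)
  mask <- full_mask(dims)
  # white noise: estimate collapses toward (well under) 1.2 voxels
  Rw <- matrix(rnorm(8 * prod(dims)), 8)
  fw <- estimate_smoothness(Rw, mask, voxel_mm = c(3, 3, 3))
  expect_true(all(fw <= 1.2 * 3))
  # fields smoothed to 6 mm FWHM: estimate within 15%
  sigma_vox <- rep(6 / (2 * sqrt(2 * log(2))) / 3, 3)
  Rs <- t(vapply(1:8, function(i) {
    f <- smooth_gaussian(array(rnorm(prod(dims)), dims), sigma_vox)
    as.vector(f)
  }, numeric(prod(dims))))
  fs <- estimate_smoothness(Rs, mask, voxel_mm = c(3, 3, 3))
  expect_true(all(abs(fs - 6) / 6 < 0.15))
  # constant residual maps are degenerate
  expect_error(estimate_smoothness(matrix(1, 4, prod(dims)), mask),
               "constant|zero")
})

test_that("extent threshold: unsmoothed tiny-p nulls need only single voxels; smoothing raises k_min", {
  mask <- qualified_mask(array(TRUE, c(12, 12, 12)))
  et0 <- monte_carlo_extent_threshold(mask, fwhm_mm = 0, voxel_p = 1e-6,
                                      alpha = 0.05, n_iter = 200, seed = 8)
  expect_equal(et0$k_min, 1L)
  etA <- monte_carlo_extent_threshold(mask, fwhm_mm = 0, voxel_p = 0.005,
                                      alpha = 0.05, n_iter = 300, seed = 9)
  etB <- monte_carlo_extent_threshold(mask, fwhm_mm = 6, voxel_p = 0.005,
                                      alpha = 0.05, n_iter = 300, seed = 9)
  expect_gte(etB$k_min, etA$k_min)
  expect_error(monte_carlo_extent_threshold(mask, 6, alpha = 1e-4,
                                            n_iter = 200, seed = 1),
               "unresolvable")
  expect_identical(
    etA$k_min,
    monte_carlo_extent_threshold(mask, 0, 0.005, 0.05, 300, seed = 9)$k_min)
})

test_that("extent threshold agrees with an independently coded null simulation", {
  dims <- c(20, 20, 20)
  mask <- qualified_mask(array(TRUE, dims))
  pkg <- monte_carlo_extent_threshold(mask, fwhm_mm = 6, voxel_p = 0.005,
                                      alpha = 0.05, n_iter = 1000, seed = 101)
  # reference: FFT-based circular convolution + stack flood fill, coded
  # independently of the package's separable operator and igraph labelling
  sigma <- 6 / (2 * sqrt(2 * log(2))) / 3
  kern1 <- function(n) {
    x <- c(0:(n / 2), -((n / 2 - 1):1))
    k <- exp(-x^2 / (2 * sigma^2)); k / sum(k)
  }
  kx <- fft(kern1(20))
  K <- outer(outer(kx, kx), kx)
  zthr <- qnorm(1 - 0.005 / 2)
  nbr <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nbr <- nbr[rowSums(abs(nbr)) > 0, ]
  max_clust <- function(above) {
    lin <- which(above)
    if (!length(lin)) return(0L)
    seen <- array(FALSE, dims)
    best <- 0L
    for (v in lin) {
      if (seen[v]) next
      stack <- v; seen[v] <- TRUE; size <- 0L
      while (length(stack)) {
        cur <- stack[length(stack)]; stack <- stack[-length(stack)]
        size <- size + 1L
        cc <- arrayInd(cur, dims)
        nb <- sweep(nbr, 2, cc, "+")
        ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 &
          nb[, 2] <= dims[2] & nb[, 3] >= 1 & nb[, 3] <= dims[3]
        nl <- nb[ok, 1] + (nb[ok, 2] - 1) * dims[1] +
          (nb[ok, 3] - 1) * dims[1] * dims[2]
        new <- nl[above[nl] & !seen[nl]]
        seen[new] <- TRUE
        stack <- c(stack, new)
      }
      best <- max(best, size)
    }
    best
  }
  set.seed(202)  # deliberately a different stream from the package run
  maxes <- integer(1000)
  for (i in 1:1000) {
    f <- Re(fft(fft(array(rnorm(8000), dims)) * K, inverse = TRUE)) / 8000
    f <- f / sd(f)
    maxes[i] <- max_clust(abs(f) > zthr)
  }
  ks <- seq_len(max(maxes) + 1L)
  ref_k <- ks[which(vapply(ks, function(k) mean(maxes >= k), numeric(1)) <= 0.05)[1]]
  expect_lte(abs(pkg$k_min - ref_k), 2)
})

test_that("cluster formation honours connectivity and extent rules", {
  dims <- c(10, 10, 10)
  p1 <- array(1, dims)
  expect_equal(nrow(form_clusters(p1, 0.005, 1)$table), 0)
  p1[4, 5, 6] <- 1e-4
  cr <- form_clusters(p1, 0.005, 1)
  expect_equal(cr$table$n_voxels, 1)
  expect_equal(cr$table$size_mm3, 27)
  p2 <- array(1, dims); p2[2:4, 2:4, 2:4] <- 1e-3
  cr2 <- form_clusters(p2, 0.005, k_min = 27, connectivity = 26)
  expect_equal(nrow(cr2$table), 1)
  expect_equal(cr2$table$n_voxels, 27)
  expect_equal(nrow(form_clusters(p2, 0.005, k_min = 28)$table), 0)
  # diagonal pair: joined under 26-connectivity, split under 6-connectivity
  p3 <- array(1, dims); p3[5, 5, 5] <- 1e-3; p3[6, 6, 6] <- 1e-3
  expect_equal(nrow(form_clusters(p3, 0.005, 1, connectivity = 26)$table), 1)
  expect_equal(nrow(form_clusters(p3, 0.005, 1, connectivity = 6)$table), 2)
  # peak location via the statistic map
  stat <- array(0, dims); stat[3, 3, 3] <- 9
  cr4 <- form_clusters(p2, 0.005, 1, stat_map = stat,
                       affine = make_affine(c(3, 3, 3), dim = dims))
  expect_equal(cr4$table$peak_stat, 9)
  expect_equal(unlist(cr4$table[c("peak_x", "peak_y", "peak_z")]),
               c(peak_x = (3 - 1) * 3 - (10 - 1) / 2 * 3,
                 peak_y = (3 - 1) * 3 - (10 - 1) / 2 * 3,
                 peak_z = (3 - 1) * 3 - (10 - 1) / 2 * 3))
})

test_that("cluster means average exactly within each cluster", {
  dims <- c(4, 4, 2)
  p <- array(1, dims); p[1, 1, 1] <- 1e-4; p[3:4, 1, 1] <- 1e-4
  cr <- form_clusters(p, 0.005, 1, connectivity = 6)
  expect_equal(nrow(cr$table), 2)
  m1 <- array(5, dims)
  m2 <- array(0, dims); m2[3, 1, 1] <- 1; m2[4, 1, 1] <- 3
  means <- extract_cluster_means(list(m1, m2), cr)
  expect_equal(dim(means), c(2L, 2L))
  expect_true(all(means[1, ] == 5))
  two_vox_cluster <- which(cr$table$n_voxels == 2)
  expect_equal(unname(means[2, two_vox_cluster]), 2)
  expect_error(extract_cluster_means(list(array(0, c(3, 3, 3))), cr),
               "grid")
})

test_that("parametric diagnosis p values agree with label permutation", {
  set.seed(71)
  n_per_cell <- 6
  ph <- noise_pheno(n_per_cell, seed = 71)
  design <- build_design(ph)
  V <- 20
  Y <- matrix(rnorm(nrow(ph) * V), nrow(ph), V)
  core <- gfcdkit:::ancova_core(Y, design)
  obs_F <- core$F["diagnosis", ]
  n_perm <- 1000
  exceed <- matrix(0, n_perm, V)
  ph_p <- ph
  for (b in seq_len(n_perm)) {
    ph_p$diagnosis <- sample(ph$diagnosis)
    dsn <- build_design(ph_p)
    exceed[b, ] <- gfcdkit:::ancova_core(Y, dsn)$F["diagnosis", ] >= obs_F
  }
  perm_p <- colMeans(exceed)
  para_p <- core$p["diagnosis", ]
  expect_lt(max(abs(perm_p - para_p)), 0.06)
  expect_lt(mean(abs(perm_p - para_p)), 0.02)
})
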