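test_that("cohort layout and determinism of the generator", {
  sp <- cohort_spec(n_per_cell = 3, n_volumes = 30, grid_shape = c(6, 6, 4))
  ref <- reference_phenotype_effects()
  eff <- effect_spec(cell_means = ref$cell_means["MMSE"],
                     noise_sd = ref$noise_sd,
                     hub_regions = list(list(center = c(3, 3, 2), radius = 1,
                                             strength = 1.5)))
  a <- generate_cohort(sp, eff, seed = 10)
  expect_equal(nrow(a$phenotypes), 18)
  expect_equal(nrow(unique(a$phenotypes[c("diagnosis", "genotype")])), 6)
  expect_equal(length(a$bold), 18)
  expect_equal(dim(a$bold[[1]]$data), c(6, 6, 4, 30))
  expect_equal(nrow(a$motion[[1]]), 30)

  b <- generate_cohort(sp, eff, seed = 10)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$bold[[5]]$data, b$bold[[5]]$data)
  expect_identical(a$motion, b$motion)
  c_ <- generate_cohort(sp, eff, seed = 11)
  expect_false(identical(a$phenotypes$MMSE, c_$phenotypes$MMSE))
})

test_that("unbalanced reference cell sizes reproduce the cohort bookkeeping", {
  sizes <- reference_cell_sizes()
  expect_equal(sum(sizes), 177)
  expect_equal(sum(sizes[grepl("^MCI", names(sizes))]), 101)
  expect_equal(unname(sizes[c("MCI_e2+", "MCI_e3e3", "MCI_e4+")]),
               c(13L, 46L, 42L))
})

test_that("hub members correlate at s^2/(s^2+1) and null hubs stay null", {
  sp <- cohort_spec(n_per_cell = 2, n_volumes = 500, grid_shape = c(8, 8, 6))
  s <- 1.2
  eff <- effect_spec(hub_regions = list(list(center = c(4, 4, 3), radius = 2,
                                             strength = s)))
  set.seed(20)
  b <- generate_bold(sp, eff$hub_regions, "CN", "e3e3")
  members <- which(array(FALSE, sp$grid_shape) |
                     (function(a) { a <- array(FALSE, sp$grid_shape)
                       idx <- as.matrix(expand.grid(1:8, 1:8, 1:6))
                       a[rowSums(sweep(idx, 2, c(4, 4, 3))^2) <= 4] <- TRUE; a })(0))
  M <- matrix(b$data, prod(sp$grid_shape), sp$n_volumes)[members, ]
  cors <- cor(t(M))
  mean_cor <- mean(cors[upper.tri(cors)])
  expect_lt(abs(mean_cor - s^2 / (s^2 + 1)), 0.05)

  # strength zero: no suprathreshold correlations anywhere
  eff0 <- effect_spec(hub_regions = list(list(center = c(4, 4, 3), radius = 2,
                                              strength = 0)))
  b0 <- generate_bold(sp, eff0$hub_regions, "CN", "e3e3")
  g0 <- compute_gfcd(bold_series(b0$data, b0$affine, 3), full_mask(sp$grid_shape))
  expect_equal(sum(g0$data), 0)
})

test_that("motion traces: shape, zero amplitude, determinism", {
  m <- generate_motion(140, 0.05, seed = 2)
  expect_equal(dim(m), c(140L, 6L))
  expect_identical(m, generate_motion(140, 0.05, seed = 2))
  z <- generate_motion(25, 0, seed = 1)
  expect_true(all(z == 0))
  expect_equal(compute_fd(z)$mean_fd, 0)
  expect_error(generate_motion(1, 0.05), "at least 2")
  expect_error(generate_motion(10, -1), "non-negative")
})

test_that("invalid specifications are rejected naming the offending field", {
  expect_error(cohort_spec(n_per_cell = 1), "n_per_cell")
  expect_error(cohort_spec(n_volumes = 10), "n_volumes")
  expect_error(cohort_spec(grid_shape = c(100, 100, 100)), "grid_shape")
  expect_error(effect_spec(noise_sd = c(MMSE = -1)), "noise_sd")
  expect_error(effect_spec(cell_means = list(MMSE = matrix(0, 2, 3)),
                           noise_sd = numeric()), "noise_sd")
  expect_error(effect_spec(hub_regions = list(list(center = c(1, 1, 1),
                                                   radius = 0.5,
                                                   strength = 1))),
               "radius")
  sp <- cohort_spec(n_per_cell = 2, n_volumes = 20, grid_shape = c(6, 6, 4))
  eff <- effect_spec(hub_regions = list(list(center = c(1, 1, 1), radius = 1,
                                             strength = 1)))
  expect_error(generate_cohort(sp, eff, seed = 1), "outside the brain mask")
})

test_that("planted mediation paths are recovered by ordinary least squares", {
  sp <- cohort_spec(n_per_cell = 850, n_volumes = 20, grid_shape = c(4, 4, 2))
  eff <- effect_spec(mediation_paths = list(a = 0.5, b = 0.5, c_prime = 0))
  ph <- generate_phenotypes(sp, eff, seed = 33)  # n = 5100
  x <- c(1, 2, 3)[match(ph$genotype, c("e2+", "e3e3", "e4+"))]
  a_hat <- coef(lm(ph$planted_mediator ~ x))[["x"]]
  b_hat <- coef(lm(ph$planted_outcome ~ x + ph$planted_mediator))[[3]]
  expect_lt(abs(a_hat - 0.5), 0.05)
  expect_lt(abs(b_hat - 0.5), 0.05)
})

test_that("direct map generator plants cell effects with unit-variance smooth noise", {
  coh <- generate_gfcd_cohort(3, grid_shape = c(10, 10, 8), fwhm_mm = 6,
                              effect_regions = list(list(
                                center = c(5, 5, 4), radius = 2,
                                cell_means = matrix(c(0, 0, 0, 0, 0, 3), 2, 3))),
                              seed = 4)
  expect_equal(dim(coh$maps), c(18L, 800L))
  expect_equal(sort(unique(coh$phenotypes$diagnosis)), c("CN", "MCI"))
  sds <- apply(coh$maps, 1, sd)
  expect_true(all(abs(sds - 1) < 0.2))
  # the (MCI, e4+) subjects carry the planted shift inside the region
  sel <- coh$phenotypes$diagnosis == "MCI" & coh$phenotypes$genotype == "e4+"
  inside <- which(coh$effect_mask)
  expect_gt(mean(coh$maps[sel, inside]) - mean(coh$maps[!sel, inside]), 2)
  expect_identical(coh$maps,
                   generate_gfcd_cohort(3, grid_shape = c(10, 10, 8),
                                        fwhm_mm = 6,
                                        effect_regions = list(list(
                                          center = c(5, 5, 4), radius = 2,
                                          cell_means = matrix(c(0, 0, 0, 0, 0, 3), 2, 3))),
                                        seed = 4)$maps)
})
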