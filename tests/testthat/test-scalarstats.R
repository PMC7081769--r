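test_that("scalar ANCOVA equals the voxel-wise fit on a one-voxel image", {
  ph <- noise_pheno(4, seed = 12)
  a <- scalar_ancova(ph, "y", covariates = c("age", "sex", "education", "mean_fd"))
  dims <- c(1, 1, 1)
  maps <- lapply(ph$y, function(v) gfcd_map(array(v, dims), "smoothed", 0.6,
                                            full_mask(dims)))
  fm <- fit_voxelwise_ancova(maps, build_design(ph), full_mask(dims))
  for (eff in names(a$F)) {
    expect_identical(a$F[[eff]], fm$F[[eff]][1, 1, 1])
  }
})

test_that("balanced two-way ANOVA without covariates matches textbook cell-mean formulas", {
  set.seed(14)
  n <- 4
  ph <- noise_pheno(n, seed = 14)
  ph$y <- rnorm(nrow(ph), 10, 2)
  a <- scalar_ancova(ph, "y", covariates = character(0))
  # textbook balanced two-way ANOVA from cell summaries
  cm <- tapply(ph$y, list(ph$diagnosis, ph$genotype), mean)
  grand <- mean(ph$y)
  ss_a <- 3 * n * sum((rowMeans(cm) - grand)^2)
  ss_b <- 2 * n * sum((colMeans(cm) - grand)^2)
  ss_ab <- n * sum((cm - outer(rowMeans(cm), colMeans(cm), "+") + grand)^2)
  ss_e <- sum((ph$y - cm[cbind(ph$diagnosis, ph$genotype)])^2)
  df_e <- nrow(ph) - 6
  expect_equal(a$F[["diagnosis"]], (ss_a / 1) / (ss_e / df_e), tolerance = 1e-10)
  expect_equal(a$F[["genotype"]], (ss_b / 2) / (ss_e / df_e), tolerance = 1e-10)
  expect_equal(a$F[["interaction"]], (ss_ab / 2) / (ss_e / df_e), tolerance = 1e-10)
  expect_equal(unname(a$adjusted_means), unname(cm), tolerance = 1e-10)
})

test_that("null outcomes reject at the nominal rate; pure diagnosis shifts leave the interaction null", {
  set.seed(15)
  reject <- interF <- numeric(400)
  for (i in 1:400) {
    ph <- noise_pheno(4, seed = 1500 + i)
    a <- scalar_ancova(ph, "y", covariates = c("age", "education"))
    reject[i] <- a$p[["genotype"]] < 0.05
    ph$y2 <- ph$y + 2 * (ph$diagnosis == "MCI")
    interF[i] <- scalar_ancova(ph, "y2", covariates = character(0))$F[["interaction"]]
  }
  expect_gt(mean(reject), 0.02)
  expect_lt(mean(reject), 0.09)
  # central F with df1 = 2 has mean df2/(df2-2) ~ 1.1 at df2 = 18
  expect_gt(mean(interF), 0.85)
  expect_lt(mean(interF), 1.35)
})

test_that("constant outcomes and missing columns are rejected", {
  ph <- noise_pheno(3, seed = 2)
  ph$const <- 5
  expect_error(scalar_ancova(ph, "const"), "constant")
  expect_error(scalar_ancova(ph, "nope"), "not found")
})

test_that("demographic tests: Kruskal-Wallis nulls, separations, ties and the sex chi-square", {
  set.seed(16)
  ph <- noise_pheno(10, seed = 16)
  out <- demographics_tests(ph, c("age", "sex", "education"))
  expect_equal(out$test, c("kruskal-wallis", "chi-square", "kruskal-wallis"))
  expect_true(all(out$p > 0 & out$p <= 1))
  # a 10-SD shifted group separates decisively
  ph$shift <- rnorm(nrow(ph))
  ph$shift[ph$diagnosis == "MCI" & ph$genotype == "e4+"] <-
    ph$shift[ph$diagnosis == "MCI" & ph$genotype == "e4+"] + 10
  expect_lt(demographics_tests(ph, "shift")$p, 0.001)
  # identical values in every group: H = 0 exactly (full rank ties across groups)
  x <- rep(c(1, 2, 3, 4, 5), 12)
  expect_equal(unname(kruskal.test(x, interaction(ph$diagnosis, ph$genotype))$statistic), 0)
  ph$tied <- 3
  expect_error(demographics_tests(ph, "tied"), "tied")
})

test_that("null demographics stay non-significant at close to the nominal rate", {
  set.seed(17)
  p <- vapply(1:300, function(i) {
    ph <- noise_pheno(4, seed = 4000 + i)
    demographics_tests(ph, "age")$p
  }, numeric(1))
  expect_gte(mean(p > 0.05), 0.90)
})

test_that("post hoc genotype contrasts behave under null and planted effects", {
  set.seed(18)
  # balance + centred orthogonal covariate: adjusted means equal raw means
  ph <- noise_pheno(6, seed = 18)
  ph$cov0 <- rep(c(-1, 1), 18)  # centred, orthogonal to the cells by balance
  res <- post_hoc_genotype(ph, "y", covariates = "cov0")
  raw <- tapply(ph$y, factor(ph$genotype, c("e2+", "e3e3", "e4+")), mean)
  expect_equal(res$emmeans$emmean, as.vector(raw), tolerance = 1e-10)

  # planted protective-allele advantage of 1 SD, n = 30/cell
  hits <- vapply(1:20, function(i) {
    ph <- noise_pheno(30, seed = 5000 + i)
    ph$y <- ph$y + (ph$genotype == "e2+")
    r <- post_hoc_genotype(ph, "y", covariates = c("age", "education"))
    pr <- r$pairs
    pr$p.value[pr$contrast == "(e2+) - e3e3"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)

  # null: pairwise p rarely significant
  nullp <- vapply(1:40, function(i) {
    ph <- noise_pheno(8, seed = 6000 + i)
    min(post_hoc_genotype(ph, "y", covariates = character(0))$pairs$p.value)
  }, numeric(1))
  expect_gte(mean(nullp > 0.05), 0.75)
})

test_that("cohort tables summarize every cell with factorial p values", {
  ph <- noise_pheno(5, seed = 19)
  tb <- cohort_table(ph, c("y"), covariates = c("age"))
  expect_equal(nrow(tb), 1)
  expect_equal(ncol(tb), 1 + 6 + 3)
  expect_match(tb$CN_e3e3, "±")
})
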