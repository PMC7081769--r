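test_that("initial-volume discard trims frames and nothing else", {
  dims <- c(4, 4, 3)
  M <- matrix(rnorm(prod(dims) * 140), prod(dims), 140)
  s <- series_from_matrix(M, dims)
  trimmed <- discard_initial(s, 10)
  expect_equal(dim(trimmed$data)[4], 130)
  expect_equal(dim(trimmed$data)[1:3], dims)
  expect_equal(trimmed$data[, , , 1], s$data[, , , 11])
  expect_identical(discard_initial(s, 0), s)

  short <- series_from_matrix(M[, 1:11], dims)
  expect_equal(dim(discard_initial(short, 10)$data)[4], 1)
  expect_error(discard_initial(short, 11), "cannot discard")
  expect_error(discard_initial(short, 12), "cannot discard")
})

test_that("framewise displacement follows the translation + arc-length formula", {
  zero <- matrix(0, 20, 6)
  fd0 <- compute_fd(zero)
  expect_equal(fd0$fd, rep(0, 20))
  expect_equal(fd0$mean_fd, 0)

  step <- matrix(0, 5, 6)
  step[3:5, 1] <- 0.1    # +0.1 mm translation from frame 3 on
  step[3:5, 4] <- 0.01   # +0.01 rad rotation from frame 3 on
  fd <- compute_fd(step, sphere_radius_mm = 50)
  expect_equal(fd$fd[3], 0.1 + 50 * 0.01)  # = 0.6 mm
  expect_equal(fd$fd[c(1, 2, 4, 5)], rep(0, 4))

  set.seed(4)
  m <- matrix(rnorm(60), 10, 6)
  expect_equal(compute_fd(-m)$fd, compute_fd(m)$fd)
  # adding a constant offset to one parameter's whole column changes nothing
  m2 <- m; m2[, 5] <- m2[, 5] + 1.3
  expect_equal(compute_fd(m2)$fd, compute_fd(m)$fd)

  expect_error(compute_fd(m[1, , drop = FALSE]), "at least 2 frames")
})

test_that("detrend/band-pass keeps in-band tones, kills ramps and out-of-band power", {
  n <- 120; tr <- 3
  t_s <- (seq_len(n) - 1) * tr
  dims <- c(2, 2, 1)
  tone_in <- sin(2 * pi * 0.05 * t_s)    # 0.05 Hz = bin 18 of 120 at TR 3
  ramp <- seq_len(n) * 0.7 + 5
  tone_out <- sin(2 * pi * 0.2 * t_s)    # 0.2 Hz, above the 0.1 Hz edge
  M <- rbind(tone_in, ramp, tone_out, tone_in + ramp)
  s <- series_from_matrix(M, dims, tr = tr)
  f <- detrend_and_bandpass(s)
  out <- matrix(f$data, prod(dims), n)
  # in-band tone survives up to the overlap with the removed drift direction
  # (a mid-band tone shares ~11% of its norm with the in-band part of the
  # centred ramp; annihilating ramps exactly costs exactly that overlap)
  expect_lt(sqrt(mean((out[1, ] - tone_in)^2)) / sqrt(mean(tone_in^2)), 0.12)
  # pure linear ramp is annihilated
  expect_lt(max(abs(out[2, ])), 1e-8)
  # out-of-band tone: residual power below 1% of input power (DFT oracle)
  pow <- function(x) sum(Mod(fft(x))^2)
  expect_lt(pow(out[3, ]) / pow(tone_out), 0.01)
  # zero temporal mean everywhere
  expect_lt(max(abs(rowMeans(out))), 1e-10)
})

test_that("the band-pass projection is exactly idempotent", {
  set.seed(9)
  dims <- c(3, 2, 2)
  s <- series_from_matrix(matrix(rnorm(prod(dims) * 90), prod(dims), 90), dims)
  once <- detrend_and_bandpass(s)
  twice <- detrend_and_bandpass(once)
  expect_lt(max(abs(twice$data - once$data)) / max(abs(once$data)), 1e-8)
})

test_that("band edges outside the Nyquist range are rejected", {
  dims <- c(2, 2, 1)
  s <- series_from_matrix(matrix(rnorm(40 * 4), 4, 40), dims, tr = 3)
  expect_error(detrend_and_bandpass(s, 0.01, 0.3), "Nyquist")
  expect_error(detrend_and_bandpass(s, 0.1, 0.05), "Nyquist|band")
})

test_that("nuisance regression matches the explicit normal-equations solve", {
  set.seed(21)
  n <- 60; dims <- c(3, 3, 2); V <- prod(dims)
  reg <- cbind(rnorm(n), rnorm(n), rnorm(n))
  M <- matrix(rnorm(V * n), V, n)
  M[1, ] <- reg[, 2]  # a voxel equal to a regressor
  s <- series_from_matrix(M, dims)
  out <- nuisance_regress(s, reg)
  res <- matrix(out$data, V, n)
  expect_lt(max(abs(res[1, ])), 1e-10)
  # oracle: residuals from (X'X)^{-1} X'y per voxel
  X <- cbind(1, reg)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  oracle <- M %*% (diag(n) - H)
  expect_lt(max(abs(res - oracle)), 1e-8)
  # residuals orthogonal to every regressor column
  expect_lt(max(abs(res %*% reg)) / max(abs(M)), 1e-8)

  # all-zero regressors + intercept = demeaning
  out0 <- nuisance_regress(s, matrix(0, n, 2))
  expect_equal(matrix(out0$data, V, n), M - rowMeans(M), ignore_attr = TRUE)
})

test_that("rank-deficient nuisance designs are rejected with the offending column", {
  set.seed(2)
  n <- 30; dims <- c(2, 2, 1)
  s <- series_from_matrix(matrix(rnorm(4 * n), 4, n), dims)
  reg <- cbind(a = rnorm(n), b = rnorm(n))
  reg <- cbind(reg, c = reg[, "a"] + reg[, "b"])
  expect_error(nuisance_regress(s, reg), "collinear")
})

test_that("tissue-signal extraction averages exactly over the mask", {
  dims <- c(3, 3, 2); V <- prod(dims); n <- 15
  M <- matrix(rnorm(V * n), V, n)
  s <- series_from_matrix(M, dims)
  m1 <- array(FALSE, dims); m1[2, 2, 1] <- TRUE
  lin <- which(m1)
  expect_equal(extract_tissue_signal(s, m1), M[lin, ])
  m2 <- array(FALSE, dims); m2[c(1, 5)] <- TRUE
  expect_equal(extract_tissue_signal(s, m2), colMeans(M[c(1, 5), ]))
  const <- series_from_matrix(matrix(7, V, n), dims)
  expect_equal(extract_tissue_signal(const, m2), rep(7, n))
  expect_error(extract_tissue_signal(s, array(FALSE, dims)), "empty")
})
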