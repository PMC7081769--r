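#' Simple mediation with bias-corrected bootstrap confidence interval
#'
#' Single-mediator (Model-4 style) decomposition of an X -> Y effect into a
#' direct path and an indirect path through M, estimated by three ordinary
#' least-squares regressions with shared covariates:
#' \itemize{
#'   \item `M ~ X + covariates` gives path `a`,
#'   \item `Y ~ X + M + covariates` gives paths `b` and the direct effect `c'`,
#'   \item `Y ~ X + covariates` gives the total effect `c`.
#' }
#' The identity `c = c' + a*b` holds exactly for these fits. Inference on the
#' indirect effect `a*b` uses case resampling of whole subject rows with a
#' bias-corrected (z0-adjusted) percentile interval; the effect is flagged
#' significant when the interval excludes zero.
#'
#' @param x,m,y numeric vectors of equal length (independent variable,
#'   mediator, outcome); no missing values.
#' @param covariates optional numeric matrix or data frame of covariates.
#' @param n_boot number of bootstrap resamples (>= 100; 10,000 is the
#'   conventional choice).
#' @param ci_level confidence level (default 0.95).
#' @param seed integer seed; the interval is fully determined by
#'   (data, seed, n_boot).
#' @return object of class `mediation_fit` with paths `a`, `b`, `c`,
#'   `c_prime`, `indirect`, the CI, the bootstrap draws, and a significance
#'   flag.
#' @export
fit_mediation <- function(x, m, y, covariates = NULL, n_boot = 10000L,
                          ci_level = 0.95, seed = 1L) {
  n <- length(x)
  if (length(m) != n || length(y) != n) stop("x, m, y must have equal length")
  if (anyNA(x) || anyNA(m) || anyNA(y)) stop("missing values are not allowed; filter first")
  if (n_boot < 100) stop("'n_boot' must be at least 100")
  if (!(ci_level > 0 && ci_level < 1)) stop("'ci_level' must lie in (0, 1)")
  C <- if (is.null(covariates)) matrix(nrow = n, ncol = 0) else {
    cm <- as.matrix(covariates)
    storage.mode(cm) <- "double"
    cm
  }
  if (nrow(C) != n) stop("covariate rows do not match the data length")
  if (n < ncol(C) + 4) stop("too few observations for the covariate count")
  Xm <- cbind(1, C, x)              # M-model design
  Xy <- cbind(1, C, x, m)           # Y-model design (direct + b)
  Xt <- Xm                          # total-effect design
  p_m <- ncol(Xm); p_y <- ncol(Xy)
  if (qr(Xy)$rank < p_y) {
    stop("collinear design: x, m and covariates are linearly dependent ",
         "(is the mediator a copy of x or of a covariate?)")
  }
  cf_m <- qr.coef(qr(Xm), m)
  cf_y <- qr.coef(qr(Xy), y)
  cf_t <- qr.coef(qr(Xt), y)
  a <- unname(cf_m[p_m]); b <- unname(cf_y[p_y])
  c_prime <- unname(cf_y[p_y - 1]); c_tot <- unname(cf_t[p_m])
  indirect <- a * b
  set.seed(as.integer(seed))
  boot <- numeric(n_boot)
  n_bad <- 0L
  for (i in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    fm <- .lm.fit(Xm[idx, , drop = FALSE], m[idx])
    fy <- .lm.fit(Xy[idx, , drop = FALSE], y[idx])
    if (fm$rank < p_m || fy$rank < p_y) {
      boot[i] <- NA_real_
      n_bad <- n_bad + 1L
    } else {
      boot[i] <- fm$coefficients[p_m] * fy$coefficients[p_y]
    }
  }
  bb <- boot[!is.na(boot)]
  prop_below <- mean(bb < indirect)
  prop_below <- min(max(prop_below, 1 / (length(bb) + 1)),
                    length(bb) / (length(bb) + 1))
  z0 <- stats::qnorm(prop_below)
  alpha2 <- (1 - ci_level) / 2
  probs <- stats::pnorm(2 * z0 + stats::qnorm(c(alpha2, 1 - alpha2)))
  ci <- unname(stats::quantile(bb, probs, type = 6))
  structure(list(a = a, b = b, c = c_tot, c_prime = c_prime,
                 indirect = indirect, ci_low = ci[1], ci_high = ci[2],
                 significant = ci[1] > 0 || ci[2] < 0,
                 ci_level = ci_level, n_boot = n_boot, n = n, seed = seed,
                 z0 = z0, boot = boot, n_degenerate_resamples = n_bad,
                 covariates = colnames(C) %||% character(0)),
            class = "mediation_fit")
}

#' @export
print.mediation_fit <- function(x, ...) {
  cat(sprintf("<mediation_fit> n = %d, %d bootstrap resamples\n", x$n, x$n_boot))
  cat(sprintf("  a = %.4f  b = %.4f  c' = %.4f  c = %.4f\n",
              x$a, x$b, x$c_prime, x$c))
  cat(sprintf("  indirect a*b = %.4f, %g%% BC CI [%.4f, %.4f]%s\n",
              x$indirect, 100 * x$ci_level, x$ci_low, x$ci_high,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Screen outcomes for a genotype association within each diagnosis group
#'
#' Per outcome and diagnosis group, tests the covariate-adjusted linear
#' effect of the ordinally coded genotype (1-df F test from comparing the
#' model with and without the genotype term). Used to select candidate
#' dependent variables for mediation; a non-significant screen does not bar
#' an outcome from mediation testing.
#'
#' @param pheno phenotype data frame.
#' @param outcomes outcome column names.
#' @param covariates covariates to adjust for.
#' @param coding numeric codes for genotypes e2+/e3e3/e4+ in risk order
#'   (default `c(1, 2, 3)`).
#' @return data frame with `diagnosis`, `outcome`, `F`, `p`.
#' @export
screen_gene_cognition <- function(pheno, outcomes,
                                  covariates = c("age", "sex", "education"),
                                  coding = c(1, 2, 3)) {
  xg <- genotype_code(pheno$genotype, coding)
  rows <- list()
  for (dx in unique(as.character(pheno$diagnosis))) {
    sel <- pheno$diagnosis == dx
    C <- covariate_matrix(pheno[sel, , drop = FALSE], covariates)
    X0 <- cbind(1, C)
    X1 <- cbind(X0, xg[sel])
    for (oc in outcomes) {
      yv <- pheno[[oc]][sel]
      rss0 <- sum(qr.resid(qr(X0), yv)^2)
      rss1 <- sum(qr.resid(qr(X1), yv)^2)
      df2 <- sum(sel) - ncol(X1)
      Fv <- (rss0 - rss1) / (rss1 / df2)
      rows[[length(rows) + 1L]] <- data.frame(
        diagnosis = dx, outcome = oc, F = Fv,
        p = stats::pf(Fv, 1, df2, lower.tail = FALSE))
    }
  }
  do.call(rbind, rows)
}

genotype_code <- function(genotype, coding = c(1, 2, 3)) {
  g <- factor(genotype, levels = c("e2+", "e3e3", "e4+"))
  if (anyNA(g)) stop("genotype contains values outside {e2+, e3e3, e4+}")
  coding[as.integer(g)]
}

covariate_matrix <- function(pheno, covariates) {
  if (!length(covariates)) return(matrix(nrow = nrow(pheno), ncol = 0))
  cols <- lapply(covariates, function(cv) {
    v <- pheno[[cv]]
    if (is.null(v)) stop("covariate '", cv, "' not found")
    if (cv == "sex") v <- as.numeric(v == "M" | v == 1)
    as.numeric(v)
  })
  out <- do.call(cbind, cols)
  colnames(out) <- covariates
  out
}

#' Run a battery of mediation fits within one diagnosis group
#'
#' One [fit_mediation()] per (mediator, outcome) pair with genotype as the
#' ordinally coded independent variable, restricted to the requested
#' diagnosis group (the MCI group by default, where gene-cognition
#' associations are expected).
#'
#' @param pheno phenotype data frame, optionally joined with cluster-mean
#'   columns from [extract_cluster_means()].
#' @param mediators column names of candidate mediators.
#' @param outcomes column names of candidate outcomes.
#' @param group diagnosis level to analyse (default `"MCI"`).
#' @param covariates covariates for all three regressions.
#' @param n_boot,ci_level,seed passed to [fit_mediation()]; each pair uses
#'   `seed + pair index` so the battery is reproducible yet resamples differ
#'   across pairs.
#' @param coding genotype coding (see [screen_gene_cognition()]).
#' @return list with `fits` (named list of `mediation_fit`) and `table`
#'   (one summary row per pair).
#' @export
run_mediation_battery <- function(pheno, mediators, outcomes, group = "MCI",
                                  covariates = c("age", "sex", "education"),
                                  n_boot = 10000L, ci_level = 0.95, seed = 1L,
                                  coding = c(1, 2, 3)) {
  sel <- pheno$diagnosis == group
  if (!any(sel)) stop("no subjects in diagnosis group '", group, "'")
  sub <- pheno[sel, , drop = FALSE]
  xg <- genotype_code(sub$genotype, coding)
  C <- covariate_matrix(sub, covariates)
  fits <- list()
  rows <- list()
  i <- 0L
  for (md in mediators) for (oc in outcomes) {
    i <- i + 1L
    fit <- fit_mediation(xg, sub[[md]], sub[[oc]], covariates = C,
                         n_boot = n_boot, ci_level = ci_level,
                         seed = as.integer(seed) + i)
    key <- paste(md, oc, sep = " -> ")
    fits[[key]] <- fit
    rows[[i]] <- data.frame(
      mediator = md, outcome = oc, a = fit$a, b = fit$b,
      c_prime = fit$c_prime, c = fit$c, indirect = fit$indirect,
      ci_low = fit$ci_low, ci_high = fit$ci_high,
      significant = fit$significant)
  }
  list(fits = fits, table = do.call(rbind, rows), group = group,
       n = nrow(sub))
}
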