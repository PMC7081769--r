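#' Build the 2x3 factorial design matrix with nuisance covariates
#'
#' Encodes diagnosis (CN/MCI) and genotype (e2+/e3e3/e4+) with sum-to-zero
#' contrasts, their interaction, and the requested covariates. Sex is entered
#' as a 0/1 male indicator; other covariates are taken as numeric columns of
#' the phenotype table. Type-III tests are obtained downstream by dropping
#' each term's columns from this matrix.
#'
#' @param pheno phenotype data frame with columns `diagnosis`, `genotype`,
#'   and every requested covariate.
#' @param covariates character vector of covariate column names (default
#'   `c("age", "sex", "education", "mean_fd")`, the imaging nuisance set).
#' @return list with the design matrix `X`, per-term column indices `cols`,
#'   the factor levels, and the row count.
#' @export
build_design <- function(pheno,
                         covariates = c("age", "sex", "education", "mean_fd")) {
  need <- c("diagnosis", "genotype", covariates)
  miss <- setdiff(need, names(pheno))
  if (length(miss)) stop("phenotype table lacks columns: ", paste(miss, collapse = ", "))
  diagnosis <- factor(pheno$diagnosis, levels = c("CN", "MCI"))
  genotype <- factor(pheno$genotype, levels = c("e2+", "e3e3", "e4+"))
  if (anyNA(diagnosis) || anyNA(genotype)) {
    stop("diagnosis/genotype contain values outside the allowed level sets")
  }
  tab <- table(diagnosis, genotype)
  if (any(tab == 0)) {
    empty <- which(tab == 0, arr.ind = TRUE)
    stop("empty design cell(s): ",
         paste(sprintf("(%s, %s)", rownames(tab)[empty[, 1]],
                       colnames(tab)[empty[, 2]]), collapse = ", "))
  }
  df <- data.frame(diagnosis = diagnosis, genotype = genotype)
  for (cv in covariates) {
    v <- pheno[[cv]]
    if (cv == "sex") v <- as.numeric(v == "M" | v == 1)
    if (!is.numeric(v)) stop("covariate '", cv, "' is not numeric")
    df[[cv]] <- v
  }
  form <- stats::as.formula(paste(
    c("~ diagnosis * genotype", covariates), collapse = " + "))
  X <- stats::model.matrix(form, df,
                           contrasts.arg = list(diagnosis = "contr.sum",
                                                genotype = "contr.sum"))
  asgn <- attr(X, "assign")
  labels <- attr(stats::terms(form), "term.labels")
  term_of <- c("(Intercept)", labels)[asgn + 1]
  cols <- list(
    diagnosis = which(term_of == "diagnosis"),
    genotype = which(term_of == "genotype"),
    interaction = which(term_of == "diagnosis:genotype"))
  list(X = X, cols = cols, covariates = covariates,
       diagnosis = diagnosis, genotype = genotype, n = nrow(X))
}

# Shared Type-III ANCOVA core. Y: n x V response matrix. For each factorial
# effect, F compares the full model to the model with that effect's sum-coded
# columns removed (partial / Type-III sums of squares).
ancova_core <- function(Y, design) {
  X <- design$X
  n <- nrow(X)
  if (!is.matrix(Y)) Y <- matrix(Y, n)
  if (nrow(Y) != n) stop("response rows do not match the design")
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("design matrix is rank deficient")
  df_err <- n - ncol(X)
  if (df_err < 1) stop("no residual degrees of freedom")
  res <- qr.resid(qx, Y)
  rss_full <- colSums(res^2)
  effects <- c("diagnosis", "genotype", "interaction")
  Fs <- ps <- matrix(NA_real_, length(effects), ncol(Y),
                     dimnames = list(effects, NULL))
  df_eff <- integer(length(effects)); names(df_eff) <- effects
  for (eff in effects) {
    cc <- design$cols[[eff]]
    df_eff[eff] <- length(cc)
    rss_red <- colSums(qr.resid(qr(X[, -cc, drop = FALSE]), Y)^2)
    Fs[eff, ] <- ((rss_red - rss_full) / length(cc)) / (rss_full / df_err)
    ps[eff, ] <- stats::pf(Fs[eff, ], length(cc), df_err, lower.tail = FALSE)
  }
  list(F = Fs, p = ps, df_effect = df_eff, df_error = df_err,
       residuals = res, rss = rss_full)
}

#' Voxel-wise 2x3 factorial ANCOVA over connectivity-density maps
#'
#' Fits, at every qualified voxel, an ordinary-least-squares model with
#' diagnosis, genotype, their interaction, and nuisance covariates, and
#' returns Type-III F and p maps for the two main effects (df 1 and 2) and
#' the interaction (df 2). Voxels with zero response variance are excluded
#' from the analysis mask and reported.
#'
#' @param maps list of [gfcd_map()] objects (or a subjects x voxels matrix
#'   accompanied by `mask`), one per design row.
#' @param design a design from [build_design()].
#' @param mask a [qualified_mask()]; analysis is restricted to it.
#' @return object of class `fmap_set`: 3D `F` and `p` arrays per effect
#'   (NA outside the analysis mask), the residual matrix, degrees of freedom,
#'   the analysis mask actually used, and the indices of excluded voxels.
#' @export
fit_voxelwise_ancova <- function(maps, design, mask) {
  stopifnot(inherits(mask, "qualified_mask"))
  dims <- dim(mask$mask)
  idx <- which(mask$mask)
  if (is.list(maps) && inherits(maps[[1]], "gfcd_map")) {
    affine <- maps[[1]]$affine
    vals <- vapply(maps, function(m) m$data[idx], numeric(length(idx)))
    Y <- if (length(idx) == 1L) matrix(vals, ncol = 1) else t(vals)
  } else {
    Y <- as.matrix(maps)
    affine <- attr(maps, "affine") %||% make_affine(dim = dims)
  }
  if (nrow(Y) != design$n) stop("number of maps does not match the design rows")
  v_sd <- apply(Y, 2, stats::sd)
  degenerate <- which(v_sd == 0)
  keep <- setdiff(seq_along(idx), degenerate)
  if (length(keep) == 0L) stop("every voxel is constant across subjects")
  core <- ancova_core(Y[, keep, drop = FALSE], design)
  as_map <- function(vals) {
    a <- array(NA_real_, dims)
    a[idx[keep]] <- vals
    a
  }
  eff <- rownames(core$F)
  amask <- array(FALSE, dims); amask[idx[keep]] <- TRUE
  structure(list(
    F = stats::setNames(lapply(eff, function(e) as_map(core$F[e, ])), eff),
    p = stats::setNames(lapply(eff, function(e) as_map(core$p[e, ])), eff),
    df_effect = core$df_effect, df_error = core$df_error,
    residuals = core$residuals, analysis_mask = amask,
    excluded_voxels = idx[degenerate], affine = affine),
    class = "fmap_set")
}

#' @export
print.fmap_set <- function(x, ...) {
  cat(sprintf("<fmap_set> %d voxels, error df %d, effects: %s\n",
              sum(x$analysis_mask), x$df_error,
              paste(names(x$F), collapse = ", ")))
  if (length(x$excluded_voxels)) {
    cat(sprintf("  %d constant voxel(s) excluded\n", length(x$excluded_voxels)))
  }
  invisible(x)
}
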