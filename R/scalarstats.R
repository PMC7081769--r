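#' 2x3 factorial ANCOVA on a scalar phenotype outcome
#'
#' Type-III F tests for the diagnosis and genotype main effects and their
#' interaction after covariate adjustment, using exactly the same linear-model
#' core as the voxel-wise analysis (a scalar outcome is a one-voxel image).
#' Also reports covariate-adjusted cell means (model predictions at the
#' covariate means).
#'
#' @param pheno phenotype data frame (see [build_design()]).
#' @param outcome name of the numeric outcome column.
#' @param covariates covariate names to adjust for; may be `character(0)` for
#'   a plain two-way ANOVA.
#' @return object of class `ancova_result` with `F`, `p`, `df_effect`,
#'   `df_error`, `adjusted_means` (2x3 matrix), `outcome`, `covariates`.
#' @export
scalar_ancova <- function(pheno, outcome, covariates = c("age", "sex", "education")) {
  y <- pheno[[outcome]]
  if (is.null(y)) stop("outcome column '", outcome, "' not found")
  if (!is.numeric(y)) stop("outcome '", outcome, "' is not numeric")
  if (anyNA(y)) stop("outcome '", outcome, "' contains missing values")
  if (stats::sd(y) == 0) stop("outcome '", outcome, "' is constant")
  design <- build_design(pheno, covariates = covariates)
  core <- ancova_core(matrix(y, ncol = 1), design)
  # adjusted cell means: prediction at each (diagnosis, genotype) cell with
  # covariates fixed at their sample means
  beta <- qr.coef(qr(design$X), y)
  cells <- expand.grid(diagnosis = c("CN", "MCI"),
                       genotype = c("e2+", "e3e3", "e4+"),
                       stringsAsFactors = FALSE)
  newd <- cells
  for (cv in covariates) {
    v <- pheno[[cv]]
    if (cv == "sex") v <- as.numeric(v == "M" | v == 1)
    newd[[cv]] <- mean(v)
  }
  newd$diagnosis <- factor(newd$diagnosis, levels = c("CN", "MCI"))
  newd$genotype <- factor(newd$genotype, levels = c("e2+", "e3e3", "e4+"))
  form <- stats::as.formula(paste(c("~ diagnosis * genotype", covariates),
                                  collapse = " + "))
  Xc <- stats::model.matrix(form, newd,
                            contrasts.arg = list(diagnosis = "contr.sum",
                                                 genotype = "contr.sum"))
  adj <- matrix(as.vector(Xc %*% beta), 2, 3,
                dimnames = list(c("CN", "MCI"), c("e2+", "e3e3", "e4+")))
  structure(list(F = core$F[, 1], p = core$p[, 1],
                 df_effect = core$df_effect, df_error = core$df_error,
                 adjusted_means = adj, outcome = outcome,
                 covariates = covariates),
            class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("<ancova_result> outcome '%s' (covariates: %s)\n", x$outcome,
              if (length(x$covariates)) paste(x$covariates, collapse = ", ") else "none"))
  out <- data.frame(effect = names(x$F), df = x$df_effect[names(x$F)],
                    F = round(x$F, 3), p = signif(x$p, 3))
  print(out, row.names = FALSE)
  invisible(x)
}

#' Distribution-free group comparisons for demographic variables
#'
#' Kruskal-Wallis tests across the six (diagnosis x genotype) cells for
#' continuous demographics, and a contingency chi-square for sex.
#'
#' @param pheno phenotype data frame.
#' @param variables columns to test (default `c("age", "sex", "education")`).
#' @return data frame with `variable`, `test`, `statistic`, `df`, `p`.
#' @export
demographics_tests <- function(pheno, variables = c("age", "sex", "education")) {
  cell <- interaction(pheno$diagnosis, pheno$genotype, drop = TRUE)
  if (nlevels(cell) < 2) stop("need at least 2 groups")
  rows <- lapply(variables, function(v) {
    x <- pheno[[v]]
    if (is.null(x)) stop("variable '", v, "' not found")
    if (v == "sex" || is.character(x) || is.factor(x)) {
      tb <- table(x, cell)
      ct <- suppressWarnings(stats::chisq.test(tb))
      data.frame(variable = v, test = "chi-square",
                 statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p = ct$p.value)
    } else {
      if (length(unique(x)) == 1L) {
        stop("variable '", v, "' has no rank variation (all values tied)")
      }
      kw <- stats::kruskal.test(x, cell)
      data.frame(variable = v, test = "kruskal-wallis",
                 statistic = unname(kw$statistic),
                 df = unname(kw$parameter), p = kw$p.value)
    }
  })
  do.call(rbind, rows)
}

#' Post hoc genotype comparisons on covariate-adjusted means
#'
#' Fits the factorial ANCOVA with \code{lm} (sum-to-zero coding), then
#' computes estimated marginal means per genotype and unadjusted pairwise t
#' contrasts (Fisher LSD; Tukey adjustment selectable), plus the contrast of
#' the protective-allele group against the pooled other genotypes.
#'
#' @param pheno phenotype data frame.
#' @param outcome outcome column name.
#' @param covariates covariates to adjust for.
#' @param adjust p-adjustment for the pairwise contrasts: `"none"` (LSD,
#'   default) or `"tukey"`.
#' @return list with `emmeans` (per-genotype adjusted means), `pairs`
#'   (pairwise contrasts) and `e2_vs_pooled` (one-row contrast summary).
#' @export
post_hoc_genotype <- function(pheno, outcome, covariates = c("age", "sex", "education"),
                              adjust = c("none", "tukey")) {
  adjust <- match.arg(adjust)
  d <- data.frame(
    y = pheno[[outcome]],
    diagnosis = factor(pheno$diagnosis, levels = c("CN", "MCI")),
    genotype = factor(pheno$genotype, levels = c("e2+", "e3e3", "e4+")))
  for (cv in covariates) {
    v <- pheno[[cv]]
    if (cv == "sex") v <- as.numeric(v == "M" | v == 1)
    d[[cv]] <- v
  }
  form <- stats::as.formula(paste(c("y ~ diagnosis * genotype", covariates),
                                  collapse = " + "))
  fit <- stats::lm(form, data = d,
                   contrasts = list(diagnosis = "contr.sum", genotype = "contr.sum"))
  emm <- emmeans::emmeans(fit, ~ genotype)
  prs <- summary(emmeans::contrast(emm, method = "pairwise", adjust = adjust))
  pooled <- summary(emmeans::contrast(
    emm, method = list("e2+ vs pooled" = c(1, -0.5, -0.5))))
  list(emmeans = summary(emm), pairs = prs, e2_vs_pooled = pooled,
       model = fit)
}

#' Table-1-style report of a phenotype cohort
#'
#' Per-cell mean +/- SD for each outcome with the three factorial p values
#' (diagnosis, genotype, interaction) from [scalar_ancova()].
#'
#' @param pheno phenotype data frame.
#' @param outcomes outcome columns to summarize.
#' @param covariates covariates for the ANCOVA p values.
#' @return data frame, one row per outcome: six `mean (sd)` cells and the
#'   three p values.
#' @export
cohort_table <- function(pheno, outcomes,
                         covariates = c("age", "sex", "education")) {
  cells <- expand.grid(diagnosis = c("CN", "MCI"),
                       genotype = c("e2+", "e3e3", "e4+"),
                       stringsAsFactors = FALSE)
  rows <- lapply(outcomes, function(oc) {
    x <- pheno[[oc]]
    cellstats <- vapply(seq_len(nrow(cells)), function(i) {
      sel <- pheno$diagnosis == cells$diagnosis[i] &
        pheno$genotype == cells$genotype[i]
      sprintf("%.2f ± %.2f", mean(x[sel]), stats::sd(x[sel]))
    }, character(1))
    a <- scalar_ancova(pheno, oc, covariates)
    out <- c(list(outcome = oc),
             stats::setNames(as.list(cellstats),
                             paste(cells$diagnosis, cells$genotype, sep = "_")),
             list(p_diagnosis = a$p[["diagnosis"]],
                  p_genotype = a$p[["genotype"]],
                  p_interaction = a$p[["interaction"]]))
    as.data.frame(out, check.names = FALSE)
  })
  do.call(rbind, rows)
}
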