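## Per-SNP case-control logistic GWAS, overlap with cis eSNPs, and
## expression-disease association models.

.assoc_design <- function(covars) {
  cbind(`(Intercept)` = 1, age = covars$age, sex = covars$sex,
        fam1 = covars$fam1, fam2 = covars$fam2)
}

.logistic_fit <- function(X, y) {
  ## IRLS maximum-likelihood logistic fit via stats::glm.fit.
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-12,
                                                maxit = 50)))
  ok <- fit$converged
  se <- rep(NA_real_, ncol(X))
  if (ok) {
    w <- fit$weights
    XtWX <- crossprod(X * sqrt(w))
    cov <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (is.null(cov)) ok <- FALSE else se <- sqrt(diag(cov))
  }
  list(coef = fit$coefficients, se = se, converged = ok)
}

## A term is separated/uninformative when its ML estimate diverges: the
## Wald SE explodes (log-odds scale) or the coefficient runs away.
.term_separated <- function(beta, se) {
  !is.finite(beta) || !is.finite(se) || se > 50 || abs(beta) > 25
}

#' Per-SNP case-control logistic GWAS
#'
#' For each SNP fits, by iteratively-reweighted least squares, the logistic
#' model status ~ intercept + age + sex + Fam1 + Fam2 + dosage (family
#' structure absorbed by the Fam1/Fam2 fixed covariates) and reports the
#' Wald test of the dosage term. Individuals with missing covariates are
#' removed; missing dosages are mean-imputed per site; zero-variance SNPs
#' and separated/unconverged fits are flagged with p = NA.
#'
#' @param genos a \code{genotype_matrix}.
#' @param covars covariate data.frame: sample_id, sex, age, fam1, fam2,
#'   status (0/1).
#' @return a \code{gwas_result} data.frame: snp, beta_g, se, pvalue,
#'   converged, sorted by p-value.
#' @export
logistic_scan <- function(genos, covars) {
  covars <- covars[stats::complete.cases(covars), , drop = FALSE]
  samples <- intersect(genos$samples, covars$sample_id)
  covars <- covars[match(samples, covars$sample_id), , drop = FALSE]
  if (length(unique(covars$status)) != 2L)
    stop("status must contain both cases and controls")
  X0 <- .assoc_design(covars)
  if (qr(X0)$rank < ncol(X0))
    stop("singular covariate design; check sex/age/fam columns")
  D <- .impute_dosage(genos$dosage[samples, , drop = FALSE])
  y <- covars$status
  res <- lapply(seq_len(ncol(D)), function(j) {
    g <- D[, j]
    if (stats::sd(g) == 0)
      return(c(beta = NA_real_, se = NA_real_, p = NA_real_, conv = 0))
    f <- .logistic_fit(cbind(X0, dosage = g), y)
    k <- ncol(X0) + 1L
    if (!f$converged || .term_separated(f$coef[k], f$se[k]))
      return(c(beta = unname(f$coef[k]), se = NA_real_, p = NA_real_,
               conv = 0))
    zz <- unname(f$coef[k] / f$se[k])
    c(beta = unname(f$coef[k]), se = unname(f$se[k]),
      p = 2 * stats::pnorm(abs(zz), lower.tail = FALSE), conv = 1)
  })
  m <- do.call(rbind, res)
  out <- data.frame(snp = colnames(D), beta_g = m[, "beta"], se = m[, "se"],
                    pvalue = m[, "p"], converged = m[, "conv"] == 1,
                    stringsAsFactors = FALSE)
  out <- out[order(out$pvalue), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gwas_result", "data.frame")
  out
}

#' @export
print.gwas_result <- function(x, n = 6L, ...) {
  cat("Logistic GWAS:", nrow(x), "SNPs;", sum(!x$converged),
      "unconverged/separated\n")
  print.data.frame(utils::head(as.data.frame(x), n))
  invisible(x)
}

#' Overlap of top GWAS SNPs with cis eSNPs
#'
#' Lists, for each of the top \code{top_n} GWAS SNPs by p-value, every
#' (treatment, gene) in which that SNP is a significant cis eSNP.
#'
#' @param gwas a \code{gwas_result}.
#' @param cis_tables named list of per-treatment cis \code{eqtl_table}s.
#' @param top_n number of top GWAS SNPs to consider (clamped to the table
#'   size with a warning).
#' @param fdr_threshold cis significance threshold.
#' @return data.frame (snp, gwas_p, treatment, gene); zero rows when
#'   nothing overlaps.
#' @export
gwas_eqtl_overlap <- function(gwas, cis_tables, top_n = 15L,
                              fdr_threshold = 0.05) {
  if (top_n > nrow(gwas)) {
    warning("top_n exceeds GWAS table; using all ", nrow(gwas), " SNPs")
    top_n <- nrow(gwas)
  }
  top <- utils::head(gwas[!is.na(gwas$pvalue), , drop = FALSE], top_n)
  rows <- list()
  for (tr in names(cis_tables)) {
    tab <- .sig_best(cis_tables[[tr]], thr = fdr_threshold)
    tab <- tab[tab$class == "cis" & tab$snp %in% top$snp, , drop = FALSE]
    if (nrow(tab))
      rows[[tr]] <- data.frame(snp = tab$snp,
                               gwas_p = top$pvalue[match(tab$snp, top$snp)],
                               treatment = tr, gene = tab$gene,
                               stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(snp = character(0), gwas_p = numeric(0),
                      treatment = character(0), gene = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$gwas_p, out$snp, out$treatment), , drop = FALSE]
}

#' Surrogate variables by protected-residual principal components
#'
#' Residualizes expression on the known covariates INCLUDING disease
#' status (so status-aligned variation is protected from capture) and
#' returns the top-k principal components of the residuals as surrogate
#' variables; columns are orthogonal to the protected design.
#'
#' @param expr an \code{expression_matrix} (or genes x samples matrix).
#' @param covars covariate data.frame (sample_id, sex, age, fam1, fam2,
#'   status).
#' @param k number of surrogate variables (0 gives a zero-column matrix).
#' @return samples x k matrix with attribute "protected" naming the design
#'   columns.
#' @export
surrogate_variables <- function(expr, covars, k) {
  V <- if (inherits(expr, "expression_matrix")) expr$values else expr
  samples <- colnames(V)
  covars <- covars[match(samples, covars$sample_id), , drop = FALSE]
  X <- cbind(.assoc_design(covars), status = covars$status)
  if (k >= length(samples) - qr(X)$rank) stop("k too large for the design")
  if (k == 0L) {
    out <- matrix(numeric(0), length(samples), 0L,
                  dimnames = list(samples, NULL))
    attr(out, "protected") <- colnames(X)
    return(out)
  }
  R <- t(stats::lm.fit(X, t(V))$residuals)
  pc <- stats::prcomp(t(R), center = FALSE, scale. = FALSE)
  out <- pc$x[, seq_len(k), drop = FALSE]
  colnames(out) <- paste0("sv", seq_len(k))
  rownames(out) <- samples
  attr(out, "protected") <- colnames(X)
  out
}

#' Logistic association between a gene's expression and disease status
#'
#' Fits status ~ intercept + sex + age + Fam1 + Fam2 + surrogate variables
#' + expression and reports the Wald test of the expression term.
#'
#' @param gene_values named expression vector (names = sample ids).
#' @param covars covariate data.frame.
#' @param svs optional surrogate-variable matrix from
#'   \code{\link{surrogate_variables}}.
#' @return list(beta_expr, se, pvalue, converged).
#' @export
expression_disease_assoc <- function(gene_values, covars, svs = NULL) {
  samples <- intersect(names(gene_values), covars$sample_id)
  covars <- covars[match(samples, covars$sample_id), , drop = FALSE]
  X <- .assoc_design(covars)
  if (!is.null(svs) && ncol(svs) > 0L)
    X <- cbind(X, svs[samples, , drop = FALSE])
  X <- cbind(X, expr = unname(gene_values[samples]))
  f <- .logistic_fit(X, covars$status)
  k <- ncol(X)
  if (!f$converged || .term_separated(f$coef[k], f$se[k]))
    return(list(beta_expr = unname(f$coef[k]), se = NA_real_,
                pvalue = NA_real_, converged = FALSE))
  zz <- f$coef[k] / f$se[k]
  list(beta_expr = unname(f$coef[k]), se = unname(f$se[k]),
       pvalue = 2 * stats::pnorm(abs(zz), lower.tail = FALSE),
       converged = TRUE)
}
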