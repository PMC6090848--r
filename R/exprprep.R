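## Expression filtration, normalization, variance stabilization and
## covariate/latent-factor residualization.

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median across reference genes of
#' the ratio of the sample's count to the gene's geometric mean across
#' samples. Reference genes are those with a nonzero count in every sample.
#'
#' @param counts genes x samples count matrix.
#' @return named vector of positive size factors (one per sample).
#' @export
size_factors <- function(counts) {
  if (any(counts < 0, na.rm = TRUE)) stop("negative counts")
  ref <- rowSums(counts == 0) == 0
  if (!any(ref))
    stop("no gene has nonzero counts in all samples; consider a ",
         "pseudo-reference fallback on a less sparse matrix")
  lg <- log(counts[ref, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(lg, 2L, function(x) exp(stats::median(x - geo)))
  if (any(!is.finite(sf) | sf <= 0)) stop("non-positive size factor")
  sf
}

#' Normalize counts by size factors
#' @param counts genes x samples count matrix.
#' @param factors per-sample size factors (defaults to
#'   \code{\link{size_factors}(counts)}).
#' @return genes x samples matrix of normalized counts.
#' @export
normalize_counts <- function(counts, factors = size_factors(counts)) {
  sweep(counts, 2L, factors, "/")
}

#' Variance-flattening transform of normalized counts
#'
#' Applies value = log2(count / size factor + 1). A monotone stand-in for a
#' full mean-dispersion variance-stabilizing transformation: it flattens the
#' mean-variance relationship of negative-binomial counts while remaining
#' deterministic and dependency-free; it is not numerically identical to
#' model-based transforms.
#'
#' @param counts genes x samples count matrix.
#' @param factors per-sample size factors.
#' @return an \code{expression_matrix}: list(values, size_factors).
#' @export
vst <- function(counts, factors = size_factors(counts)) {
  if (any(counts < 0, na.rm = TRUE)) stop("negative counts")
  values <- log2(sweep(counts, 2L, factors, "/") + 1)
  out <- list(values = values, size_factors = factors)
  class(out) <- "expression_matrix"
  out
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("Expression matrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples (variance-stabilized scale)\n")
  invisible(x)
}

## Two-sample Kolmogorov-Smirnov D statistic (sup |ECDF_x - ECDF_y|),
## computed directly; cheap enough for the pairwise cutoff loop.
ks_D <- function(x, y) {
  nx <- length(x); ny <- length(y)
  z <- c(x, y)
  o <- order(z)
  steps <- ifelse(o <= nx, 1 / nx, -1 / ny)
  cs <- cumsum(steps)
  zs <- z[o]
  ## at ties, only the value after the full tie group counts
  last <- c(zs[-1] != zs[-length(zs)], TRUE)
  max(abs(cs[last]))
}

#' Pairwise iterative KS read-count cutoff
#'
#' Iterates cutoff values over \code{grid} (default 0..300 step 2). At each
#' cutoff, genes whose mean normalized count over the two samples falls
#' below the cutoff are dropped, and the two-sample KS D statistic between
#' the two samples' retained expression profiles is computed. Iteration
#' stops, returning the current cutoff, when the current D is (i) lower
#' than the first D, (ii) lower than the next D, and (iii) lower than the
#' first D minus 0.0001. If the rules are never satisfied (or fewer than 2
#' genes remain) the maximum grid value is returned flagged.
#'
#' @param exprA,exprB normalized per-gene values for the two samples, over
#'   an identical gene set.
#' @param grid increasing cutoff grid.
#' @return list(cutoff, flagged, d_first, d_path).
#' @export
ks_cutoff_pair <- function(exprA, exprB, grid = seq(0, 300, by = 2)) {
  stopifnot(length(exprA) == length(exprB))
  pair_mean <- (exprA + exprB) / 2
  d_at <- function(cut) {
    keep <- pair_mean >= cut
    if (sum(keep) < 2L) return(NA_real_)
    ks_D(exprA[keep], exprB[keep])
  }
  d <- vapply(grid, function(g) NA_real_, numeric(1))
  d[1L] <- d_at(grid[1L])
  if (is.na(d[1L]))
    return(list(cutoff = max(grid), flagged = TRUE, d_first = NA_real_,
                d_path = d))
  d_first <- d[1L]
  for (i in seq_along(grid)[-length(grid)]) {
    if (is.na(d[i])) break
    d[i + 1L] <- d_at(grid[i + 1L])
    if (is.na(d[i + 1L])) break
    if (d[i] < d_first && d[i] < d[i + 1L] && d[i] < d_first - 1e-4)
      return(list(cutoff = grid[i], flagged = FALSE, d_first = d_first,
                  d_path = d))
  }
  list(cutoff = max(grid), flagged = TRUE, d_first = d_first, d_path = d)
}

#' Cohort-level KS cutoff and low-expression gene filtration
#'
#' Pre-filters to genes with at least one read in at least one sample,
#' normalizes by median-of-ratios size factors, runs
#' \code{\link{ks_cutoff_pair}} over all unordered sample pairs, and
#' summarizes the per-pair cutoffs by their mean and median (flagged,
#' unresolved pairs are excluded with a warning). Genes whose mean
#' normalized count reaches the mean cutoff are retained.
#'
#' @param counts genes x samples count matrix.
#' @param grid cutoff grid passed to \code{\link{ks_cutoff_pair}}.
#' @return a \code{ks_cutoff_result}: list(pairwise_cutoffs, flagged,
#'   mean_cutoff, median_cutoff, genes_retained, n_pairs).
#' @export
ks_cutoff_cohort <- function(counts, grid = seq(0, 300, by = 2)) {
  n <- ncol(counts)
  if (n < 2L) stop("need at least 2 samples")
  expressed <- rowSums(counts) >= 1
  cm <- counts[expressed, , drop = FALSE]
  norm <- normalize_counts(cm)
  pairs <- utils::combn(n, 2L)
  cutoffs <- numeric(ncol(pairs)); flagged <- logical(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    r <- ks_cutoff_pair(norm[, pairs[1L, k]], norm[, pairs[2L, k]], grid)
    cutoffs[k] <- r$cutoff; flagged[k] <- r$flagged
  }
  if (any(flagged))
    warning(sum(flagged), " of ", length(flagged),
            " sample pairs never satisfied the stopping rules; ",
            "excluded from the mean/median cutoff")
  ok <- !flagged
  mean_cut <- if (any(ok)) mean(cutoffs[ok]) else 0
  med_cut <- if (any(ok)) stats::median(cutoffs[ok]) else 0
  retained <- rownames(cm)[rowMeans(norm) >= mean_cut]
  out <- list(pairwise_cutoffs = cutoffs, flagged = flagged,
              mean_cutoff = mean_cut, median_cutoff = med_cut,
              genes_retained = retained, n_pairs = ncol(pairs))
  class(out) <- "ks_cutoff_result"
  out
}

#' @export
print.ks_cutoff_result <- function(x, ...) {
  cat("KS read-count cutoff over", x$n_pairs, "sample pairs\n")
  cat("  mean cutoff:", round(x$mean_cutoff, 2),
      " median cutoff:", x$median_cutoff, "\n")
  cat("  unresolved pairs:", sum(x$flagged), "\n")
  cat("  genes retained:", length(x$genes_retained), "\n")
  invisible(x)
}

.design_matrix <- function(covariates, samples) {
  stopifnot(all(samples %in% covariates$sample_id))
  cv <- covariates[match(samples, covariates$sample_id), , drop = FALSE]
  cols <- setdiff(names(cv), "sample_id")
  X <- cbind(`(Intercept)` = 1,
             as.matrix(as.data.frame(lapply(cv[cols], as.numeric))))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient covariate matrix; collinear column(s): ",
         paste(drop, collapse = ", "))
  }
  X
}

#' Residualize expression on known covariates and latent factors
#'
#' Each gene is regressed on intercept + the supplied covariates; the top-k
#' principal components of the resulting residual matrix serve as latent
#' batch factors; expression is then re-regressed on covariates plus
#' factors and the final residuals are returned. With k = 0 this is plain
#' covariate regression.
#'
#' @param expr an \code{expression_matrix} (or a genes x samples matrix).
#' @param covariates data.frame with sample_id plus numeric covariate
#'   columns; NULL for intercept-only.
#' @param k_factors number of latent factors (principal components).
#' @param factors optional pre-computed latent factor matrix (samples x k),
#'   e.g. from a previous pass; when supplied it is used as-is instead of
#'   re-estimating, which makes the operation idempotent.
#' @return a \code{residual_matrix}: list(residuals, k_factors, factors,
#'   covariates_used).
#' @export
residualize <- function(expr, covariates = NULL, k_factors = 0L,
                        factors = NULL) {
  V <- if (inherits(expr, "expression_matrix")) expr$values else expr
  samples <- colnames(V)
  X <- if (is.null(covariates))
    matrix(1, ncol(V), 1L, dimnames = list(samples, "(Intercept)"))
  else .design_matrix(covariates, samples)
  if (k_factors >= ncol(V) - ncol(X) - 1L)
    stop("k_factors must be < n_samples - covariates - 1")
  proj_resid <- function(M, X) {
    ## residual of each row of M on the columns of X (sample dimension)
    t(stats::lm.fit(X, t(M))$residuals)
  }
  if (is.null(factors) && k_factors > 0L) {
    R1 <- proj_resid(V, X)
    pc <- stats::prcomp(t(R1), center = FALSE, scale. = FALSE)
    factors <- pc$x[, seq_len(k_factors), drop = FALSE]
    colnames(factors) <- paste0("factor", seq_len(k_factors))
  }
  if (!is.null(factors) && ncol(factors) > 0L) X <- cbind(X, factors)
  R <- proj_resid(V, X)
  dimnames(R) <- dimnames(V)
  k_factors <- if (is.null(factors)) 0L else ncol(factors)
  out <- list(residuals = R, k_factors = as.integer(k_factors),
              factors = factors,
              covariates_used = setdiff(colnames(X), "(Intercept)"))
  class(out) <- "residual_matrix"
  out
}

#' @export
print.residual_matrix <- function(x, ...) {
  cat("Residual expression matrix:", nrow(x$residuals), "genes x",
      ncol(x$residuals), "samples;", x$k_factors, "latent factor(s)\n")
  if (length(x$covariates_used))
    cat("  covariates:", paste(x$covariates_used, collapse = ", "), "\n")
  invisible(x)
}
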