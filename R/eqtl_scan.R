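## The additive linear cis/trans eQTL scan with BH FDR control.

#' Classify a SNP/gene pair as cis or trans
#'
#' A pair is cis iff the SNP lies on the gene's chromosome within
#' \code{cis_dist} bp (inclusive) of its transcription start site;
#' otherwise trans.
#'
#' @param snp_chrom,snp_pos SNP coordinates (vectors recycle).
#' @param gene_chrom,gene_tss gene coordinates.
#' @param cis_dist window half-width in bp (default 1 Mb).
#' @return character vector "cis"/"trans".
#' @export
classify_pair <- function(snp_chrom, snp_pos, gene_chrom, gene_tss,
                          cis_dist = 1e6) {
  stopifnot(cis_dist > 0)
  ifelse(snp_chrom == gene_chrom & abs(snp_pos - gene_tss) <= cis_dist,
         "cis", "trans")
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up adjusted p-values q_(i) = min over j >= i of p_(j) * m / j,
#' mapped back to input order (delegates to \code{stats::p.adjust}).
#'
#' @param pvalues vector of p-values in (0, 1].
#' @return FDR (BH-adjusted p) vector in input order.
#' @export
bh_fdr <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(!is.finite(pvalues) | pvalues <= 0 | pvalues > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

.impute_dosage <- function(dosage) {
  nmiss <- colSums(is.na(dosage))
  if (any(nmiss > 0)) {
    mu <- colMeans(dosage, na.rm = TRUE)
    for (j in which(nmiss > 0))
      dosage[is.na(dosage[, j]), j] <- mu[j]
  }
  dosage
}

.is_x_chrom <- function(chrom) toupper(sub("^chr", "", chrom)) == "X"

#' Additive linear cis/trans eQTL scan
#'
#' For every (SNP, gene) pair in scope, fits the additive model
#' y = mu + m u + e by simple linear regression of residual expression on
#' allele dosage, using the correlation identity t = r sqrt(n-2) /
#' sqrt(1-r^2) with a two-sided Student-t p-value on n-2 df.
#' Benjamini-Hochberg FDRs are computed separately within the cis and trans
#' streams. X-chromosome SNPs and genes are excluded; zero-variance SNPs
#' are skipped and counted; missing dosages are mean-imputed per site.
#'
#' @param residuals a \code{residual_matrix} (or genes x samples matrix) of
#'   covariate-free expression residuals.
#' @param genos a \code{genotype_matrix}.
#' @param genes a \code{gene_models} object covering the expression rows.
#' @param cis_dist cis window half-width in bp (default 1 Mb, giving the
#'   conventional 2 Mb window).
#' @param fdr_threshold significance threshold recorded on the result.
#' @param mode "cis", "trans" or "both": which stream(s) to test.
#' @param min_nonmissing minimum non-missing genotype calls per SNP.
#' @return an \code{eqtl_table} with columns snp, gene, class, beta, tstat,
#'   pvalue, fdr, confidence ("unset"), distance (signed snp - TSS bp, NA
#'   across chromosomes); attributes n_samples, n_skipped, fdr_threshold.
#' @export
eqtl_scan <- function(residuals, genos, genes, cis_dist = 1e6,
                      fdr_threshold = 0.05, mode = c("both", "cis", "trans"),
                      min_nonmissing = 3L) {
  mode <- match.arg(mode)
  R <- if (inherits(residuals, "residual_matrix")) residuals$residuals
  else residuals
  stopifnot(inherits(genos, "genotype_matrix"), inherits(genes, "gene_models"))
  samples <- intersect(colnames(R), rownames(genos$dosage))
  if (length(samples) < 4L) stop("fewer than 4 shared samples")
  R <- R[, samples, drop = FALSE]
  D <- genos$dosage[samples, , drop = FALSE]
  snps <- genos$snps

  gm <- genes$genes[match(rownames(R), genes$genes$gene_id), , drop = FALSE]
  if (anyNA(gm$gene_id)) stop("expression rows missing from gene models")
  keep_g <- !.is_x_chrom(gm$chrom)
  keep_s <- !.is_x_chrom(snps$chrom) &
    colSums(!is.na(D)) >= min_nonmissing
  D <- .impute_dosage(D[, keep_s, drop = FALSE])
  snps <- snps[keep_s, , drop = FALSE]
  sdg <- apply(D, 2L, stats::sd)
  n_skipped <- sum(sdg == 0)
  nz <- sdg > 0
  D <- D[, nz, drop = FALSE]; snps <- snps[nz, , drop = FALSE]
  R <- R[keep_g, , drop = FALSE]; gm <- gm[keep_g, , drop = FALSE]
  n <- length(samples)
  if (!nrow(R) || !nrow(snps)) stop("nothing to test after filtering")

  ## correlation of every SNP with every gene via standardized cross-product
  Zg <- scale(D)                      # n x S
  Zy <- scale(t(R))                   # n x G
  sd_g <- attr(Zg, "scaled:scale"); sd_y <- attr(Zy, "scaled:scale")
  r <- crossprod(Zg, Zy) / (n - 1)    # S x G
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  pp <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  pp <- pmax(pp, .Machine$double.xmin)
  beta <- r * outer(1 / sd_g, sd_y)

  same <- outer(snps$chrom, gm$chrom, "==")
  dist <- outer(snps$pos, gm$tss, "-")
  is_cis <- same & abs(dist) <= cis_dist
  dist[!same] <- NA_real_

  sel <- switch(mode, both = rep(TRUE, length(is_cis)),
                cis = as.vector(is_cis), trans = as.vector(!is_cis))
  idx <- which(sel)
  S <- nrow(snps)
  tab <- data.frame(
    snp = snps$id[((idx - 1L) %% S) + 1L],
    gene = gm$gene_id[((idx - 1L) %/% S) + 1L],
    class = ifelse(as.vector(is_cis)[idx], "cis", "trans"),
    beta = as.vector(beta)[idx],
    tstat = as.vector(tt)[idx],
    pvalue = as.vector(pp)[idx],
    fdr = NA_real_,
    confidence = "unset",
    distance = as.vector(dist)[idx],
    stringsAsFactors = FALSE)
  for (kl in c("cis", "trans")) {
    m <- tab$class == kl
    if (any(m)) tab$fdr[m] <- bh_fdr(tab$pvalue[m])
  }
  tab <- eqtl_table(tab)
  attr(tab, "n_samples") <- n
  attr(tab, "n_skipped") <- n_skipped
  attr(tab, "fdr_threshold") <- fdr_threshold
  attr(tab, "cis_dist") <- cis_dist
  tab
}

#' Best eSNP per gene
#'
#' Keeps, for each gene, the record with the lowest FDR; ties broken by
#' lower raw p-value, then smaller |SNP - TSS| distance (records without a
#' shared chromosome rank last), then lexicographic SNP id.
#'
#' @param table an \code{eqtl_table} with the fdr column populated.
#' @return an \code{eqtl_table} with exactly one record per input gene.
#' @export
best_per_gene <- function(table) {
  stopifnot(inherits(table, "eqtl_table"))
  if (!nrow(table)) return(table)
  d <- abs(table$distance %||% rep(NA_real_, nrow(table)))
  d[is.na(d)] <- Inf
  o <- order(table$gene, table$fdr, table$pvalue, d, table$snp)
  out <- table[o, , drop = FALSE][!duplicated(table$gene[o]), , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("n_samples", "fdr_threshold", "cis_dist"))
    attr(out, a) <- attr(table, a)
  out
}
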