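## Readers/writers for the standard formats the pipeline touches.

#' Read and filter genotypes from a VCF file
#'
#' Retains biallelic SNPs only, converts genotype calls to 0/1/2 dosage
#' (alternate-allele count), drops sites with more than \code{max_missing}
#' missing calls, minor allele frequency below \code{maf_min}, or strong
#' deviation from Hardy-Weinberg equilibrium (p <= \code{hwe_alpha}). When a
#' \code{status} vector is supplied the HWE test uses control individuals
#' (status == 0) only. Remaining missing dosages are kept as NA and
#' mean-imputed per site at regression time.
#'
#' @param path VCF 4.x file (plain text or bgzipped).
#' @param maf_min minimum minor allele frequency (sites with MAF strictly
#'   below are removed).
#' @param hwe_alpha HWE p-value at or below which a site is removed.
#'   Default 1e-6.
#' @param status optional named 0/1 vector (names = sample ids); HWE is
#'   then computed from controls only.
#' @param max_missing maximum tolerated fraction of missing calls per site.
#' @param hwe_exact use the exact conditional HWE test instead of the
#'   1-df chi-square goodness of fit.
#' @return a \code{genotype_matrix}.
#' @export
read_genotypes <- function(path, maf_min = 0.05, hwe_alpha = 1e-6,
                           status = NULL, max_missing = 0.1,
                           hwe_exact = FALSE) {
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e)
                    stop("malformed VCF '", path, "': ", conditionMessage(e)))
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n_in <- nrow(fix)
  biallelic <- !is.na(fix[, "ALT"]) & !grepl(",", fix[, "ALT"], fixed = TRUE) &
    nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  keep <- which(biallelic)
  if (length(keep) == 0L) stop("no biallelic SNPs in VCF")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]

  samples <- colnames(gt)
  phased <- all(grepl("|", gt[!is.na(gt)], fixed = TRUE))
  a1 <- substr(gt, 1L, 1L); a2 <- substr(gt, 3L, 3L)
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt))
  ok <- !is.na(gt) & a1 %in% c("0", "1") & a2 %in% c("0", "1")
  dos[ok] <- (a1[ok] == "1") + (a2[ok] == "1")
  hap <- NULL
  if (phased) {
    h1 <- matrix(NA_integer_, nrow(gt), ncol(gt))
    h2 <- h1
    h1[ok] <- as.integer(a1[ok] == "1"); h2[ok] <- as.integer(a2[ok] == "1")
    hap <- list(h1 = t(h1), h2 = t(h2))
  }
  dos <- t(dos)  # samples x snps
  rownames(dos) <- samples

  miss_frac <- colMeans(is.na(dos))
  af <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  ctrl <- samples
  if (!is.null(status)) {
    ctrl <- intersect(samples, names(status)[status == 0])
    if (length(ctrl) == 0L) stop("no control individuals for the HWE test")
  }
  hwe_p <- apply(dos[ctrl, , drop = FALSE], 2L, function(d) {
    d <- d[!is.na(d)]
    if (length(d) < 2L) return(1)
    n0 <- sum(d == 0L); n1 <- sum(d == 1L); n2 <- sum(d == 2L)
    if (hwe_exact) hwe_exact_test(n0, n1, n2) else hwe_chisq(n0, n1, n2)
  })

  fail_miss <- miss_frac > max_missing
  fail_maf <- maf < maf_min
  fail_hwe <- hwe_p <= hwe_alpha
  keep2 <- !(fail_miss | fail_maf | fail_hwe)
  message(sprintf(
    "read_genotypes: %d records, %d biallelic; dropped %d missingness, %d MAF, %d HWE; %d retained",
    n_in, ncol(dos), sum(fail_miss), sum(fail_maf & !fail_miss),
    sum(fail_hwe & !fail_miss & !fail_maf), sum(keep2)))
  if (!any(keep2)) stop("no SNPs survive the MAF/HWE/missingness filters")

  snps <- data.frame(id = fix[, "ID"], chrom = fix[, "CHROM"],
                     pos = as.integer(fix[, "POS"]),
                     ref = fix[, "REF"], alt = fix[, "ALT"],
                     maf = maf, stringsAsFactors = FALSE)
  no_id <- is.na(snps$id) | snps$id == "."
  snps$id[no_id] <- sprintf("%s_%d", snps$chrom[no_id], snps$pos[no_id])
  snps <- snps[keep2, , drop = FALSE]
  rownames(snps) <- NULL
  dos <- dos[, keep2, drop = FALSE]
  colnames(dos) <- snps$id
  if (!is.null(hap)) {
    hap$h1 <- hap$h1[, keep2, drop = FALSE]
    hap$h2 <- hap$h2[, keep2, drop = FALSE]
    colnames(hap$h1) <- colnames(hap$h2) <- snps$id
    rownames(hap$h1) <- rownames(hap$h2) <- samples
  }
  g <- list(snps = snps, samples = samples, cohort = NULL, dosage = dos,
            phased = phased, haplotypes = hap)
  class(g) <- "genotype_matrix"
  g
}

#' Hardy-Weinberg chi-square goodness-of-fit p-value
#'
#' 1-df chi-square on the three genotype counts against the expectation
#' from the sample allele frequency.
#'
#' @param n0,n1,n2 counts of reference-homozygous, heterozygous and
#'   alternate-homozygous individuals.
#' @return p-value.
#' @export
hwe_chisq <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  p <- (2 * n0 + n1) / (2 * n)
  if (p <= 0 || p >= 1) return(1)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  stat <- sum((c(n0, n1, n2) - e)^2 / e)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Exact conditional Hardy-Weinberg test p-value
#'
#' Sums the probabilities of all heterozygote counts (conditional on allele
#' counts) no more likely than the observed one.
#'
#' @inheritParams hwe_chisq
#' @return p-value.
#' @export
hwe_exact_test <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  nA <- 2 * n0 + n1          # rarer allele decided below
  nB <- 2 * n2 + n1
  n_rare <- min(nA, nB)
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  logp <- vapply(hets, function(h) {
    hom_r <- (n_rare - h) / 2
    hom_c <- n - h - hom_r
    lgamma(n + 1) - lgamma(hom_r + 1) - lgamma(h + 1) - lgamma(hom_c + 1) +
      h * log(2) + lgamma(n_rare + 1) + lgamma(2 * n - n_rare + 1) -
      lgamma(2 * n + 1)
  }, numeric(1))
  pr <- exp(logp - max(logp)); pr <- pr / sum(pr)
  obs <- pr[match(n1, hets)]
  min(1, sum(pr[pr <= obs + 1e-12]))
}

#' Read gene models from GFF3 or BED12
#'
#' GFF3: rows of type "gene" give span and strand; exon and UTR rows are
#' assigned to their gene via the Parent (or gene) attribute. BED12: the
#' twelve-column block layout gives exons, the thick region separates coding
#' sequence from UTRs. Introns are derived as the gaps between consecutive
#' exons. The TSS is the 5' end on the annotated strand: start for "+",
#' end for "-". Coordinates are 1-based closed throughout.
#'
#' @param path a .gff/.gff3 or .bed file.
#' @return a \code{gene_models} object: list with \code{genes} (data.frame
#'   gene_id, chrom, strand, tss, start, end) and \code{intervals}
#'   (data.frame gene_id, start, end, feature in 5UTR/exon/intron/3UTR).
#' @export
read_gene_models <- function(path) {
  ext <- tolower(tools::file_ext(path))
  gm <- if (ext %in% c("gff", "gff3")) .read_gff3_models(path)
  else if (ext == "bed") .read_bed12_models(path)
  else stop("unsupported gene model format: .", ext)
  bad <- gm$intervals$end < gm$intervals$start
  if (any(bad))
    stop("zero/negative-length interval in gene(s): ",
         paste(unique(gm$intervals$gene_id[bad]), collapse = ", "))
  class(gm) <- "gene_models"
  gm
}

.derive_introns <- function(ex) {
  ex <- ex[order(ex$start), , drop = FALSE]
  if (nrow(ex) < 2L) return(NULL)
  data.frame(gene_id = ex$gene_id[-1],
             start = ex$end[-nrow(ex)] + 1L, end = ex$start[-1] - 1L,
             feature = "intron", stringsAsFactors = FALSE)
}

.read_gff3_models <- function(path) {
  g <- rtracklayer::readGFF(path)
  g <- as.data.frame(g, stringsAsFactors = FALSE)
  is_gene <- g$type == "gene"
  if (!any(is_gene)) stop("no 'gene' records in GFF3 file")
  strand <- as.character(g$strand)
  if (any(!strand[is_gene] %in% c("+", "-")))
    stop("gene(s) without strand in GFF3: ",
         paste(g$ID[is_gene & !strand %in% c("+", "-")], collapse = ", "))
  genes <- data.frame(gene_id = as.character(g$ID[is_gene]),
                      chrom = as.character(g$seqid[is_gene]),
                      strand = strand[is_gene],
                      start = g$start[is_gene], end = g$end[is_gene],
                      stringsAsFactors = FALSE)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  parent <- if ("Parent" %in% names(g))
    vapply(g$Parent, function(p) if (length(p)) as.character(p[[1]]) else NA_character_,
           character(1))
  else rep(NA_character_, nrow(g))
  feat_map <- c(exon = "exon", five_prime_UTR = "5UTR",
                three_prime_UTR = "3UTR")
  is_feat <- g$type %in% names(feat_map)
  iv <- data.frame(gene_id = parent[is_feat],
                   start = g$start[is_feat], end = g$end[is_feat],
                   feature = unname(feat_map[as.character(g$type[is_feat])]),
                   stringsAsFactors = FALSE)
  iv <- iv[iv$gene_id %in% genes$gene_id, , drop = FALSE]
  intr <- do.call(rbind, lapply(split(iv[iv$feature == "exon", , drop = FALSE],
                                      iv$gene_id[iv$feature == "exon"]),
                                .derive_introns))
  iv <- rbind(iv, intr)
  rownames(iv) <- NULL
  list(genes = genes[, c("gene_id", "chrom", "strand", "tss", "start", "end")],
       intervals = iv)
}

.read_bed12_models <- function(path) {
  b <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                         comment.char = "#")
  if (ncol(b) < 12L) stop("BED12 requires 12 columns, found ", ncol(b))
  names(b)[1:12] <- c("chrom", "start0", "end", "gene_id", "score", "strand",
                      "thick_start0", "thick_end", "rgb", "n_blocks",
                      "block_sizes", "block_starts")
  if (any(!b$strand %in% c("+", "-")))
    stop("gene(s) without strand in BED12: ",
         paste(b$gene_id[!b$strand %in% c("+", "-")], collapse = ", "))
  genes <- data.frame(gene_id = b$gene_id, chrom = b$chrom, strand = b$strand,
                      tss = ifelse(b$strand == "+", b$start0 + 1L, b$end),
                      start = b$start0 + 1L, end = b$end,
                      stringsAsFactors = FALSE)
  iv <- vector("list", nrow(b))
  for (i in seq_len(nrow(b))) {
    sizes <- as.integer(strsplit(b$block_sizes[i], ",")[[1]])
    offs <- as.integer(strsplit(b$block_starts[i], ",")[[1]])
    ex_s <- b$start0[i] + offs + 1L       # 1-based closed
    ex_e <- ex_s + sizes - 1L
    ts <- b$thick_start0[i] + 1L; te <- b$thick_end[i]
    rows <- list()
    for (k in seq_along(sizes)) {
      s <- ex_s[k]; e <- ex_e[k]
      segs <- list()
      if (te >= ts) {  # coding gene: split exon on the thick region
        if (s < ts) segs <- c(segs, list(c(s, min(e, ts - 1L), 1L)))
        cs <- max(s, ts); ce <- min(e, te)
        if (cs <= ce) segs <- c(segs, list(c(cs, ce, 2L)))
        if (e > te) segs <- c(segs, list(c(max(s, te + 1L), e, 3L)))
      } else segs <- list(c(s, e, 2L))
      rows <- c(rows, segs)
    }
    m <- do.call(rbind, rows)
    left_lab <- if (b$strand[i] == "+") "5UTR" else "3UTR"
    right_lab <- if (b$strand[i] == "+") "3UTR" else "5UTR"
    feat <- c(left_lab, "exon", right_lab)[m[, 3]]
    exdf <- data.frame(gene_id = b$gene_id[i], start = ex_s, end = ex_e,
                       feature = "exon", stringsAsFactors = FALSE)
    utr <- data.frame(gene_id = b$gene_id[i], start = m[, 1], end = m[, 2],
                      feature = feat, stringsAsFactors = FALSE)
    utr <- utr[utr$feature != "exon", , drop = FALSE]
    iv[[i]] <- rbind(exdf, utr, .derive_introns(exdf))
  }
  iv <- do.call(rbind, iv)
  rownames(iv) <- NULL
  list(genes = genes, intervals = iv)
}

#' @export
print.gene_models <- function(x, ...) {
  cat("Gene models:", nrow(x$genes), "genes on",
      length(unique(x$genes$chrom)), "chromosome(s);",
      nrow(x$intervals), "feature intervals\n")
  invisible(x)
}

.eqtl_cols <- c("snp", "gene", "class", "beta", "tstat", "pvalue", "fdr",
                "confidence")

#' Construct an eQTL table
#'
#' @param df data.frame with columns snp, gene, class, beta, tstat, pvalue,
#'   fdr, confidence (and optionally distance).
#' @return an \code{eqtl_table} (a classed data.frame).
#' @export
eqtl_table <- function(df) {
  miss <- setdiff(.eqtl_cols, names(df))
  if (length(miss)) stop("missing eQTL table columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(df) && any(!df$class %in% c("cis", "trans")))
    stop("class must be 'cis' or 'trans'")
  class(df) <- c("eqtl_table", "data.frame")
  df
}

#' Write an eQTL table to TSV (canonical order, full precision)
#'
#' Rows are sorted by (gene, fdr, snp) so output is byte-stable; numeric
#' fields are written with 17 significant digits so the table round-trips
#' exactly. Non-finite statistics are refused.
#'
#' @param table an \code{eqtl_table}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_eqtl_table <- function(table, path) {
  stopifnot(inherits(table, "eqtl_table"))
  num <- c("beta", "tstat", "pvalue", "fdr")
  if (nrow(table)) {
    bad <- !Reduce(`&`, lapply(table[num], is.finite))
    if (any(bad))
      stop("non-finite statistic in row(s): ",
           paste(utils::head(which(bad), 5), collapse = ", "),
           " (snp ", table$snp[which(bad)[1]], ", gene ",
           table$gene[which(bad)[1]], ")")
    table <- table[order(table$gene, table$fdr, table$snp), , drop = FALSE]
  }
  out <- data.frame(snp = table$snp, gene = table$gene, class = table$class,
                    beta = sprintf("%.17g", table$beta),
                    tstat = sprintf("%.17g", table$tstat),
                    pvalue = sprintf("%.17g", table$pvalue),
                    fdr = sprintf("%.17g", table$fdr),
                    confidence = table$confidence,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an eQTL table written by \code{\link{write_eqtl_table}}
#'
#' @param path TSV file with the fixed header.
#' @return an \code{eqtl_table}.
#' @export
read_eqtl_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character", "character",
                                         "numeric", "numeric", "numeric",
                                         "numeric", "character"),
                          stringsAsFactors = FALSE)
  if (!identical(names(df), .eqtl_cols))
    stop("unexpected eQTL table header: ", paste(names(df), collapse = " "))
  eqtl_table(df)
}

#' Write a genotype matrix as a plain-text VCF 4.2 file
#'
#' Minimal writer for simulated cohorts: GT-only FORMAT, phased separators
#' when haplotypes are available.
#'
#' @param genotypes a \code{genotype_matrix}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_vcf <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", genotypes$samples), collapse = "\t")),
             con)
  sep <- if (isTRUE(genotypes$phased)) "|" else "/"
  n_s <- nrow(genotypes$snps)
  if (isTRUE(genotypes$phased)) {
    a1 <- genotypes$haplotypes$h1; a2 <- genotypes$haplotypes$h2
  } else {
    d <- genotypes$dosage
    a1 <- (d == 2) + 0L; a2 <- (d >= 1) + 0L
    a1[is.na(d)] <- NA; a2[is.na(d)] <- NA
  }
  gt <- matrix(paste(a1, a2, sep = sep), nrow = nrow(a1))
  gt[is.na(a1)] <- paste(".", ".", sep = sep)
  lines <- vapply(seq_len(n_s), function(j) {
    paste(c(genotypes$snps$chrom[j], genotypes$snps$pos[j],
            genotypes$snps$id[j], genotypes$snps$ref[j],
            genotypes$snps$alt[j], ".", "PASS", ".", "GT", gt[, j]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

#' Write/read a count matrix as TSV (genes x samples)
#' @param counts integer matrix with gene rownames and sample colnames.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  if (any(m < 0, na.rm = TRUE)) stop("negative counts in ", path)
  m
}

#' @export
print.eqtl_table <- function(x, n = 6L, ...) {
  cat("eQTL table:", nrow(x), "records (",
      sum(x$class == "cis"), "cis /", sum(x$class == "trans"), "trans )\n")
  thr <- attr(x, "fdr_threshold")
  if (!is.null(thr))
    cat("  significant at FDR <", thr, ":", sum(x$fdr < thr), "\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), n))
  invisible(x)
}

#' @export
summary.eqtl_table <- function(object, fdr_threshold = NULL, ...) {
  thr <- fdr_threshold %||% attr(object, "fdr_threshold") %||% 0.05
  sig <- object[object$fdr < thr, , drop = FALSE]
  out <- list(
    n = nrow(object), n_cis = sum(object$class == "cis"),
    n_trans = sum(object$class == "trans"), fdr_threshold = thr,
    n_sig_cis = sum(sig$class == "cis"),
    n_sig_trans = sum(sig$class == "trans"),
    confidence = table(factor(sig$confidence,
                              levels = c("high", "low", "unset"))))
  class(out) <- "summary.eqtl_table"
  out
}

#' @export
print.summary.eqtl_table <- function(x, ...) {
  cat("eQTL scan:", x$n, "tested pairs (", x$n_cis, "cis /", x$n_trans,
      "trans )\n")
  cat("significant at FDR <", x$fdr_threshold, ":", x$n_sig_cis, "cis,",
      x$n_sig_trans, "trans\n")
  cat("confidence among significant: high", x$confidence[["high"]],
      "/ low", x$confidence[["low"]],
      "/ unset", x$confidence[["unset"]], "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
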