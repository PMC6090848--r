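## Cross-treatment sharing, eSNP distance analyses, TSS-proximity
## enrichment, trans-hotspot detection, and the genic-proportion z-test.

.sig_best <- function(tab, thr = NULL) {
  thr <- thr %||% attr(tab, "fdr_threshold") %||% 0.05
  tab[tab$fdr < thr, , drop = FALSE]
}

#' Gene sharing across treatment-specific eQTL tables
#'
#' Given best-per-gene eQTL tables for several treatments (restricted to
#' significant records), counts how many genes are unique to one treatment,
#' shared by exactly two, three, ..., all treatments.
#'
#' @param sets named list of significant best-per-gene \code{eqtl_table}s.
#' @return list(counts: named vector by number of treatments, membership:
#'   gene -> treatments list).
#' @export
treatment_overlap <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2L)
  genes <- lapply(sets, function(t) unique(t$gene))
  if (length(unique(unlist(genes))) == 0L)
    stop("all treatment tables are empty")
  union_g <- unique(unlist(genes))
  membership <- lapply(union_g, function(g)
    names(sets)[vapply(genes, function(x) g %in% x, logical(1))])
  names(membership) <- union_g
  k <- lengths(membership)
  counts <- tabulate(k, nbins = length(sets))
  names(counts) <- paste0("in_", seq_along(sets), "_treatments")
  list(counts = counts, membership = membership)
}

#' -log10 p-value matrix for cross-treatment comparison
#'
#' Restricts to genes whose eQTL is significant in at least one treatment
#' and whose raw p-value is strictly below \code{raw_p_max} in every
#' treatment; values are -log10(raw p).
#'
#' @param sets named list of best-per-gene \code{eqtl_table}s (all genes,
#'   significant or not, so each treatment has a raw p per gene).
#' @param raw_p_max per-treatment raw p-value ceiling (default 1e-2,
#'   strict).
#' @param fdr_threshold significance threshold for the ">= 1 treatment"
#'   condition.
#' @return genes x treatments numeric matrix of -log10 p.
#' @export
pvalue_matrix <- function(sets, raw_p_max = 1e-2, fdr_threshold = 0.05) {
  common <- Reduce(intersect, lapply(sets, function(t) t$gene))
  if (!length(common)) stop("no genes shared across treatment tables")
  P <- sapply(sets, function(t) t$pvalue[match(common, t$gene)])
  Q <- sapply(sets, function(t) t$fdr[match(common, t$gene)])
  rownames(P) <- rownames(Q) <- common
  keep <- apply(Q < fdr_threshold, 1L, any) & apply(P < raw_p_max, 1L, all)
  -log10(P[keep, , drop = FALSE])
}

#' Null distribution of within-window SNP pair distances
#'
#' Draws \code{n_windows} uniform window starts on one chromosome and pools
#' all pairwise distances |pos_i - pos_j| between SNPs falling inside each
#' window.
#'
#' @param positions sorted SNP positions on the chromosome.
#' @param n_windows number of random windows (default 100).
#' @param window_bp window width in bp (default 2 Mb).
#' @param chrom_length chromosome length (default: max position).
#' @param seed RNG seed for the window draws.
#' @return numeric vector of pooled pair distances.
#' @export
esnp_distance_null <- function(positions, n_windows = 100, window_bp = 2e6,
                               chrom_length = max(positions), seed = 1L) {
  if (chrom_length < window_bp)
    stop("chromosome shorter than one window")
  set.seed(seed, kind = "Mersenne-Twister")
  positions <- sort(positions)
  out <- vector("list", n_windows)
  for (w in seq_len(n_windows)) {
    start <- stats::runif(1, 0, chrom_length - window_bp)
    inw <- positions[positions >= start & positions <= start + window_bp]
    if (length(inw) >= 2L) out[[w]] <- as.vector(stats::dist(inw))
  }
  unlist(out) %||% numeric(0)
}

#' Distances between best eSNPs of genes shared across all treatments
#'
#' For every gene significant in all treatments whose best eSNPs differ
#' between a pair of treatments but share a chromosome, collects
#' |posA - posB|, and compares the pooled sample to a windowed null (see
#' \code{\link{esnp_distance_null}}) by a two-sided two-sample KS test.
#'
#' @param sets named list of best-per-gene \code{eqtl_table}s.
#' @param snps SNP metadata data.frame (id, chrom, pos).
#' @param null_sample distances from \code{\link{esnp_distance_null}}.
#' @param fdr_threshold significance threshold per treatment.
#' @return list(distances, n_genes, D, p); D/p NA when fewer than 10
#'   distances were collected (with a warning).
#' @export
shared_gene_esnp_distances <- function(sets, snps, null_sample,
                                       fdr_threshold = 0.05) {
  sig <- lapply(sets, .sig_best, thr = fdr_threshold)
  shared <- Reduce(intersect, lapply(sig, function(t) t$gene))
  dists <- numeric(0); n_genes <- 0L
  combs <- utils::combn(length(sets), 2L)
  for (g in shared) {
    ids <- vapply(sig, function(t) t$snp[match(g, t$gene)], character(1))
    got <- FALSE
    for (k in seq_len(ncol(combs))) {
      a <- ids[combs[1L, k]]; b <- ids[combs[2L, k]]
      if (a == b) next
      ia <- match(a, snps$id); ib <- match(b, snps$id)
      if (snps$chrom[ia] != snps$chrom[ib]) next
      dists <- c(dists, abs(snps$pos[ia] - snps$pos[ib]))
      got <- TRUE
    }
    if (got) n_genes <- n_genes + 1L
  }
  if (length(dists) < 10L) {
    warning("fewer than 10 eSNP distances; KS test skipped")
    return(list(distances = dists, n_genes = n_genes, D = NA_real_,
                p = NA_real_))
  }
  ks <- suppressWarnings(stats::ks.test(dists, null_sample))
  list(distances = dists, n_genes = n_genes,
       D = unname(ks$statistic), p = ks$p.value)
}

#' TSS-proximity enrichment of cis eSNPs
#'
#' Signed distances snp position - gene TSS for a best-per-gene cis table,
#' tested against the Uniform(-cis_dist, +cis_dist) reference by a
#' one-sample KS test. A concentration of eSNPs near the TSS yields a
#' large D and a small p.
#'
#' @param cis_table best-per-gene cis \code{eqtl_table} (high-confidence
#'   records recommended).
#' @param genes a \code{gene_models} object.
#' @param snps SNP metadata data.frame (id, chrom, pos).
#' @param cis_dist the scan's cis window half-width.
#' @return list(distances, D, p).
#' @export
tss_enrichment <- function(cis_table, genes, snps, cis_dist = 1e6) {
  stopifnot(nrow(cis_table) > 0)
  pos <- snps$pos[match(cis_table$snp, snps$id)]
  tss <- genes$genes$tss[match(cis_table$gene, genes$genes$gene_id)]
  d <- pos - tss
  if (any(abs(d) > cis_dist))
    stop("record(s) outside the cis window: classification bug upstream")
  ks <- suppressWarnings(
    stats::ks.test(d, "punif", -cis_dist, cis_dist))
  list(distances = d, D = unname(ks$statistic), p = ks$p.value)
}

#' Trans regulatory hotspot detection
#'
#' Counts, per SNP, the genes it regulates in trans (best-per-gene input so
#' counts sum to the number of records), and tests each SNP's count for
#' enrichment against proportional allocation across tag SNPs with a
#' binomial test (success probability 1 / number of tags; under allocation
#' proportional to per-bin tag density the bin term cancels, leaving the
#' per-tag uniform rate). Records are sorted by descending target count.
#'
#' @param trans_table best-per-gene trans \code{eqtl_table} (significant,
#'   high-confidence records recommended).
#' @param tag_snps SNP metadata data.frame (id, chrom, pos) of all tag SNPs
#'   that entered the scan.
#' @param bin_bp bin width for the reported local tag density.
#' @param alpha family-wise threshold; per-SNP calls use alpha / n tested
#'   (Bonferroni).
#' @return data.frame (snp, trans_gene_count, background_density,
#'   enrichment_p, hotspot) sorted by count, with target gene lists in
#'   attribute "targets".
#' @export
trans_hotspots <- function(trans_table, tag_snps, bin_bp = 1e6,
                           alpha = 0.05) {
  stopifnot(nrow(trans_table) > 0)
  counts <- table(trans_table$snp)
  N <- nrow(trans_table)
  p0 <- 1 / nrow(tag_snps)
  ids <- names(counts)
  idx <- match(ids, tag_snps$id)
  dens <- vapply(seq_along(ids), function(k) {
    i <- idx[k]
    if (is.na(i)) return(NA_integer_)
    bin <- floor(tag_snps$pos[i] / bin_bp)
    sum(tag_snps$chrom == tag_snps$chrom[i] &
          floor(tag_snps$pos / bin_bp) == bin)
  }, integer(1))
  pvals <- vapply(as.integer(counts), function(x)
    stats::binom.test(x, N, p0, alternative = "greater")$p.value, numeric(1))
  out <- data.frame(snp = ids, trans_gene_count = as.integer(counts),
                    background_density = dens, enrichment_p = pvals,
                    stringsAsFactors = FALSE)
  out$hotspot <- out$enrichment_p < alpha / nrow(out)
  o <- order(-out$trans_gene_count, out$enrichment_p, out$snp)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "targets") <- split(trans_table$gene, trans_table$snp)[out$snp]
  out
}

.genic_hits <- function(pos, chrom, genes) {
  iv <- genes$intervals
  gchrom <- genes$genes$chrom[match(iv$gene_id, genes$genes$gene_id)]
  vapply(seq_along(pos), function(k) {
    any(gchrom == chrom[k] & iv$start <= pos[k] & iv$end >= pos[k])
  }, logical(1))
}

#' Two-proportion z-test on genic eSNP fractions
#'
#' An eSNP is genic iff its position falls in any 5'UTR/exon/intron/3'UTR
#' interval of any gene. Compares the genic proportion of cis eSNPs with
#' that of trans eSNPs using the pooled-variance two-proportion z statistic
#' (no continuity correction), two-sided.
#'
#' @param cis_table,trans_table best-per-gene \code{eqtl_table}s.
#' @param genes a \code{gene_models} object.
#' @param snps SNP metadata data.frame (id, chrom, pos).
#' @return list(prop_cis, prop_trans, n_cis, n_trans, z, p).
#' @export
genic_proportion_ztest <- function(cis_table, trans_table, genes, snps) {
  get_prop <- function(tab) {
    i <- match(tab$snp, snps$id)
    hits <- .genic_hits(snps$pos[i], snps$chrom[i], genes)
    c(x = sum(hits), n = length(hits))
  }
  a <- get_prop(cis_table); b <- get_prop(trans_table)
  if (a["n"] == 0L || b["n"] == 0L) stop("empty eSNP set")
  two_proportion_z(a["x"], a["n"], b["x"], b["n"])
}

#' Pooled two-proportion z-test
#'
#' @param x1,n1 successes and trials in group 1.
#' @param x2,n2 successes and trials in group 2.
#' @return list(prop_cis = x1/n1, prop_trans = x2/n2, n_cis, n_trans, z,
#'   p): z = (p1 - p2) / sqrt(pp (1-pp) (1/n1 + 1/n2)) with pooled pp,
#'   two-sided normal p.
#' @export
two_proportion_z <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  p <- if (se == 0) 1 else 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  list(prop_cis = unname(p1), prop_trans = unname(p2),
       n_cis = unname(n1), n_trans = unname(n2), z = unname(z), p = p)
}
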