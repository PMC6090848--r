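## Allele statistics, haplotype LD and greedy windowed tag-SNP selection.

#' Haplotype linkage disequilibrium between two sites
#'
#' From two aligned binary haplotype vectors computes the linkage
#' coefficient D = pAB - pA pB, its normalized form D' = D / Dmax (with the
#' standard sign-dependent Dmax), and the squared haplotype correlation
#' r2 = D^2 / (pA qA pB qB).
#'
#' @param hapA,hapB binary (0/1) haplotype vectors of equal length >= 2.
#' @return an \code{ld_result}: list(D, Dprime, r2, hap_counts) where
#'   hap_counts is the 2x2 table of haplotype counts (AB, Ab, aB, ab with
#'   "A"/"B" the 1 alleles).
#' @export
haplotype_ld <- function(hapA, hapB) {
  stopifnot(length(hapA) == length(hapB), length(hapA) >= 2L)
  pA <- mean(hapA); pB <- mean(hapB)
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    stop("monomorphic site: LD undefined")
  pAB <- mean(hapA == 1 & hapB == 1)
  D <- pAB - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
  else min(pA * pB, (1 - pA) * (1 - pB))
  dprime <- if (dmax == 0) 0 else D / dmax
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  hc <- matrix(c(sum(hapA == 1 & hapB == 1), sum(hapA == 1 & hapB == 0),
                 sum(hapA == 0 & hapB == 1), sum(hapA == 0 & hapB == 0)),
               2L, 2L, byrow = TRUE,
               dimnames = list(A = c("1", "0"), B = c("1", "0")))
  out <- list(D = D, Dprime = dprime, r2 = r2, hap_counts = hc)
  class(out) <- "ld_result"
  out
}

#' @export
print.ld_result <- function(x, ...) {
  cat(sprintf("LD: D = %.4g, D' = %.4g, r2 = %.4g\n", x$D, x$Dprime, x$r2))
  invisible(x)
}

#' Greedy windowed tag-SNP selection
#'
#' Restricted to SNPs with MAF > \code{maf_min}, repeatedly picks (per
#' chromosome) the untagged SNP that covers the most untagged SNPs at
#' haplotype r2 >= \code{r2_threshold} within +/- \code{window_bp} of its
#' position (ties broken by lowest position), until every SNP is a tag or
#' covered by one.
#'
#' @param genos a phased \code{genotype_matrix}.
#' @param window_bp coverage window half-width anchored on the tag.
#' @param r2_threshold minimum haplotype r2 for a tag to represent a SNP.
#' @param maf_min minimum MAF for participation.
#' @return a \code{tag_set}: list(tags, represented (tag -> covered SNP
#'   ids, tag included), window_bp, r2_threshold).
#' @export
select_tag_snps <- function(genos, window_bp = 100000, r2_threshold = 0.99,
                            maf_min = 0.05) {
  stopifnot(inherits(genos, "genotype_matrix"))
  if (!isTRUE(genos$phased) || is.null(genos$haplotypes))
    stop("tag selection requires phased haplotypes; phase the input or ",
         "use a dosage-r2 fallback")
  snps <- genos$snps
  elig <- snps$maf > maf_min
  tags <- character(0); represented <- list()
  H <- rbind(genos$haplotypes$h1, genos$haplotypes$h2)
  for (chrom in unique(snps$chrom)) {
    idx <- which(elig & snps$chrom == chrom)
    if (!length(idx)) next
    pos <- snps$pos[idx]
    ids <- snps$id[idx]
    hc <- H[, idx, drop = FALSE]
    r2 <- suppressWarnings(stats::cor(hc))^2
    r2[is.na(r2)] <- 0
    inwin <- abs(outer(pos, pos, "-")) <= window_bp
    cover <- (r2 >= r2_threshold) & inwin
    diag(cover) <- TRUE
    untagged <- rep(TRUE, length(idx))
    while (any(untagged)) {
      gain <- colSums(cover & untagged)
      gain[!untagged] <- -1L  # only untagged SNPs may become tags
      best <- which(gain == max(gain))
      best <- best[which.min(pos[best])]
      members <- which(cover[, best] & untagged)
      tags <- c(tags, ids[best])
      represented[[ids[best]]] <- ids[members]
      untagged[members] <- FALSE
    }
  }
  out <- list(tags = tags, represented = represented,
              window_bp = window_bp, r2_threshold = r2_threshold)
  class(out) <- "tag_set"
  out
}

#' @export
print.tag_set <- function(x, ...) {
  cat("Tag set:", length(x$tags), "tags covering",
      length(unlist(x$represented)), "SNPs (r2 >=", x$r2_threshold,
      "within +/-", x$window_bp, "bp)\n")
  invisible(x)
}
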