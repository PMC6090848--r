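#' Configuration for the synthetic eQTL cohort generator
#'
#' Bundles every tunable of the simulator: cohort composition (two half-sib
#' families plus unrelated individuals), marker map and linkage
#' disequilibrium, the negative-binomial expression model with planted
#' additive cis effects, a trans regulatory hotspot, latent batch factors,
#' low-expression noise genes, planted outlier individuals, and a binary
#' disease phenotype partially driven by a few SNPs.
#'
#' Defaults mirror the cohort the pipeline was designed around: 82
#' individuals (50 unrelated, a 17-offspring and a 15-offspring half-sib
#' family), dense SNPs in moderate LD, and a handful of planted cis effects.
#'
#' @param n_unrelated,n_fam1,n_fam2 cohort composition (counts).
#' @param n_chroms number of autosomes to simulate.
#' @param n_snps SNPs per chromosome (>= 2).
#' @param chrom_length chromosome length in bp.
#' @param ld_decay probability that a founder haplotype copies the previous
#'   site's allele; 0 gives independent sites, values near 1 give strong
#'   adjacent-site LD (approximately r ~ ld_decay between neighbours).
#' @param maf_min,maf_max bounds of the target alternate-allele frequency
#'   spectrum.
#' @param n_genes number of expressed genes.
#' @param n_noise_genes number of low-expression "noise" genes (baseline
#'   mean below ~5 counts) whose values are sequencing noise.
#' @param nb_dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param baseline_mean median baseline count of expressed genes.
#' @param sf_sd log-normal SD of per-sample library size factors.
#' @param n_cis_effects number of cis eQTLs planted automatically when
#'   \code{cis_effects} is NULL.
#' @param cis_fold fold change in expression per alternate allele for
#'   auto-planted cis effects.
#' @param cis_maf_min minimum MAF for auto-chosen causal cis SNPs.
#' @param cis_effects explicit data.frame (snp, gene, fold) of planted cis
#'   effects, or NULL to auto-plant.
#' @param cis_tss_sd NULL for uniform placement of auto-planted causal SNPs
#'   within the cis window, or a bp standard deviation: candidate SNPs are
#'   then sampled with Gaussian weight on their TSS distance, emulating the
#'   promoter-proximal concentration of real cis-regulatory variants.
#' @param hotspot NULL, or list(n_targets, fold, snp = NULL) describing a
#'   trans regulatory hotspot: one SNP additively regulating
#'   \code{n_targets} genes genome-wide.
#' @param n_batch_factors number of latent batch factors.
#' @param batch_affect_frac fraction of genes loaded on each batch factor.
#' @param batch_loading log-scale loading magnitude of affected genes.
#' @param outliers NULL, or data.frame (sample, gene, multiplier) of planted
#'   multiplicative expression spikes.
#' @param pheno_snps NULL, or data.frame (snp, beta) of log-odds-per-allele
#'   effects on disease status.
#' @param pheno_intercept baseline log-odds of disease.
#' @param fam_offsets length-2 log-odds offsets for family 1 and family 2
#'   membership (creates the confounding the Fam1/Fam2 covariates must
#'   absorb).
#' @param seed integer seed; mandatory, all outputs are deterministic in it.
#'
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(n_unrelated = 50, n_fam1 = 17, n_fam2 = 15,
                       n_chroms = 2, n_snps = 300, chrom_length = 1e7,
                       ld_decay = 0.9, maf_min = 0.05, maf_max = 0.5,
                       n_genes = 150, n_noise_genes = 50,
                       nb_dispersion = 0.1, baseline_mean = 200, sf_sd = 0.15,
                       n_cis_effects = 15, cis_fold = 1.5, cis_maf_min = 0.2,
                       cis_effects = NULL, cis_tss_sd = NULL,
                       hotspot = NULL,
                       n_batch_factors = 0, batch_affect_frac = 0.5,
                       batch_loading = 0.5,
                       outliers = NULL,
                       pheno_snps = NULL, pheno_intercept = 0,
                       fam_offsets = c(0.5, -0.5),
                       seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' is mandatory and must be a single integer")
  counts <- c(n_unrelated, n_fam1, n_fam2, n_chroms, n_snps,
              n_genes, n_noise_genes)
  if (any(counts < 0)) stop("all counts must be >= 0")
  if (n_snps < 2) stop("need at least 2 SNPs per chromosome")
  if (!is.null(cis_effects) && any(cis_effects$fold <= 0))
    stop("fold changes must be > 0")
  if (ld_decay < 0 || ld_decay >= 1) stop("ld_decay must be in [0, 1)")
  cfg <- list(
    n_unrelated = n_unrelated, n_fam1 = n_fam1, n_fam2 = n_fam2,
    n_chroms = n_chroms, n_snps = n_snps, chrom_length = chrom_length,
    ld_decay = ld_decay, maf_min = maf_min, maf_max = maf_max,
    n_genes = n_genes, n_noise_genes = n_noise_genes,
    nb_dispersion = nb_dispersion, baseline_mean = baseline_mean,
    sf_sd = sf_sd,
    n_cis_effects = n_cis_effects, cis_fold = cis_fold,
    cis_maf_min = cis_maf_min, cis_effects = cis_effects,
    cis_tss_sd = cis_tss_sd,
    hotspot = hotspot,
    n_batch_factors = n_batch_factors,
    batch_affect_frac = batch_affect_frac, batch_loading = batch_loading,
    outliers = outliers,
    pheno_snps = pheno_snps, pheno_intercept = pheno_intercept,
    fam_offsets = fam_offsets,
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

## Founder haplotypes: first-order Markov copy chain along each chromosome.
## H[i, s] = H[i, s-1] with probability ld_decay, else a fresh Bernoulli
## draw at the site's target frequency.  Adjacent-site allele correlation is
## approximately ld_decay.
.founder_haplotypes <- function(n_hap, freqs, ld_decay) {
  S <- length(freqs)
  H <- matrix(0L, n_hap, S)
  H[, 1L] <- stats::rbinom(n_hap, 1L, freqs[1L])
  if (S > 1L) {
    copy <- matrix(stats::runif(n_hap * (S - 1L)) < ld_decay, n_hap, S - 1L)
    fresh <- matrix(stats::rbinom(n_hap * (S - 1L), 1L,
                                  rep(freqs[-1L], each = n_hap)),
                    n_hap, S - 1L)
    for (s in 2:S)
      H[, s] <- ifelse(copy[, s - 1L], H[, s - 1L], fresh[, s - 1L])
  }
  H
}

## Single uniform crossover per chromosome per meiosis.
.gamete <- function(hap1, hap2, positions, chrom_length) {
  brk <- stats::runif(1L, 0, chrom_length)
  first <- sample(c(TRUE, FALSE), 1L)
  left <- positions <= brk
  out <- integer(length(positions))
  if (first) { out[left] <- hap1[left]; out[!left] <- hap2[!left] }
  else       { out[left] <- hap2[left]; out[!left] <- hap1[!left] }
  out
}

#' Simulate phased genotypes for a two-family outbred cohort
#'
#' Founder haplotypes are drawn with first-order autocorrelation
#' \code{ld_decay} along each chromosome; half-sib offspring receive one
#' recombinant gamete (single uniform crossover) from their family's shared
#' sire and one fresh founder haplotype from an unrelated dam; unrelated
#' individuals receive two fresh founder haplotypes. Dosage is the haplotype
#' sum.
#'
#' @param config a \code{\link{sim_config}}.
#' @return a \code{genotype_matrix}: list with \code{snps} (data.frame id,
#'   chrom, pos, ref, alt, maf), \code{samples}, \code{cohort}
#'   ("unrelated"/"fam1"/"fam2" per sample), \code{dosage} (samples x SNPs),
#'   \code{phased = TRUE} and \code{haplotypes} (list of two binary
#'   matrices).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed, kind = "Mersenne-Twister")
  n_u <- config$n_unrelated; n_f1 <- config$n_fam1; n_f2 <- config$n_fam2
  n <- n_u + n_f1 + n_f2
  samples <- c(sprintf("U%03d", seq_len(n_u)),
               sprintf("F1_%02d", seq_len(n_f1)),
               sprintf("F2_%02d", seq_len(n_f2)))
  cohort <- rep(c("unrelated", "fam1", "fam2"), c(n_u, n_f1, n_f2))
  names(cohort) <- samples

  snp_list <- list(); h1_list <- list(); h2_list <- list()
  for (cc in seq_len(config$n_chroms)) {
    S <- config$n_snps
    pos <- sort(sample.int(config$chrom_length, S))
    freqs <- stats::runif(S, config$maf_min, config$maf_max)
    ## founders: two haplotypes per unrelated, two per sire, one fresh dam
    ## gamete per offspring
    n_hap <- 2L * n_u + 4L + n_f1 + n_f2
    H <- .founder_haplotypes(n_hap, freqs, config$ld_decay)
    h1 <- matrix(0L, n, S); h2 <- matrix(0L, n, S)
    idx <- 0L
    for (i in seq_len(n_u)) {
      h1[i, ] <- H[idx + 1L, ]; h2[i, ] <- H[idx + 2L, ]; idx <- idx + 2L
    }
    sire1 <- H[idx + (1:2), , drop = FALSE]
    sire2 <- H[idx + (3:4), , drop = FALSE]
    idx <- idx + 4L
    for (i in seq_len(n_f1)) {
      r <- n_u + i
      h1[r, ] <- .gamete(sire1[1, ], sire1[2, ], pos, config$chrom_length)
      h2[r, ] <- H[idx + i, ]
    }
    idx <- idx + n_f1
    for (i in seq_len(n_f2)) {
      r <- n_u + n_f1 + i
      h1[r, ] <- .gamete(sire2[1, ], sire2[2, ], pos, config$chrom_length)
      h2[r, ] <- H[idx + i, ]
    }
    chrom <- as.character(cc)
    snp_list[[cc]] <- data.frame(
      id = sprintf("snp.%s.%d", chrom, pos), chrom = chrom, pos = pos,
      ref = "A", alt = "G", stringsAsFactors = FALSE)
    h1_list[[cc]] <- h1; h2_list[[cc]] <- h2
  }
  snps <- do.call(rbind, snp_list)
  h1 <- do.call(cbind, h1_list); h2 <- do.call(cbind, h2_list)
  dimnames(h1) <- dimnames(h2) <- list(samples, snps$id)
  dosage <- h1 + h2
  af <- colMeans(dosage) / 2
  snps$maf <- pmin(af, 1 - af)
  g <- list(snps = snps, samples = samples, cohort = cohort,
            dosage = dosage, phased = TRUE,
            haplotypes = list(h1 = h1, h2 = h2))
  class(g) <- "genotype_matrix"
  g
}

#' Simulate gene models along the simulated chromosomes
#'
#' Places genes (expressed first, then noise genes) at random positions,
#' alternating strand at random, each with a simple multi-exon structure
#' (5'UTR, exons, introns, 3'UTR) so genic-overlap analyses have substrate.
#'
#' @param config a \code{\link{sim_config}}.
#' @return a \code{gene_models} object (see \code{\link{read_gene_models}}).
#' @export
simulate_gene_models <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 10L, kind = "Mersenne-Twister")
  n_tot <- config$n_genes + config$n_noise_genes
  chrom <- as.character(sample.int(config$n_chroms, n_tot, replace = TRUE))
  span <- sample(8000:40000, n_tot, replace = TRUE)
  start <- vapply(span, function(s)
    sample.int(config$chrom_length - s, 1L), integer(1))
  strand <- sample(c("+", "-"), n_tot, replace = TRUE)
  ids <- sprintf("gene%04d", seq_len(n_tot))
  genes <- data.frame(gene_id = ids, chrom = chrom, strand = strand,
                      tss = ifelse(strand == "+", start, start + span),
                      start = start, end = start + span,
                      stringsAsFactors = FALSE)
  iv <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    ## three exons separated by introns, UTRs at the transcript ends
    s <- start[i]; e <- start[i] + span[i]
    b <- sort(sample(seq(s + 500, e - 500, by = 100), 4L))
    ex <- rbind(c(s, b[1]), c(b[2], b[3]), c(b[4], e))
    utr5 <- if (strand[i] == "+") c(s, s + 200) else c(e - 200, e)
    utr3 <- if (strand[i] == "+") c(e - 200, e) else c(s, s + 200)
    iv[[i]] <- data.frame(
      gene_id = ids[i],
      start = c(utr5[1], ex[, 1], c(ex[1, 2] + 1, ex[2, 2] + 1), utr3[1]),
      end = c(utr5[2], ex[, 2], c(ex[2, 1] - 1, ex[3, 1] - 1), utr3[2]),
      feature = c("5UTR", "exon", "exon", "exon", "intron", "intron", "3UTR"),
      stringsAsFactors = FALSE)
  }
  gm <- list(genes = genes, intervals = do.call(rbind, iv))
  class(gm) <- "gene_models"
  gm
}

.pick_cis_effects <- function(genotypes, genes, config) {
  set.seed(config$seed + 20L, kind = "Mersenne-Twister")
  ge <- genes$genes[seq_len(config$n_genes), , drop = FALSE]
  sn <- genotypes$snps
  eligible <- sn[sn$maf >= config$cis_maf_min, , drop = FALSE]
  out <- list()
  pool <- sample(nrow(ge))
  for (gi in pool) {
    cand <- eligible[eligible$chrom == ge$chrom[gi] &
                       abs(eligible$pos - ge$tss[gi]) <= 1e6, , drop = FALSE]
    if (nrow(cand) == 0L) next
    w <- if (is.null(config$cis_tss_sd)) rep(1, nrow(cand))
    else stats::dnorm(cand$pos - ge$tss[gi], 0, config$cis_tss_sd) + 1e-12
    out[[length(out) + 1L]] <- data.frame(
      snp = cand$id[sample.int(nrow(cand), 1L, prob = w)],
      gene = ge$gene_id[gi], fold = config$cis_fold,
      stringsAsFactors = FALSE)
    if (length(out) >= config$n_cis_effects) break
  }
  if (length(out) == 0L) return(NULL)
  do.call(rbind, out)
}

#' Simulate a negative-binomial expression count matrix with planted effects
#'
#' Gene/sample mean = baseline x size factor x fold^dosage x exp(batch
#' loading), counts drawn NB(mean, 1/dispersion). Noise genes have baseline
#' means below ~5 counts. Planted outliers are multiplicative spikes on
#' single (sample, gene) cells.
#'
#' @param genotypes a \code{genotype_matrix} from
#'   \code{\link{simulate_genotypes}}.
#' @param genes a \code{gene_models} object from
#'   \code{\link{simulate_gene_models}}.
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{counts} (integer matrix genes x samples),
#'   \code{truth} (a \code{truth_set}: cis_effects, hotspot, outliers,
#'   batch matrix) and \code{size_factors_true}.
#' @export
simulate_expression <- function(genotypes, genes, config) {
  stopifnot(inherits(config, "sim_config"),
            inherits(genotypes, "genotype_matrix"))
  cis <- config$cis_effects
  if (is.null(cis) && config$n_cis_effects > 0L)
    cis <- .pick_cis_effects(genotypes, genes, config)
  set.seed(config$seed + 30L, kind = "Mersenne-Twister")
  n <- length(genotypes$samples)
  gm <- genes$genes
  n_tot <- nrow(gm)
  n_expr <- config$n_genes
  if (n_tot != n_expr + config$n_noise_genes)
    stop("gene models do not match the configured gene counts")
  baseline <- c(stats::rlnorm(n_expr, log(config$baseline_mean), 0.8),
                stats::runif(config$n_noise_genes, 0.2, 4))
  sf <- exp(stats::rnorm(n, 0, config$sf_sd))
  logmu <- matrix(log(baseline), n_tot, n) +
    matrix(log(sf), n_tot, n, byrow = TRUE)
  rownames(logmu) <- gm$gene_id; colnames(logmu) <- genotypes$samples

  add_effect <- function(snp, gene, fold) {
    if (!snp %in% colnames(genotypes$dosage))
      stop("planted effect references unknown SNP: ", snp)
    if (!gene %in% gm$gene_id)
      stop("planted effect references unknown gene: ", gene)
    logmu[gene, ] <<- logmu[gene, ] + log(fold) * genotypes$dosage[, snp]
  }
  if (!is.null(cis))
    for (k in seq_len(nrow(cis))) add_effect(cis$snp[k], cis$gene[k], cis$fold[k])

  hotspot <- config$hotspot
  if (!is.null(hotspot)) {
    hs_snp <- hotspot$snp
    if (is.null(hs_snp)) {
      elig <- genotypes$snps$id[genotypes$snps$maf >= config$cis_maf_min]
      hs_snp <- sample(elig, 1L)
    }
    ## targets drawn across the genome, away from the hotspot's cis window
    hs_pos <- genotypes$snps$pos[match(hs_snp, genotypes$snps$id)]
    hs_chr <- genotypes$snps$chrom[match(hs_snp, genotypes$snps$id)]
    far <- gm$gene_id[seq_len(n_expr)][
      gm$chrom[seq_len(n_expr)] != hs_chr |
        abs(gm$tss[seq_len(n_expr)] - hs_pos) > 1e6]
    avoid <- if (is.null(cis)) character(0) else cis$gene
    far <- setdiff(far, avoid)
    targets <- sample(far, min(hotspot$n_targets, length(far)))
    for (g in targets) add_effect(hs_snp, g, hotspot$fold)
    hotspot <- list(snp = hs_snp, targets = targets, fold = hotspot$fold)
  }

  batch <- NULL
  if (config$n_batch_factors > 0L) {
    batch <- matrix(stats::rnorm(n * config$n_batch_factors), n)
    rownames(batch) <- genotypes$samples
    for (k in seq_len(config$n_batch_factors)) {
      hit <- stats::runif(n_tot) < config$batch_affect_frac
      load <- ifelse(hit, config$batch_loading, 0)
      logmu <- logmu + outer(load, batch[, k])
    }
  }

  mu <- exp(logmu)
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / config$nb_dispersion),
                   n_tot, n, dimnames = dimnames(mu))
  if (!is.null(config$outliers)) {
    ol <- config$outliers
    for (k in seq_len(nrow(ol)))
      counts[ol$gene[k], ol$sample[k]] <-
        as.integer(round(counts[ol$gene[k], ol$sample[k]] * ol$multiplier[k] +
                           ol$multiplier[k]))
  }
  truth <- list(cis_effects = cis, hotspot = hotspot,
                outliers = config$outliers, pheno_snps = config$pheno_snps,
                batch = batch)
  class(truth) <- "truth_set"
  list(counts = counts, truth = truth, size_factors_true = sf)
}

#' Simulate a binary disease phenotype and covariates
#'
#' Disease status is Bernoulli with logit = intercept + planted SNP effects
#' + family offsets; sex and age are drawn independently. If a draw is
#' all-case or all-control it is re-drawn up to 10 times, then an error is
#' raised.
#'
#' @param genotypes a \code{genotype_matrix}.
#' @param config a \code{\link{sim_config}}.
#' @return a covariate data.frame: sample_id, sex (0/1), age (years),
#'   fam1, fam2, status (0/1).
#' @export
simulate_phenotype <- function(genotypes, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 40L, kind = "Mersenne-Twister")
  n <- length(genotypes$samples)
  fam1 <- as.integer(genotypes$cohort == "fam1")
  fam2 <- as.integer(genotypes$cohort == "fam2")
  eta <- rep(config$pheno_intercept, n) +
    fam1 * config$fam_offsets[1] + fam2 * config$fam_offsets[2]
  if (!is.null(config$pheno_snps)) {
    ps <- config$pheno_snps
    miss <- setdiff(ps$snp, colnames(genotypes$dosage))
    if (length(miss)) stop("pheno_snps reference unknown SNPs: ",
                           paste(miss, collapse = ", "))
    for (k in seq_len(nrow(ps)))
      eta <- eta + ps$beta[k] * genotypes$dosage[, ps$snp[k]]
  }
  prob <- stats::plogis(eta)
  status <- NULL
  for (try in 1:10) {
    draw <- stats::rbinom(n, 1L, prob)
    if (length(unique(draw)) == 2L) { status <- draw; break }
    warning("degenerate phenotype draw (all one class); re-drawing")
  }
  if (is.null(status))
    stop("phenotype degenerate after 10 re-draws; check intercept/effects")
  data.frame(sample_id = genotypes$samples,
             sex = stats::rbinom(n, 1L, 0.5),
             age = round(stats::runif(n, 4, 25), 1),
             fam1 = fam1, fam2 = fam2, status = status,
             stringsAsFactors = FALSE)
}

#' Simulate a complete cohort: genotypes, gene models, counts, covariates
#'
#' Convenience wrapper running \code{\link{simulate_genotypes}},
#' \code{\link{simulate_gene_models}}, \code{\link{simulate_expression}} and
#' \code{\link{simulate_phenotype}} under one configuration.
#'
#' @param config a \code{\link{sim_config}}.
#' @return an object of class \code{eqtl_sim}: list(genotypes, genes,
#'   counts, covariates, truth).
#' @export
simulate_cohort <- function(config) {
  genotypes <- simulate_genotypes(config)
  genes <- simulate_gene_models(config)
  expr <- simulate_expression(genotypes, genes, config)
  covars <- simulate_phenotype(genotypes, config)
  out <- list(genotypes = genotypes, genes = genes, counts = expr$counts,
              covariates = covars, truth = expr$truth,
              size_factors_true = expr$size_factors_true, config = config)
  class(out) <- "eqtl_sim"
  out
}

#' @export
print.eqtl_sim <- function(x, ...) {
  cat("Simulated eQTL cohort:",
      length(x$genotypes$samples), "individuals (",
      sum(x$genotypes$cohort == "unrelated"), "unrelated,",
      sum(x$genotypes$cohort == "fam1"), "fam1,",
      sum(x$genotypes$cohort == "fam2"), "fam2 ),",
      nrow(x$genotypes$snps), "SNPs,", nrow(x$counts), "genes\n")
  if (!is.null(x$truth$cis_effects))
    cat("  planted cis effects:", nrow(x$truth$cis_effects), "\n")
  if (!is.null(x$truth$hotspot))
    cat("  trans hotspot:", x$truth$hotspot$snp, "->",
        length(x$truth$hotspot$targets), "target genes\n")
  invisible(x)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix:", length(x$samples), "samples x", nrow(x$snps),
      "SNPs;", if (isTRUE(x$phased)) "phased" else "unphased", "\n")
  cat("  chromosomes:", paste(unique(x$snps$chrom), collapse = ", "), "\n")
  invisible(x)
}
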