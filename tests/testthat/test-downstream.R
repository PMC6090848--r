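# Cross-treatment sharing, distance nulls, TSS enrichment, hotspots,
# genic z-test.

mk_tab <- function(snp, gene, p = 1e-4, fdr = 0.01, class = "cis") {
  eqtl_table(data.frame(snp = snp, gene = gene, class = class, beta = 1,
                        tstat = 5, pvalue = p, fdr = fdr,
                        confidence = "high", stringsAsFactors = FALSE))
}

test_that("treatment overlap partitions the gene union", {
  t1 <- mk_tab(c("s1", "s2"), c("gA", "gB"))
  ov_same <- treatment_overlap(list(a = t1, b = t1, c = t1, d = t1))
  expect_equal(unname(ov_same$counts), c(0, 0, 0, 2))
  t2 <- mk_tab(c("s3", "s4"), c("gC", "gD"))
  ov_disj <- treatment_overlap(list(a = t1, b = t2))
  expect_equal(unname(ov_disj$counts), c(4, 0))
  expect_equal(sum(ov_disj$counts), length(unique(c(t1$gene, t2$gene))))
})

test_that("p-value matrix filters on strict raw p and any-significance", {
  mk <- function(p, fdr) mk_tab(paste0("s", 1:3), paste0("g", 1:3),
                                p = p, fdr = fdr)
  sets <- list(
    a = mk(c(0.01, 1e-4, 1e-3), c(0.01, 0.01, 0.5)),
    b = mk(c(1e-3, 1e-4, 1e-3), c(0.01, 0.01, 0.5)))
  m <- pvalue_matrix(sets, raw_p_max = 1e-2)
  ## g1 excluded: p exactly 0.01 in treatment a (strict <)
  expect_false("g1" %in% rownames(m))
  expect_true("g2" %in% rownames(m))
  expect_equal(unname(m["g2", ]), c(4, 4))
  ## g3 excluded: significant nowhere
  expect_false("g3" %in% rownames(m))
  ## brute-force row-count oracle on random sets
  set.seed(23)
  sets2 <- lapply(1:4, function(i)
    mk_tab(paste0("s", 1:50), paste0("g", 1:50),
           p = 10^-runif(50, 0, 5), fdr = runif(50)))
  names(sets2) <- paste0("t", 1:4)
  m2 <- pvalue_matrix(sets2)
  P <- sapply(sets2, function(t) t$pvalue)
  Q <- sapply(sets2, function(t) t$fdr)
  want <- sum(apply(Q < 0.05, 1, any) & apply(P < 1e-2, 1, all))
  expect_equal(nrow(m2), want)
})

test_that("windowed distance null: exhaustive pairs and support bound", {
  ## window spans the whole chromosome -> deterministic pair set
  d <- esnp_distance_null(c(10e3, 30e3, 100e3), n_windows = 3,
                          window_bp = 2e6, chrom_length = 2e6, seed = 1)
  expect_setequal(unique(d), c(20e3, 70e3, 90e3))
  ## single SNP per window contributes nothing
  expect_length(esnp_distance_null(c(5e5), n_windows = 5, window_bp = 1e6,
                                   chrom_length = 2e6, seed = 1), 0)
  ## distances bounded by the window width
  pos <- seq(1e4, 5e7, by = 1e4)
  d2 <- esnp_distance_null(pos, n_windows = 20, window_bp = 2e6, seed = 2)
  expect_true(all(d2 <= 2e6))
  expect_true(all(d2 >= 0))
  expect_error(esnp_distance_null(c(1, 2), window_bp = 10, chrom_length = 5),
               "shorter")
})

test_that("shared-gene eSNP distances detect clustered regulation", {
  snps <- data.frame(id = sprintf("s%04d", 1:2000), chrom = "1",
                     pos = sort(sample.int(5e7, 2000)),
                     stringsAsFactors = FALSE)
  ## identical best eSNPs everywhere -> empty sample, KS skipped
  t_same <- mk_tab(snps$id[1:20], paste0("g", 1:20))
  expect_warning(
    r0 <- shared_gene_esnp_distances(list(a = t_same, b = t_same), snps,
                                     null_sample = c(1, 2, 3)),
    "fewer than 10")
  expect_length(r0$distances, 0)
  ## jittered best eSNPs near a shared locus vs a 2 Mb windowed null
  set.seed(24)
  hits <- vapply(1:5, function(s) {
    set.seed(240 + s)
    base <- sample(200:1800, 40)
    pick <- function() snps$id[base + sample(-3:3, 40, TRUE)]
    sets <- list(a = mk_tab(pick(), paste0("g", 1:40)),
                 b = mk_tab(pick(), paste0("g", 1:40)),
                 c = mk_tab(pick(), paste0("g", 1:40)))
    null <- esnp_distance_null(snps$pos, n_windows = 50, window_bp = 2e6,
                               seed = s)
    r <- shared_gene_esnp_distances(sets, snps, null)
    r$p < 0.01
  }, logical(1))
  expect_true(all(hits))
})

test_that("TSS enrichment: concentration detected, out-of-window rejected", {
  genes <- list(genes = data.frame(gene_id = paste0("g", 1:500), chrom = "1",
                                   strand = "+", tss = seq(2e6, by = 3e6,
                                                           length.out = 500),
                                   stringsAsFactors = FALSE))
  class(genes) <- "gene_models"
  set.seed(25)
  off <- pmax(pmin(rnorm(500, 0, 5e4), 1e6), -1e6)
  snps <- data.frame(id = paste0("e", 1:500), chrom = "1",
                     pos = genes$genes$tss + round(off),
                     stringsAsFactors = FALSE)
  tab <- mk_tab(snps$id, genes$genes$gene_id)
  r <- tss_enrichment(tab, genes, snps)
  expect_lt(r$p, 1e-6)
  ## all eSNPs exactly at the TSS: extreme concentration, tiny p
  snps0 <- snps; snps0$pos <- genes$genes$tss
  r0 <- tss_enrichment(tab, genes, snps0)
  expect_lt(r0$p, 1e-10)
  ## a record outside the window is a classification bug
  snps_bad <- snps; snps_bad$pos[1] <- genes$genes$tss[1] + 2e6
  expect_error(tss_enrichment(tab, genes, snps_bad), "outside")
})

test_that("hotspot counting and enrichment behave at the extremes", {
  tags <- data.frame(id = sprintf("t%04d", 1:2000), chrom = "1",
                     pos = sort(sample.int(5e7, 2000)),
                     stringsAsFactors = FALSE)
  ## every SNP regulating one gene: no hotspot
  t1 <- mk_tab(tags$id[1:50], paste0("g", 1:50), class = "trans")
  h1 <- trans_hotspots(t1, tags)
  expect_false(any(h1$hotspot))
  expect_equal(sum(h1$trans_gene_count), nrow(t1))
  ## planted 40-target hotspot among scattered background
  set.seed(26)
  bg <- mk_tab(sample(tags$id[-1], 500, TRUE), paste0("g", 1:500),
               class = "trans")
  hs <- mk_tab(rep(tags$id[1], 40), paste0("h", 1:40), class = "trans")
  h2 <- trans_hotspots(eqtl_table(rbind(bg, hs)), tags)
  expect_equal(h2$snp[1], tags$id[1])
  expect_equal(h2$trans_gene_count[1], 40L)
  expect_true(h2$hotspot[1])
  expect_equal(sum(h2$trans_gene_count), 540L)
  expect_setequal(attr(h2, "targets")[[tags$id[1]]], paste0("h", 1:40))
})

test_that("genic proportions: worked z example and interval oracle", {
  r <- two_proportion_z(40, 100, 60, 100)
  expect_equal(r$z, -2.8284, tolerance = 1e-4)
  expect_equal(r$p, 0.00468, tolerance = 1e-3)
  expect_equal(two_proportion_z(30, 100, 30, 100)$z, 0)
  expect_equal(two_proportion_z(30, 100, 30, 100)$p, 1)
  ## interval membership against a brute-force oracle
  sim <- shared_sim()
  snps <- sim$genotypes$snps
  set.seed(27)
  pick <- snps[sample(nrow(snps), 200), ]
  got <- equiqtl:::.genic_hits(pick$pos, pick$chrom, sim$genes)
  iv <- sim$genes$intervals
  ivch <- sim$genes$genes$chrom[match(iv$gene_id, sim$genes$genes$gene_id)]
  want <- vapply(seq_len(nrow(pick)), function(k) {
    hit <- FALSE
    for (j in seq_len(nrow(iv)))
      if (ivch[j] == pick$chrom[k] && iv$start[j] <= pick$pos[k] &&
          iv$end[j] >= pick$pos[k]) { hit <- TRUE; break }
    hit
  }, logical(1))
  expect_equal(got, want)
  ## end-to-end proportions use those counts
  ct <- mk_tab(pick$id[1:100], paste0("g", 1:100))
  tt <- mk_tab(pick$id[101:200], paste0("g", 101:200), class = "trans")
  rz <- genic_proportion_ztest(ct, tt, sim$genes, snps)
  expect_equal(rz$prop_cis, mean(want[1:100]))
  expect_equal(rz$prop_trans, mean(want[101:200]))
})
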