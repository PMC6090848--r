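# Shared fixture builders: all data constructed in code at test time.

# Hand-build a genotype_matrix from two haplotype matrices (samples x snps).
make_genos <- function(h1, h2, pos = NULL, chrom = "1", phased = TRUE) {
  n <- nrow(h1); S <- ncol(h1)
  if (is.null(pos)) pos <- seq_len(S) * 1000L
  samples <- sprintf("s%02d", seq_len(n))
  ids <- sprintf("snp.%s.%d", chrom, pos)
  dimnames(h1) <- dimnames(h2) <- list(samples, ids)
  dosage <- h1 + h2
  af <- colMeans(dosage) / 2
  g <- list(snps = data.frame(id = ids, chrom = chrom, pos = pos,
                              ref = "A", alt = "G", maf = pmin(af, 1 - af),
                              stringsAsFactors = FALSE),
            samples = samples, cohort = NULL, dosage = dosage,
            phased = phased,
            haplotypes = if (phased) list(h1 = h1, h2 = h2))
  class(g) <- "genotype_matrix"
  g
}

# Minimal hand-written VCF: one string per variant row, fixed 3 samples
# unless a header is supplied.
write_text_vcf <- function(body_rows, path, samples = c("s1", "s2", "s3")) {
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t"),
               body_rows), path)
  path
}

vcf_row <- function(chrom, pos, id, ref, alt, gts) {
  paste(c(chrom, pos, id, ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}

# Cohort for the KS-cutoff recovery scenario: expressed genes span a
# continuous abundance range; noise genes sit just below normalized count
# 20 at a sample-specific level (library background differs between
# samples), which is what makes the pairwise KS D sensitive to them.
make_ks_cohort <- function(seed, n = 12, n_expr = 500, n_noise = 300) {
  set.seed(seed)
  mu_expr <- stats::runif(n_expr, 25, 400)
  cm_expr <- matrix(stats::rnbinom(n_expr * n, mu = rep(mu_expr, n),
                                   size = 10), n_expr, n)
  lev <- stats::runif(n, 17, 20)
  cm_noise <- sapply(lev, function(sj)
    stats::rnbinom(n_noise, mu = sj, size = 50))
  m <- rbind(cm_expr, cm_noise)
  rownames(m) <- sprintf("g%04d", seq_len(nrow(m)))
  colnames(m) <- sprintf("s%02d", seq_len(n))
  m
}

# Textbook OLS oracle via the normal equations (independent of the scan's
# correlation identity).
ols_oracle <- function(y, g) {
  X <- cbind(1, g)
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  e <- y - X %*% beta
  n <- length(y)
  s2 <- sum(e^2) / (n - 2)
  se <- sqrt(diag(s2 * solve(XtX)))
  t <- beta[2] / se[2]
  list(beta = beta[2], t = t,
       p = 2 * stats::pt(abs(t), n - 2, lower.tail = FALSE))
}

# Logistic negative log-likelihood and gradient for the ML oracle.
logit_nll <- function(b, X, y) {
  eta <- drop(X %*% b)
  sum(log1p(exp(eta))) - sum(y * eta)
}
logit_grad <- function(b, X, y) {
  p <- stats::plogis(drop(X %*% b))
  drop(crossprod(X, p - y))
}
logit_ml_oracle <- function(X, y) {
  o <- stats::optim(rep(0, ncol(X)), logit_nll, gr = logit_grad,
                    X = X, y = y, method = "BFGS",
                    control = list(maxit = 2000, reltol = 1e-15))
  ## polish with a second, independent optimizer until the gradient
  ## vanishes (BFGS alone stalls around |grad| ~ 1e-5)
  fn <- function(b) {
    v <- logit_nll(b, X, y)
    attr(v, "gradient") <- logit_grad(b, X, y)
    v
  }
  stats::nlm(fn, o$par, gradtol = 1e-12, steptol = 1e-14,
             iterlim = 500)$estimate
}

# A small cohort with planted structure, cached per session.
.fixture_env <- new.env(parent = emptyenv())
shared_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    cfg <- sim_config(seed = 424242, n_chroms = 2, n_snps = 150,
                      n_genes = 80, n_noise_genes = 20,
                      n_cis_effects = 8, cis_fold = 1.6,
                      hotspot = list(n_targets = 15, fold = 1.8),
                      pheno_snps = NULL)
    .fixture_env$sim <- simulate_cohort(cfg)
  }
  .fixture_env$sim
}
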