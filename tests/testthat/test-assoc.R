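# Logistic GWAS, GWAS/eQTL overlap, surrogate variables,
# expression-disease association.

mk_covars <- function(n, seed = 1, status = NULL) {
  set.seed(seed)
  data.frame(sample_id = sprintf("s%03d", seq_len(n)),
             sex = rbinom(n, 1, 0.5), age = round(runif(n, 4, 25), 1),
             fam1 = rep(c(1, 0), c(n %/% 5, n - n %/% 5)),
             fam2 = rep(c(0, 1, 0), c(n %/% 5, n %/% 5, n - 2 * (n %/% 5))),
             status = if (is.null(status)) rbinom(n, 1, 0.5) else status,
             stringsAsFactors = FALSE)
}

mk_assoc_genos <- function(n, S, seed = 2, maf = 0.3) {
  set.seed(seed)
  h1 <- matrix(rbinom(n * S, 1, maf), n)
  h2 <- matrix(rbinom(n * S, 1, maf), n)
  g <- make_genos(h1, h2)
  g$samples <- sprintf("s%03d", seq_len(n))
  rownames(g$dosage) <- g$samples
  rownames(g$haplotypes$h1) <- rownames(g$haplotypes$h2) <- g$samples
  g
}

test_that("logistic scan agrees with glm and flags degenerate SNPs", {
  n <- 120
  cv <- mk_covars(n, seed = 31)
  g <- mk_assoc_genos(n, 8, seed = 32)
  g$dosage[, 3] <- 1L                      # constant dosage
  res <- logistic_scan(g, cv)
  expect_equal(nrow(res), 8L)
  flagged <- res[res$snp == g$snps$id[3], ]
  expect_false(flagged$converged)
  expect_true(is.na(flagged$pvalue))
  for (j in c(1, 2, 4)) {
    id <- g$snps$id[j]
    fit <- glm(cv$status ~ age + sex + fam1 + fam2 + g$dosage[, j],
               data = cv, family = binomial())
    sm <- summary(fit)$coefficients
    row <- res[res$snp == id, ]
    expect_equal(row$beta_g, unname(sm[6, 1]), tolerance = 1e-8)
    expect_equal(row$pvalue, unname(sm[6, 4]), tolerance = 1e-6)
  }
  ## results are ranked by p-value
  expect_true(!is.unsorted(res$pvalue[!is.na(res$pvalue)]))
})

test_that("two-parameter fits match a grid/Newton likelihood oracle", {
  set.seed(33)
  for (i in 1:10) {
    g <- rbinom(80, 2, 0.35)
    y <- rbinom(80, 1, plogis(-0.3 + 0.6 * g))
    if (length(unique(y)) < 2) next
    X <- cbind(1, g)
    f <- equiqtl:::.logistic_fit(X, y)
    if (!f$converged) next
    expect_lt(max(abs(f$coef - logit_ml_oracle(X, y))), 1e-6)
  }
})

test_that("separation is reported, not patched", {
  n <- 60
  cv <- mk_covars(n, seed = 34, status = rep(c(0, 1), each = 30))
  g <- mk_assoc_genos(n, 2, seed = 35)
  g$dosage[, 1] <- rep(c(0L, 2L), each = 30)   # perfectly separates status
  res <- logistic_scan(g, cv)
  row <- res[res$snp == g$snps$id[1], ]
  expect_false(row$converged)
  expect_true(is.na(row$pvalue))
})

test_that("scan is invariant to sample order and allele relabelling", {
  n <- 150
  cv <- mk_covars(n, seed = 36)
  g <- mk_assoc_genos(n, 5, seed = 37)
  r1 <- logistic_scan(g, cv)
  perm <- sample(n)
  g2 <- g
  g2$samples <- g$samples[perm]
  g2$dosage <- g$dosage[perm, , drop = FALSE]
  r2 <- logistic_scan(g2, cv)
  expect_equal(r1$beta_g, r2$beta_g, tolerance = 1e-8)
  g3 <- g
  g3$dosage[, 2] <- 2L - g3$dosage[, 2]        # swap allele labels
  r3 <- logistic_scan(g3, cv)
  i1 <- match(g$snps$id[2], r1$snp); i3 <- match(g$snps$id[2], r3$snp)
  expect_equal(r3$beta_g[i3], -r1$beta_g[i1], tolerance = 1e-6)
  expect_equal(r3$pvalue[i3], r1$pvalue[i1], tolerance = 1e-6)
})

test_that("GWAS/eQTL overlap joins top SNPs with significant cis records", {
  gwas <- data.frame(snp = paste0("s", 1:20), beta_g = 0, se = 1,
                     pvalue = (1:20) / 100, converged = TRUE,
                     stringsAsFactors = FALSE)
  class(gwas) <- c("gwas_result", "data.frame")
  cis <- mk_tab <- eqtl_table(data.frame(
    snp = c("s1", "s5", "s19"), gene = c("gA", "gB", "gC"), class = "cis",
    beta = 1, tstat = 5, pvalue = 1e-5, fdr = c(0.01, 0.01, 0.2),
    confidence = "high", stringsAsFactors = FALSE))
  ov <- gwas_eqtl_overlap(gwas, list(MCK = cis), top_n = 15)
  expect_setequal(ov$snp, c("s1", "s5"))       # s19 not top-15, gC not sig
  ## disjoint SNP space
  cis2 <- cis; cis2$snp <- paste0("x", 1:3)
  expect_equal(nrow(gwas_eqtl_overlap(gwas, list(MCK = cis2))), 0L)
  expect_warning(gwas_eqtl_overlap(gwas, list(MCK = cis), top_n = 50),
                 "top_n")
})

test_that("surrogate variables capture batch but protect status", {
  n <- 82
  cv <- mk_covars(n, seed = 38)
  set.seed(39)
  batch <- rnorm(n)
  load <- ifelse(runif(300) < 0.5, 1, 0)
  V <- matrix(rnorm(300 * n), 300, n) + outer(load, batch)
  colnames(V) <- cv$sample_id; rownames(V) <- sprintf("g%03d", 1:300)
  sv <- surrogate_variables(V, cv, k = 2)
  expect_gt(abs(cor(sv[, 1], batch)), 0.9)
  ## orthogonal to the protected design (status included)
  X <- cbind(1, cv$age, cv$sex, cv$fam1, cv$fam2, cv$status)
  expect_lt(max(abs(crossprod(X, sv))), 1e-6)
  ## a status-aligned signal is not captured
  V2 <- matrix(rnorm(300 * n), 300, n) + outer(load, 2 * cv$status)
  dimnames(V2) <- dimnames(V)
  sv2 <- surrogate_variables(V2, cv, k = 2)
  expect_lt(max(abs(cor(sv2, cv$status))), 0.1)
  ## k = 0 and k too large
  expect_equal(ncol(surrogate_variables(V, cv, k = 0)), 0L)
  expect_error(surrogate_variables(V, cv, k = 80), "too large")
})

test_that("expression-disease association finds planted mediation", {
  n <- 82
  hits <- vapply(1:20, function(s) {
    set.seed(400 + s)
    cv <- mk_covars(n, seed = 400 + s)
    eta <- rnorm(n, 0, 2)                       # strong linear predictor
    cv$status <- rbinom(n, 1, plogis(eta))
    if (length(unique(cv$status)) < 2) return(NA)
    expr <- eta + rnorm(n, 0, sqrt(1 / 0.3 - 1) * sd(eta))  # R2 ~ 0.3
    names(expr) <- cv$sample_id
    r <- expression_disease_assoc(expr, cv)
    isTRUE(r$pvalue < 0.05)
  }, logical(1))
  expect_gte(mean(hits, na.rm = TRUE), 0.7)
})
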