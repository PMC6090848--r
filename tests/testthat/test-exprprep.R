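# Size factors, variance-flattening transform, iterative KS cutoff,
# residualization.

test_that("size factors: symmetry, scaling algebra, brute-force oracle", {
  m <- matrix(c(10, 20, 30, 40, 10, 20, 30, 40), 4)
  dimnames(m) <- list(paste0("g", 1:4), c("a", "b"))
  expect_equal(unname(size_factors(m)), c(1, 1))
  m2 <- cbind(a = c(10, 20, 30, 40), b = c(20, 40, 60, 80))
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)))
  set.seed(3)
  m3 <- matrix(rpois(15, 50) + 1, 5, 3,
               dimnames = list(paste0("g", 1:5), paste0("s", 1:3)))
  ## direct median-of-ratios oracle
  geo <- exp(rowMeans(log(m3)))
  oracle <- apply(m3, 2, function(col) median(col / geo))
  expect_equal(unname(size_factors(m3)), unname(oracle), tolerance = 1e-12)
  ## zero row everywhere but one sample -> still fine; all-zero-ref error
  m4 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_error(size_factors(m4), "nonzero")
})

test_that("size factors agree with the DESeq2 median-of-ratios reference", {
  set.seed(4)
  m <- matrix(rnbinom(600, mu = 100, size = 5) + 1, 60, 10,
              dimnames = list(sprintf("g%02d", 1:60), sprintf("s%02d", 1:10)))
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(size_factors(m)), unname(ref), tolerance = 1e-10)
})

test_that("vst: zero maps to zero, order preserved, variance flattened", {
  m <- matrix(c(0, 3, 7, 1), 4, 1, dimnames = list(paste0("g", 1:4), "a"))
  v <- vst(m, factors = 1)
  expect_equal(v$values[1, 1], 0)
  expect_true(all(diff(v$values[order(m[, 1]), 1]) >= 0))
  expect_error(vst(matrix(-1, 1, 1)), "negative")
  ## flattening: SD-vs-mean slope shrinks at least 5x on NB data
  set.seed(5)
  mu <- exp(runif(300, log(5), log(2000)))
  cm <- matrix(rnbinom(300 * 40, mu = rep(mu, 40), size = 10), 300, 40,
               dimnames = list(sprintf("g%03d", 1:300), sprintf("s%02d", 1:40)))
  raw_slope <- coef(lm(apply(cm, 1, sd) ~ rowMeans(cm)))[2]
  vv <- vst(cm, factors = rep(1, 40))$values
  vst_slope <- coef(lm(apply(vv, 1, sd) ~ rowMeans(vv)))[2]
  expect_lt(abs(vst_slope), abs(raw_slope) / 5)
})

test_that("the KS D statistic matches ks.test, ties included", {
  set.seed(6)
  for (i in 1:20) {
    x <- sample(0:30, 40, replace = TRUE)
    y <- sample(0:30, 35, replace = TRUE)
    expect_equal(equiqtl:::ks_D(x, y),
                 unname(suppressWarnings(ks.test(x, y)$statistic)))
  }
})

test_that("pairwise KS cutoff: identical profiles flag, rules honoured", {
  x <- c(1, 5, 10, 20, 50, 100, 200, 300, 12, 18)
  r <- ks_cutoff_pair(x, x)
  expect_true(r$flagged)
  expect_equal(r$cutoff, 300)
  ## symmetry
  set.seed(7)
  a <- rnbinom(200, mu = 40, size = 5); b <- rnbinom(200, mu = 60, size = 5)
  r1 <- ks_cutoff_pair(a, b); r2 <- ks_cutoff_pair(b, a)
  expect_equal(r1$cutoff, r2$cutoff)
  expect_equal(r1$flagged, r2$flagged)
})

test_that("pairwise KS cutoff equals an independent rule-by-rule oracle", {
  grid <- seq(0, 300, by = 2)
  oracle <- function(A, B) {
    pm <- (A + B) / 2
    d <- vapply(grid, function(cut) {
      k <- pm >= cut
      if (sum(k) < 2) return(NA_real_)
      unname(suppressWarnings(ks.test(A[k], B[k])$statistic))
    }, numeric(1))
    for (i in seq_along(grid)[-length(grid)]) {
      if (is.na(d[i]) || is.na(d[i + 1])) break
      if (d[i] < d[1] && d[i] < d[i + 1] && d[i] < d[1] - 1e-4)
        return(list(cutoff = grid[i], flagged = FALSE))
    }
    list(cutoff = 300, flagged = TRUE)
  }
  set.seed(8)
  for (i in 1:15) {
    n_noise <- sample(50:150, 1)
    A <- c(rnbinom(300, mu = runif(300, 30, 300), size = 10),
           rnbinom(n_noise, mu = 18, size = 30))
    B <- c(rnbinom(300, mu = runif(300, 30, 300), size = 10),
           rnbinom(n_noise, mu = runif(1, 5, 15), size = 30))
    got <- ks_cutoff_pair(A, B, grid)
    want <- oracle(A, B)
    expect_equal(got$cutoff, want$cutoff)
    expect_equal(got$flagged, want$flagged)
  }
})

test_that("cohort KS cutoff: identical samples, pair counts, retention", {
  m <- matrix(rep(c(0, 2, 5, 20, 100, 400), 3), 6, 3,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:3)))
  r <- suppressWarnings(ks_cutoff_cohort(m))
  expect_true(all(r$flagged))
  expect_equal(r$n_pairs, 3L)
  ## all pairs flagged -> cutoff 0 -> every gene with >= 1 read retained
  expect_setequal(r$genes_retained, rownames(m)[rowSums(m) >= 1])
  ## pair count is choose(n, 2)
  m10 <- make_ks_cohort(1, n = 10)
  r10 <- suppressWarnings(ks_cutoff_cohort(m10))
  expect_equal(length(r10$pairwise_cutoffs), choose(10, 2))
})

test_that("residualize: centering, idempotence, batch factor removal", {
  sim <- shared_sim()
  ex <- vst(sim$counts)
  r0 <- residualize(ex, covariates = NULL, k_factors = 0)
  expect_equal(unname(r0$residuals),
               unname(ex$values - rowMeans(ex$values)), tolerance = 1e-10)
  expect_lt(max(abs(rowMeans(r0$residuals))), 1e-8)
  ## idempotence: a second pass with the same covariates and the same
  ## factor matrix changes nothing
  cv <- sim$covariates
  r1 <- residualize(ex, cv, k_factors = 2)
  r2 <- residualize(r1$residuals, cv, factors = r1$factors)
  expect_lt(max(abs(r2$residuals - r1$residuals)), 1e-8)
  ## planted single batch factor absorbed at k = 1
  cfgb <- sim_config(seed = 77, n_chroms = 1, n_snps = 50, n_genes = 120,
                     n_noise_genes = 0, n_cis_effects = 0,
                     n_batch_factors = 1, batch_affect_frac = 0.5,
                     batch_loading = 1)
  simb <- simulate_cohort(cfgb)
  exb <- vst(simb$counts)
  rb <- residualize(exb, simb$covariates, k_factors = 1)
  batch <- simb$truth$batch[, 1]
  cors <- abs(apply(rb$residuals, 1, function(y) cor(y, batch)))
  expect_lt(median(cors), 0.05)
  ## rank-deficient design names the collinear column
  cv2 <- cv
  cv2$dup <- cv2$sex
  expect_error(residualize(ex, cv2, 0), "collinear")
})
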