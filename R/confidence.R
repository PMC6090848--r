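## Outlier diagnostics and linear-model-assumption testing used to label
## significant eQTLs high or low confidence.

#' Leverage and Cook's distance for a simple-regression eQTL re-fit
#'
#' Re-fits residual expression on dosage and returns the per-sample hat
#' values h_i of the design [1, g] and Cook's distances
#' D_i = e_i^2 h_i / (p s^2 (1 - h_i)^2).
#'
#' @param y residual expression vector.
#' @param g dosage vector of the same length (n >= 4).
#' @return a \code{diagnostics_record}: list(leverage, cooks, n, p_coef,
#'   outlier_ids).
#' @export
refit_diagnostics <- function(y, g) {
  stopifnot(length(y) == length(g), length(y) >= 4L)
  if (stats::sd(g) == 0) stop("constant dosage: no fit")
  n <- length(y); p <- 2L
  gc_ <- g - mean(g)
  h <- 1 / n + gc_^2 / sum(gc_^2)
  b <- sum(gc_ * (y - mean(y))) / sum(gc_^2)
  e <- (y - mean(y)) - b * gc_
  s2 <- sum(e^2) / (n - p)
  cooks <- if (s2 == 0) rep(0, n) else e^2 * h / (p * s2 * (1 - h)^2)
  out <- list(leverage = h, cooks = cooks, n = n, p_coef = p,
              sample_ids = names(y))
  class(out) <- "diagnostics_record"
  out
}

#' Flag outlier individuals of an eQTL fit
#'
#' An individual is an outlier iff its Cook's distance exceeds
#' \code{cooks_max} AND its leverage exceeds 2 p / n (the conjunction). A
#' disjunction mode is available for sensitivity analysis.
#'
#' @param diag a \code{diagnostics_record}.
#' @param cooks_max Cook's distance threshold (default 0.5).
#' @param rule "and" (default) or "or".
#' @return integer indices (named when sample names are available) of
#'   flagged individuals.
#' @export
flag_outliers <- function(diag, cooks_max = 0.5, rule = c("and", "or")) {
  rule <- match.arg(rule)
  lev_thr <- 2 * diag$p_coef / diag$n
  hit <- if (rule == "and") diag$cooks > cooks_max & diag$leverage > lev_thr
  else diag$cooks > cooks_max | diag$leverage > lev_thr
  which(hit)
}

## D'Agostino (1970) transformed skewness z-score.
.skew_z <- function(x) {
  n <- length(x)
  m2 <- mean((x - mean(x))^2); m3 <- mean((x - mean(x))^3)
  g1 <- m3 / m2^1.5
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  delta * asinh(Y / alpha)
}

## Anscombe-Glynn (1983) transformed kurtosis z-score.
.kurt_z <- function(x) {
  n <- length(x)
  m2 <- mean((x - mean(x))^2); m4 <- mean((x - mean(x))^4)
  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  sb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sb1 * (2 / sb1 + sqrt(1 + 4 / sb1^2))
  z <- (b2 - eb2) / sqrt(vb2)
  (1 - 2 / (9 * A) -
      ((1 - 2 / A) / (1 + z * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))
}

## Score (n R^2) test of z added to the design X, response e (residuals).
.score_stat <- function(e, X, z) {
  rz <- stats::lm.fit(X, z)$residuals
  if (sum(rz^2) < 1e-12 * length(e)) return(0)
  r <- sum(e * rz)^2 / (sum(e^2) * sum(rz^2))
  length(e) * r
}

#' Global validation of linear-model assumptions (four-component omnibus)
#'
#' Fits y ~ g and computes four directional statistics on the residuals,
#' each referred to chi-square(1): skewness and kurtosis (moment z-scores
#' with small-sample standardization, squared), a link-function score test
#' for an added squared-fitted-value term, and a heteroscedasticity score
#' test of the squared residuals on the fitted values. The global statistic
#' is their sum, referred to chi-square(4); the fit is accepted iff the
#' global p-value exceeds \code{alpha}.
#'
#' @param y response (residual expression) vector, n >= 10.
#' @param g dosage vector.
#' @param alpha acceptance level (default 0.05).
#' @return an \code{assumption_result}: list(components (4 x stat/p
#'   data.frame), global_stat, global_p, accepted, alpha).
#' @export
assumption_omnibus <- function(y, g, alpha = 0.05) {
  stopifnot(length(y) == length(g), length(y) >= 10L)
  n <- length(y)
  X <- cbind(1, g)
  fit <- stats::lm.fit(X, y)
  e <- fit$residuals
  if (stats::var(e) < .Machine$double.eps)
    stop("degenerate residuals (zero variance)")
  s_skew <- .skew_z(e)^2
  s_kurt <- .kurt_z(e)^2
  yhat <- fit$fitted.values
  s_link <- .score_stat(e, X, yhat^2)
  ## heteroscedasticity: squared residuals on fitted values (intercept-only
  ## projection: yhat itself lies in the span of X)
  s_het <- .score_stat(e^2 - mean(e^2), matrix(1, n, 1L), yhat)
  stats_ <- c(skewness = s_skew, kurtosis = s_kurt, link_function = s_link,
              heteroscedasticity = s_het)
  comp <- data.frame(component = names(stats_), statistic = unname(stats_),
                     p = stats::pchisq(unname(stats_), 1, lower.tail = FALSE),
                     stringsAsFactors = FALSE)
  global <- sum(stats_)
  gp <- stats::pchisq(global, 4, lower.tail = FALSE)
  out <- list(components = comp, global_stat = global, global_p = gp,
              accepted = gp > alpha, alpha = alpha)
  class(out) <- "assumption_result"
  out
}

#' @export
print.assumption_result <- function(x, ...) {
  cat("Linear-model assumption omnibus (alpha =", x$alpha, ")\n")
  print(x$components, row.names = FALSE)
  cat(sprintf("global: stat = %.3f on 4 df, p = %.3g -> %s\n",
              x$global_stat, x$global_p,
              if (x$accepted) "accepted" else "NOT accepted"))
  invisible(x)
}

#' Confidence label for one eQTL
#'
#' Low confidence iff any outlier individual was flagged OR the assumption
#' omnibus was not accepted; high otherwise.
#'
#' @param outliers flagged sample indices (from \code{\link{flag_outliers}}).
#' @param omnibus an \code{assumption_result}.
#' @return "high" or "low".
#' @export
classify_confidence <- function(outliers, omnibus) {
  if (length(outliers) > 0L || !omnibus$accepted) "low" else "high"
}

#' Label significant eQTLs high or low confidence
#'
#' Re-fits every record significant at the table's FDR threshold, runs the
#' outlier diagnostics and the assumption omnibus, and fills the
#' \code{confidence} column ("high"/"low"); non-significant records keep
#' "unset".
#'
#' @param table an \code{eqtl_table} from \code{\link{eqtl_scan}}.
#' @param residuals the \code{residual_matrix} the scan used.
#' @param genos the \code{genotype_matrix} the scan used.
#' @param alpha omnibus acceptance level.
#' @param cooks_max,rule outlier rule parameters (see
#'   \code{\link{flag_outliers}}).
#' @param fdr_threshold overrides the threshold stored on the table.
#' @return the table with confidence labels, plus a per-record diagnostics
#'   data.frame in attribute "diagnostics" (snp, gene, n_outliers,
#'   global_stat, global_p).
#' @export
add_confidence <- function(table, residuals, genos, alpha = 0.05,
                           cooks_max = 0.5, rule = "and",
                           fdr_threshold = NULL) {
  stopifnot(inherits(table, "eqtl_table"))
  thr <- fdr_threshold %||% attr(table, "fdr_threshold") %||% 0.05
  R <- if (inherits(residuals, "residual_matrix")) residuals$residuals
  else residuals
  D <- .impute_dosage(genos$dosage[colnames(R), , drop = FALSE])
  sig <- which(table$fdr < thr)
  diag_rows <- vector("list", length(sig))
  for (k in seq_along(sig)) {
    i <- sig[k]
    y <- R[table$gene[i], ]; g <- D[, table$snp[i]]
    dg <- refit_diagnostics(y, g)
    fl <- flag_outliers(dg, cooks_max = cooks_max, rule = rule)
    om <- assumption_omnibus(y, g, alpha = alpha)
    table$confidence[i] <- classify_confidence(fl, om)
    diag_rows[[k]] <- data.frame(
      snp = table$snp[i], gene = table$gene[i], n_outliers = length(fl),
      global_stat = om$global_stat, global_p = om$global_p,
      stringsAsFactors = FALSE)
  }
  attr(table, "diagnostics") <- do.call(rbind, diag_rows)
  table
}
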