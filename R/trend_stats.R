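# Trend statistics applied to species-cluster traits: Pearson correlation
# with two-sided p, least-squares slope, feasible GLS under
# heteroscedasticity, exact two-sided binomial test, Benjamini-Hochberg FDR
# and 2-component PCA. All tests are two-sided.

#' Pearson trend of a trait against pH
#'
#' Product-moment correlation with the two-sided p-value from the t
#' transform on n - 2 degrees of freedom, plus the least-squares slope and
#' intercept. Requires at least three points and non-constant x and y.
#'
#' @param x Predictor (pH optima of the species clusters).
#' @param y Trait values.
#' @param trait_name Label carried into the result.
#' @return One-row data.frame of class `trend_result`: `trait_name`, `n`,
#'   `slope`, `intercept`, `pearson_r`, `p_value`, `slope_se`.
#' @export
pearson_trend <- function(x, y, trait_name = "trait") {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input vector: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  fit <- stats::lm(y ~ x)
  out <- data.frame(trait_name = trait_name, n = length(x),
                    slope = unname(stats::coef(fit)[2L]),
                    intercept = unname(stats::coef(fit)[1L]),
                    pearson_r = unname(ct$estimate),
                    p_value = ct$p.value,
                    slope_se = summary(fit)$coefficients[2L, 2L],
                    stringsAsFactors = FALSE)
  class(out) <- c("trend_result", class(out))
  out
}

#' Feasible GLS trend under heteroscedasticity
#'
#' Two-stage feasible generalized least squares with a log-linear variance
#' model in the predictor: (1) OLS fit; (2) regress log(residual^2) on x;
#' (3) weights = 1 / exp(fitted log-variance); (4) weighted least squares.
#' Reports the weighted slope and its two-sided p-value. Squared residuals
#' are floored at machine epsilon before the log so an exact fit degenerates
#' to equal weights (i.e. OLS) instead of failing.
#'
#' @param x Predictor; @param y response. Requires n >= 10.
#' @return One-row data.frame: `n`, `slope`, `intercept`, `gls_p_value`.
#' @export
fgls_trend <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 10L) stop("FGLS requires at least 10 points")
  ols <- stats::lm(y ~ x)
  res2 <- pmax(stats::resid(ols)^2, .Machine$double.eps)
  vfit <- stats::lm(log(res2) ~ x)
  w <- 1 / exp(stats::fitted(vfit))
  if (any(!is.finite(w))) stop("degenerate FGLS weights")
  wls <- stats::lm(y ~ x, weights = w)
  sm <- summary(wls)$coefficients
  data.frame(n = length(x),
             slope = unname(stats::coef(wls)[2L]),
             intercept = unname(stats::coef(wls)[1L]),
             gls_p_value = sm[2L, 4L])
}

#' Exact two-sided binomial test
#'
#' Small-probability-sum convention: the p-value is the sum of P(j) over all
#' outcomes j whose point probability does not exceed that of the observed
#' count (with the standard relative tolerance for floating-point ties), the
#' convention of the classical exact test.
#'
#' @param k Successes; @param n trials; @param p0 null probability.
#' @return Two-sided p-value.
#' @export
binomial_two_sided <- function(k, n, p0 = 0.5) {
  stopifnot(k >= 0, k <= n, p0 > 0, p0 < 1)
  stats::binom.test(k, n, p = p0, alternative = "two.sided")$p.value
}

#' Benjamini-Hochberg step-up FDR
#'
#' Adjusted q-values with enforced monotonicity; a test is flagged
#' significant iff its adjusted value is at most `q`.
#'
#' @param p_values Raw p-values in [0, 1].
#' @param q FDR level (default 0.05).
#' @return data.frame `p_value`, `q_value`, `significant` in input order.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  stopifnot(all(is.na(p_values) | (p_values >= 0 & p_values <= 1)))
  adj <- stats::p.adjust(p_values, method = "BH")
  data.frame(p_value = p_values, q_value = adj,
             significant = !is.na(adj) & adj <= q)
}

#' Two-component PCA of standardized genomic traits
#'
#' Variables are standardized to zero mean and unit variance (the four
#' traits differ by orders of magnitude in units), so the components are the
#' top-2 eigenvectors of the correlation matrix. Returns loadings and scores
#' for biplot rendering plus the explained-variance fractions.
#'
#' @param traits data.frame or matrix of cluster traits (typically `ph_opt`,
#'   `temp_opt`, `gc_percent`, `genome_size_mb`), no missing values,
#'   at least 4 rows.
#' @return List of class `pca_result`: `loadings` (variables x 2), `scores`
#'   (clusters x 2), `explained_variance_fraction` (length 2).
#' @export
pca_biplot <- function(traits) {
  m <- as.matrix(traits)
  stopifnot(is.numeric(m), nrow(m) >= 4L, !anyNA(m))
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant variable: ", colnames(m)[which(sds == 0)[1L]])
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  structure(list(loadings = pc$rotation[, 1:2, drop = FALSE],
                 scores = pc$x[, 1:2, drop = FALSE],
                 explained_variance_fraction = ev[1:2] / sum(ev)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result> ", nrow(x$scores), " points; explained variance ",
      paste(sprintf("%.1f%%", 100 * x$explained_variance_fraction),
            collapse = " + "), "\n", sep = "")
  print(round(x$loadings, 3))
  invisible(x)
}

#' Trait-vs-pH trend battery for a cluster table
#'
#' Pearson trend (and FGLS when n allows) of each named trait against the
#' cluster pH optimum.
#'
#' @param clusters Cluster trait table from [aggregate_clusters].
#' @param traits Character vector of trait column names.
#' @return data.frame with one row per trait including `gls_p_value`.
#' @export
trait_trends <- function(clusters,
                         traits = c("genome_size_mb", "orf_count",
                                    "ig_percent", "mean_protein_len")) {
  rows <- lapply(traits, function(tn) {
    tr <- pearson_trend(clusters$ph_opt, clusters[[tn]], tn)
    tr$gls_p_value <- if (tr$n >= 10L)
      fgls_trend(clusters$ph_opt, clusters[[tn]])$gls_p_value else NA_real_
    tr
  })
  do.call(rbind, rows)
}
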