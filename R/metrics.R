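#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' The probability that a randomly chosen case scores higher than a randomly
#' chosen control, with half credit for ties; computed from rank sums in
#' O(n log n).
#'
#' @param scores numeric predictions.
#' @param labels binary 0/1 vector (1 = case); both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n1 <- as.numeric(sum(labels == 1L)); n0 <- as.numeric(sum(labels == 0L))
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ROC vertices with tied scores grouped: one vertex per distinct score,
# thresholds descending. Returns (fpr, tpr) starting at (0,0).
.roc_vertices <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  last <- cumsum(rle(s)$lengths)    # last index of each tied group
  tp <- cumsum(y)[last]; fp <- (last - cumsum(y)[last])
  n1 <- sum(y); n0 <- length(y) - n1
  list(fpr = c(0, fp / n0), tpr = c(0, tp / n1))
}

#' Partial AUC over a high-specificity window
#'
#' Unnormalized area under the empirical ROC curve restricted to false
#' positive rates in `[1 - spec_hi, 1 - spec_lo]` (default specificities
#' 90-100%, so the maximum possible value is 0.1). Linear interpolation is
#' used where the window edge falls between ROC vertices. With
#' `spec_lo = 0, spec_hi = 1` this equals [auc()] exactly.
#'
#' @inheritParams auc
#' @param spec_lo,spec_hi specificity window bounds, `spec_lo < spec_hi`.
#' @param standardized if `TRUE`, apply the McClish transformation to map the
#'   result to `[0.5, 1]`; default `FALSE` (raw area).
#' @return Partial AUC (raw area by default).
#' @export
partial_auc <- function(scores, labels, spec_lo = 0.90, spec_hi = 1.00,
                        standardized = FALSE) {
  labels <- as.integer(labels)
  if (spec_lo >= spec_hi) stop("spec_lo must be < spec_hi")
  if (!any(labels == 1L) || !any(labels == 0L))
    stop("both classes must be present")
  v <- .roc_vertices(scores, labels)
  lo <- 1 - spec_hi; hi <- 1 - spec_lo
  # clip every ROC segment to the FPR window and accumulate trapezoids;
  # tied-score groups yield diagonal segments, so this reproduces the
  # half-credit Mann-Whitney area exactly on the full window
  x0 <- utils::head(v$fpr, -1); x1 <- utils::tail(v$fpr, -1)
  y0 <- utils::head(v$tpr, -1); y1 <- utils::tail(v$tpr, -1)
  a <- pmax(x0, lo); b <- pmin(x1, hi)
  w <- b - a
  keep <- w > 0 & x1 > x0
  interp <- function(xq, x0, x1, y0, y1) y0 + (y1 - y0) * (xq - x0) / (x1 - x0)
  ya <- interp(a[keep], x0[keep], x1[keep], y0[keep], y1[keep])
  yb <- interp(b[keep], x0[keep], x1[keep], y0[keep], y1[keep])
  area <- sum(w[keep] * (ya + yb) / 2)
  if (!standardized) return(area)
  w <- hi - lo
  min_a <- w^2 / 2
  0.5 * (1 + (area - min_a) / (w - min_a))
}

#' Bootstrap standard deviation of a mean
#'
#' Nonparametric bootstrap: the SD over `n_boot` means of samples drawn with
#' replacement. Deterministic given `seed`.
#'
#' @param values numeric vector.
#' @param n_boot number of bootstrap replicates (default 1e5).
#' @param seed integer seed.
#' @return Bootstrap SD of the mean.
#' @export
bootstrap_sd_of_mean <- function(values, n_boot = 1e5, seed = 1L) {
  n <- length(values)
  if (n == 0L) stop("empty input")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  idx <- sample.int(n, n * n_boot, replace = TRUE)
  stats::sd(colMeans(matrix(values[idx], nrow = n)))
}

#' Maximum achievable AUC under the liability threshold model
#'
#' The AUC of the true genetic liability itself: with liability
#' `y = g + e`, `g ~ N(0, h2)`, `e ~ N(0, 1 - h2)` and case status
#' `y > qnorm(1 - K)`, no genotype-based score can discriminate better than
#' `g`. Estimated by Monte Carlo; a deterministic cross-check integrates the
#' exact case/control densities of `g` numerically (`P(g_case > g_control)`
#' as a double integral over truncated-liability mixtures). A cruder
#' normal-theory approximation (treating `g | case` and `g | control` as
#' Gaussian with truncated-normal moments) is also reported; it is accurate
#' at moderate h2 but biased low for large h2.
#'
#' @param h2 liability-scale heritability in (0, 1).
#' @param prevalence disease prevalence K in (0, 1).
#' @param n_sim Monte Carlo sample size (default 1e6).
#' @param seed integer seed.
#' @return List with `auc` (Monte Carlo estimate), `closed_form` (exact
#'   numerical integral), `normal_approx`, `n_sim`.
#' @export
max_achievable_auc <- function(h2, prevalence, n_sim = 1e6, seed = 1L) {
  stopifnot(h2 > 0, h2 < 1, prevalence > 0, prevalence < 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  t <- stats::qnorm(1 - prevalence)
  g <- stats::rnorm(n_sim, 0, sqrt(h2))
  e <- stats::rnorm(n_sim, 0, sqrt(1 - h2))
  case <- as.integer(g + e > t)
  if (!any(case == 1L) || !any(case == 0L))
    stop("n_sim too small: a simulated class is empty")
  list(auc = auc(g, case),
       closed_form = .max_auc_exact(h2, prevalence),
       normal_approx = .max_auc_normal_approx(h2, prevalence),
       n_sim = n_sim)
}

# exact P(g_case > g_control) by nested quadrature over the conditional
# densities f(g | case) and F(g | control)
.max_auc_exact <- function(h2, K) {
  t <- stats::qnorm(1 - K)
  sg <- sqrt(h2); se <- sqrt(1 - h2)
  F0 <- Vectorize(function(g)
    stats::integrate(function(u) stats::dnorm(u, 0, sg) *
                       stats::pnorm((t - u) / se) / (1 - K),
                     -Inf, g, rel.tol = 1e-10)$value)
  stats::integrate(function(g) stats::dnorm(g, 0, sg) *
                     stats::pnorm((g - t) / se) / K * F0(g),
                   -Inf, Inf, rel.tol = 1e-8)$value
}

# normal-theory approximation via truncated-normal case/control moments of
# the full liability (g = h2 * y + u with u ~ N(0, h2 (1 - h2)))
.max_auc_normal_approx <- function(h2, K) {
  t <- stats::qnorm(1 - K); z <- stats::dnorm(t)
  mu1 <- z / K; mu0 <- -z / (1 - K)
  s1 <- 1 + t * z / K - mu1^2
  s0 <- 1 - t * z / (1 - K) - mu0^2
  v1 <- h2^2 * s1 + h2 * (1 - h2)
  v0 <- h2^2 * s0 + h2 * (1 - h2)
  stats::pnorm(h2 * (mu1 - mu0) / sqrt(v1 + v0))
}

#' Evaluate a score vector against binary labels
#'
#' Convenience wrapper producing one evaluation row: AUC and partial AUC over
#' the default 90-100% specificity window. Uncertainty across replicate runs
#' is obtained with [bootstrap_sd_of_mean()] on the per-run AUCs.
#'
#' @inheritParams auc
#' @param n_predictors number of nonzero predictors behind the score.
#' @param method_label free-text label.
#' @return One-row data.frame (`method_label`, `auc`, `pauc`, `n_predictors`).
#' @export
eval_report <- function(scores, labels, n_predictors = NA_integer_,
                        method_label = "score") {
  data.frame(method_label = method_label,
             auc = auc(scores, labels),
             pauc = partial_auc(scores, labels),
             n_predictors = n_predictors,
             stringsAsFactors = FALSE)
}
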