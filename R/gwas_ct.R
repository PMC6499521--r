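#' Per-SNP association scan (GWAS)
#'
#' Fits one regression per SNP (intercept, optional covariates, the SNP) on
#' the requested rows and reports the SNP effect, its standard error, the
#' Wald z statistic and the two-sided P-value. Logistic fits use
#' Newton-Raphson to a gradient infinity-norm below 1e-8; SNPs showing
#' (quasi-)separation fall back to the score test under the covariate-only
#' null, which stays well defined where the Wald test degenerates.
#'
#' @param dataset a [genotype_dataset] without missing values (or a plain
#'   matrix).
#' @param phenotype full-length response vector (0/1 for logistic).
#' @param rows training row indices (default all).
#' @param covariates optional full-length covariate matrix.
#' @param family `"logistic"` or `"linear"`.
#' @return A `gwas_result` data.frame with columns `id`, `chrom`, `pos`,
#'   `a1`, `beta`, `se`, `z`, `p`, and attribute `n_used`.
#' @export
gwas <- function(dataset, phenotype, rows = NULL, covariates = NULL,
                 family = c("logistic", "linear")) {
  family <- match.arg(family)
  G <- if (inherits(dataset, "genotype_dataset")) dataset$genotypes
       else as.matrix(dataset)
  if (is.null(rows)) rows <- seq_len(nrow(G))
  Gr <- G[rows, , drop = FALSE]
  if (anyNA(Gr)) stop("gwas() requires imputed (non-missing) genotypes")
  y <- as.numeric(phenotype[rows])
  if (length(unique(y)) < 2L) stop("phenotype is constant on the fitting rows")
  n <- length(y)
  C <- matrix(1, n, 1)
  if (!is.null(covariates)) {
    C <- cbind(C, as.matrix(covariates)[rows, , drop = FALSE])
    if (qr(C)$rank < ncol(C))
      stop("covariates are collinear with the intercept")
  }
  if (family == "logistic") {
    if (!all(y %in% 0:1)) stop("logistic family requires a 0/1 phenotype")
    null_fit <- stats::glm.fit(C, y, family = stats::binomial())
    null_coef <- null_fit$coefficients
    res <- gwas_scan(Gr, y, C, 1L, null_coef)
  } else {
    res <- gwas_scan(Gr, y, C, 0L, numeric(ncol(C)))
  }
  v <- if (inherits(dataset, "genotype_dataset")) dataset$variants
       else data.frame(id = sprintf("snp_%d", seq_len(ncol(G))),
                       chrom = "1", pos = seq_len(ncol(G)), a1 = "A")
  out <- data.frame(id = v$id, chrom = v$chrom, pos = v$pos, a1 = v$a1,
                    beta = res$beta, se = res$se, z = res$z, p = res$p,
                    stringsAsFactors = FALSE)
  attr(out, "n_used") <- n
  class(out) <- c("gwas_result", "data.frame")
  out
}

#' Read/write GWAS summary statistics TSV
#'
#' Header: `id`, `chrom`, `pos`, `a1`, `beta`, `se`, `z`, `p`.
#'
#' @param gwas a `gwas_result`.
#' @param path file path.
#' @export
write_gwas_tsv <- function(gwas, path) {
  utils::write.table(as.data.frame(gwas), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_gwas_tsv
#' @export
read_gwas_tsv <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c(id = "character",
                                          chrom = "character"))
  class(out) <- c("gwas_result", "data.frame")
  out
}

#' Greedy LD clumping
#'
#' Repeatedly takes the not-yet-assigned SNP with the smallest GWAS P-value
#' as an index SNP (ties broken by smaller genomic position, then smaller
#' column index) and prunes every unassigned SNP on the same chromosome
#' within `window_kb` whose squared Pearson correlation with it, computed on
#' `ld_rows`, exceeds `r2_threshold`. The paper's protocol computes LD on
#' the test rows; pass training rows to avoid that (deliberate) leakage.
#'
#' @param gwas a `gwas_result` aligned with `ld_dataset`'s variants.
#' @param ld_dataset a [genotype_dataset] providing the LD reference.
#' @param ld_rows rows used for the correlations (default all).
#' @param r2_threshold squared-correlation threshold in (0, 1]; default 0.2.
#' @param window_kb half-window in kilobases (default 500, i.e. +/- 500 kb).
#' @return A `clump_result`: list with `kept` (index SNPs, in keep order),
#'   `assigned_to` (length-p map to the kept index SNP, self for kept),
#'   `r2_threshold`, `window_kb`.
#' @export
clump <- function(gwas, ld_dataset, ld_rows = NULL, r2_threshold = 0.2,
                  window_kb = 500) {
  stopifnot(r2_threshold > 0, r2_threshold <= 1)
  p <- nrow(gwas)
  if (p != ncol(ld_dataset$genotypes))
    stop("gwas result and LD dataset disagree on the number of variants")
  if (is.null(ld_rows)) ld_rows <- seq_len(nrow(ld_dataset$genotypes))
  X <- ld_dataset$genotypes[ld_rows, , drop = FALSE]
  if (anyNA(X)) stop("clump() requires imputed genotypes")
  m <- colMeans(X)
  s <- sqrt(pmax(colMeans(X^2) - m^2, 0))
  nz <- s > 1e-12
  Xs <- sweep(X, 2, m, "-")
  Xs[, nz] <- sweep(Xs[, nz, drop = FALSE], 2, s[nz], "/")
  Xs[, !nz] <- 0  # constant columns correlate with nothing
  ord <- order(gwas$p, gwas$pos, seq_len(p)) - 1L
  chrom_id <- as.integer(factor(gwas$chrom, levels = unique(gwas$chrom)))
  res <- clump_greedy(Xs, chrom_id, as.numeric(gwas$pos), as.integer(ord),
                      r2_threshold, window_kb * 1000)
  structure(list(kept = res$kept, assigned_to = res$assigned,
                 r2_threshold = r2_threshold, window_kb = window_kb),
            class = "clump_result")
}

#' P-value threshold grid
#'
#' `n_points` thresholds, log10-equally spaced and strictly decreasing from
#' 1 down to `p_min`. Defaults give the 102-point grid between 1 and 1e-100.
#'
#' @param n_points grid size (>= 2; default 102).
#' @param p_min smallest threshold (default 1e-100).
#' @return Strictly decreasing numeric vector of length `n_points`.
#' @export
threshold_grid <- function(n_points = 102L, p_min = 1e-100) {
  stopifnot(n_points >= 2, p_min > 0, p_min < 1)
  10^seq(0, log10(p_min), length.out = n_points)
}

#' Build a C+T model
#'
#' Keeps the clumped SNPs whose GWAS P-value is strictly below
#' `p_threshold` and stores their GWAS effect sizes as PRS weights.
#'
#' @param gwas a `gwas_result`.
#' @param clump a `clump_result` on the same variants.
#' @param p_threshold inclusion threshold `p_T`.
#' @param variant label: `"all"`, `"stringent"`, `"max"`, or `"custom"`.
#' @return A `ct_model`: list with `selected` (SNP indices), `weights`,
#'   `p_threshold`, `variant`.
#' @export
ct_model <- function(gwas, clump, p_threshold, variant = "custom") {
  kept <- clump$kept
  selected <- kept[gwas$p[kept] < p_threshold | p_threshold >= 1]
  structure(list(selected = selected, weights = gwas$beta[selected],
                 p_threshold = p_threshold, variant = variant),
            class = "ct_model")
}

#' Score a polygenic risk score model
#'
#' `PRS_i = sum_j beta_j * G_ij` over the model's selected SNPs, on raw
#' allele counts.
#'
#' @param model a `ct_model` (or any list with `selected` and `weights`).
#' @param dataset a [genotype_dataset].
#' @param rows rows to score (default all).
#' @return Numeric score vector.
#' @export
prs_score <- function(model, dataset, rows = NULL) {
  G <- dataset$genotypes
  if (is.null(rows)) rows <- seq_len(nrow(G))
  if (length(model$selected) == 0L) return(numeric(length(rows)))
  Gs <- G[rows, model$selected, drop = FALSE]
  if (anyNA(Gs)) stop("prs_score() requires imputed genotypes")
  drop(Gs %*% model$weights)
}

#' The C+T-all / C+T-stringent / C+T-max variants
#'
#' `C+T-all` keeps every clumped SNP (`p_T = 1`); `C+T-stringent` keeps
#' those at genome-wide significance (`p_T = 5e-8`); `C+T-max` evaluates the
#' test-set AUC at every threshold of `grid` and returns the argmax (ties
#' resolved toward the larger threshold, i.e. more SNPs). Because the
#' threshold is chosen on the test set, C+T-max is an optimistic upper
#' bound of C+T performance — this mirrors the published protocol and is
#' flagged in the output.
#'
#' @param gwas a `gwas_result` (fitted on the training rows).
#' @param clump a `clump_result`.
#' @param dataset a [genotype_dataset].
#' @param test_rows rows used for scoring/AUC.
#' @param labels full-length binary phenotype.
#' @param grid threshold grid for C+T-max (default [threshold_grid()]).
#' @return Named list of entries `all`, `stringent`, `max`, each a list with
#'   `model` (a `ct_model`), `auc`, `pauc`, `n_predictors`; entry `max` also
#'   has `grid_auc` (AUC at every grid threshold) and `optimistic = TRUE`.
#' @export
ct_variants <- function(gwas, clump, dataset, test_rows, labels,
                        grid = threshold_grid()) {
  y <- as.integer(labels[test_rows])
  if (length(unique(y)) < 2L)
    stop("test labels contain a single class")
  eval_one <- function(model) {
    s <- prs_score(model, dataset, test_rows)
    list(model = model,
         auc = if (length(model$selected)) auc(s, y) else 0.5,
         pauc = if (length(model$selected)) partial_auc(s, y)
                else 0.1 * 0.1 / 2,
         n_predictors = length(model$selected))
  }
  out <- list(
    all = eval_one(ct_model(gwas, clump, 1, "all")),
    stringent = eval_one(ct_model(gwas, clump, 5e-8, "stringent")))
  grid_auc <- vapply(grid, function(pt) {
    m <- ct_model(gwas, clump, pt, "max")
    if (!length(m$selected)) return(0.5)
    auc(prs_score(m, dataset, test_rows), y)
  }, numeric(1))
  # argmax; ties toward the larger threshold (grid is decreasing)
  best <- which.max(grid_auc)
  out$max <- eval_one(ct_model(gwas, clump, grid[best], "max"))
  out$max$grid_auc <- grid_auc
  out$max$grid <- grid
  out$max$optimistic <- TRUE
  out
}
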