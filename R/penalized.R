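#' Elastic-net penalized regression objective
#'
#' The mean-loss objective minimized by the path solver:
#' \deqn{(1/n) \sum_i loss_i + \lambda ((1-\alpha) \|\beta\|_2^2 / 2 +
#'       \alpha \|\beta\|_1)}
#' with the logistic negative log-likelihood (or squared error / 2 for the
#' linear family) as the loss. The intercept and any designated unpenalized
#' columns are excluded from the penalty. The mean (1/n) scaling makes
#' \eqn{\lambda} comparable across sample sizes; an unnormalized-sum
#' parameterization corresponds to \eqn{\lambda_{sum} = n \lambda}.
#'
#' @param beta0 intercept.
#' @param beta coefficient vector (on the scale of `X`).
#' @param X design matrix.
#' @param y response; 0/1 for `"logistic"`, numeric for `"linear"`.
#' @param lambda,alpha penalty strength and elastic-net mixing in (0, 1].
#' @param family `"logistic"` or `"linear"`.
#' @param unpenalized_cols columns of `X` excluded from the penalty.
#' @return The objective value (a scalar).
#' @export
objective <- function(beta0, beta, X, y, lambda, alpha,
                      family = c("logistic", "linear"),
                      unpenalized_cols = integer(0)) {
  family <- match.arg(family)
  eta <- drop(beta0 + X %*% beta)
  n <- length(y)
  loss <- if (family == "logistic") {
    if (!all(y %in% 0:1)) stop("logistic family requires 0/1 response")
    # -y*eta + log(1 + exp(eta)), computed stably
    mean(-y * eta + ifelse(eta > 30, eta, log1p(exp(pmin(eta, 30)))))
  } else {
    mean((y - eta)^2) / 2
  }
  bp <- if (length(unpenalized_cols)) beta[-unpenalized_cols] else beta
  loss + lambda * ((1 - alpha) * sum(bp^2) / 2 + alpha * sum(abs(bp)))
}

#' Smallest penalty that zeroes all coefficients
#'
#' For the mean-loss elastic-net objective the KKT conditions give
#' \eqn{\lambda_{max} = \max_j |x_j^T (y - \bar y)| / (n \alpha)} over the
#' penalized columns (the null-model residual; for the logistic family
#' \eqn{\bar y} is the null probability). Fitting at or above this value
#' returns the intercept-only model.
#'
#' @param X column-standardized design matrix.
#' @param y response.
#' @param alpha elastic-net mixing; must be > 0.
#' @param family `"logistic"` or `"linear"`.
#' @param unpenalized_cols columns excluded from the penalty (ignored in the
#'   maximum). For a nonempty set the exact entry point would require the
#'   covariate-adjusted null model; the unadjusted value is an upper bound
#'   and is what the path uses.
#' @return The scalar \eqn{\lambda_{max}}.
#' @export
lambda_max <- function(X, y, alpha, family = c("logistic", "linear"),
                       unpenalized_cols = integer(0)) {
  family <- match.arg(family)
  if (alpha <= 0)
    stop("alpha = 0 has no finite lambda_max; supply a fixed lambda path")
  r <- y - mean(y)
  g <- abs(crossprod(X, r)) / nrow(X)
  if (length(unpenalized_cols)) g[unpenalized_cols] <- 0
  max(g) / alpha
}

#' Fit an elastic-net regularization path
#'
#' Cyclic coordinate descent with warm starts down a log-spaced
#' \eqn{\lambda} sequence from [lambda_max()] to
#' `lambda_min_ratio * lambda_max`. Sequential strong rules screen the
#' candidate predictors at each step and a full KKT sweep re-admits any
#' violators, so screening never changes the solution. If a validation set
#' is supplied, the path stops early once validation loss has not improved
#' for `patience` consecutive \eqn{\lambda} values.
#'
#' @param X numeric design matrix (raw scale).
#' @param y response (0/1 for logistic).
#' @param alpha elastic-net mixing in (0, 1].
#' @param family `"logistic"` or `"linear"`.
#' @param n_lambda path length (default 200).
#' @param lambda_min_ratio ratio of smallest to largest \eqn{\lambda};
#'   default 1e-4 when `n > p`, 1e-2 otherwise.
#' @param lambdas optional explicit decreasing \eqn{\lambda} sequence
#'   (overrides `n_lambda`/`lambda_min_ratio`).
#' @param validation optional `list(X =, y =)` held-out set for early
#'   stopping and per-\eqn{\lambda} validation loss.
#' @param unpenalized_cols columns of `X` exempt from the penalty
#'   (covariates).
#' @param standardize center/scale columns internally (population SD learned
#'   on the fitting rows); coefficients are returned on the input scale.
#'   Set `FALSE` if `X` is already standardized.
#' @param patience early-stopping window (consecutive non-improving
#'   \eqn{\lambda} steps); default 10.
#' @param tol coordinate-descent convergence tolerance on the standardized
#'   scale (default 1e-7).
#' @param max_iter total inner-iteration budget per \eqn{\lambda}.
#' @param use_strong enable the sequential strong rule screen (results are
#'   identical either way; `FALSE` is for verification).
#' @param dfmax stop the path once a solution has more than this many
#'   nonzero coefficients (glmnet-style cap; default `Inf`). Solutions
#'   already computed are kept.
#' @return A `path_fit`: list with `alpha`, `lambda`, `intercepts`,
#'   `coefficients` (p x n_lambda, input scale), `validation_loss`,
#'   `stopped_at`, `best_index`, `family`, `n_nonzero`.
#' @export
fit_path <- function(X, y, alpha, family = c("logistic", "linear"),
                     n_lambda = 200L, lambda_min_ratio = NULL,
                     lambdas = NULL, validation = NULL,
                     unpenalized_cols = integer(0), standardize = TRUE,
                     patience = 10L, tol = 1e-7, max_iter = 1e5,
                     use_strong = TRUE, dfmax = Inf) {
  family <- match.arg(family)
  X <- as.matrix(X); storage.mode(X) <- "double"
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), alpha > 0, alpha <= 1)
  if (family == "logistic" && !all(y %in% 0:1))
    stop("logistic family requires a 0/1 response")
  n <- nrow(X); p <- ncol(X)

  if (standardize) {
    ctr <- colMeans(X)
    scl <- sqrt(pmax(colMeans(X^2) - ctr^2, 0))
    ok <- scl > 1e-12
    scl[!ok] <- 1  # constant columns stay zero-coefficient
    Xs <- scale_columns(X, ctr, ifelse(ok, scl, -1))
  } else {
    ctr <- rep(0, p); scl <- rep(1, p); ok <- rep(TRUE, p)
    Xs <- X
  }

  pf <- rep(1, p)
  pf[unpenalized_cols] <- 0

  if (is.null(lambdas)) {
    lmax <- lambda_max(Xs, y, alpha, family, unpenalized_cols)
    if (lmax <= 0) lmax <- .Machine$double.eps
    if (is.null(lambda_min_ratio))
      lambda_min_ratio <- if (n > p) 1e-4 else 1e-2
    lambdas <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                       length.out = n_lambda))
  } else {
    if (is.unsorted(rev(lambdas), strictly = TRUE))
      stop("lambdas must be strictly decreasing")
  }

  has_val <- !is.null(validation)
  if (has_val) {
    Xv <- as.matrix(validation$X)
    storage.mode(Xv) <- "double"
    if (standardize) Xv <- scale_columns(Xv, ctr, ifelse(ok, scl, -1))
    yv <- as.numeric(validation$y)
  } else {
    Xv <- matrix(0, 1, 1); yv <- 0
  }

  fit <- cd_elnet_path(Xs, y, if (family == "linear") 0L else 1L,
                       lambdas, alpha, pf, Xv, yv, has_val,
                       as.integer(patience), tol, as.integer(max_iter),
                       use_strong,
                       if (is.finite(dfmax)) as.integer(dfmax) else -1L)

  # back-transform to the input scale
  B <- fit$beta / scl
  b0 <- fit$beta0 - drop(crossprod(B, ctr))
  structure(list(alpha = alpha, lambda = fit$lambda,
                 intercepts = b0, coefficients = B,
                 validation_loss = fit$val_loss,
                 stopped_at = fit$stopped_at,
                 best_index = if (has_val) fit$best_index else NA_integer_,
                 family = family,
                 n_nonzero = colSums(fit$beta != 0),
                 center = ctr, scale = scl),
            class = "path_fit")
}

#' @export
print.path_fit <- function(x, ...) {
  cat(sprintf(
    "<path_fit> %s family, alpha = %g: %d lambda values (stopped at %d), up to %d nonzero\n",
    x$family, x$alpha, length(x$lambda), x$stopped_at, max(x$n_nonzero)))
  invisible(x)
}

#' Triple (additive / recessive / dominant) genotype encoding
#'
#' Expands each SNP into three predictors: the allele count itself, a
#' recessive indicator (1 if homozygous for the counted allele, i.e.
#' count 2) and a dominant indicator (1 if at least one copy, i.e.
#' count >= 1), giving a design with exactly `3p` columns. Penalized
#' regression on this design ("PLR3") can pick up departures from
#' additivity.
#'
#' @param dataset a [genotype_dataset] or 0/1/2 matrix without missing
#'   values.
#' @return List with `matrix` (n x 3p) and `map` (data.frame `snp`, `role`
#'   with roles `additive`, `recessive`, `dominant`).
#' @export
triple_encode <- function(dataset) {
  G <- if (inherits(dataset, "genotype_dataset")) dataset$genotypes else dataset
  if (anyNA(G)) stop("triple_encode() requires imputed genotypes")
  if (!all(G %in% c(0, 1, 2)))
    stop("triple encoding is defined for hard 0/1/2 allele counts")
  p <- ncol(G)
  out <- matrix(0, nrow(G), 3L * p)
  cols <- 3L * (seq_len(p) - 1L)
  out[, cols + 1L] <- G
  out[, cols + 2L] <- (G == 2) + 0
  out[, cols + 3L] <- (G >= 1) + 0
  snp_ids <- if (inherits(dataset, "genotype_dataset")) dataset$variants$id
             else sprintf("snp_%d", seq_len(p))
  map <- data.frame(snp = rep(snp_ids, each = 3L),
                    snp_index = rep(seq_len(p), each = 3L),
                    role = rep(c("additive", "recessive", "dominant"), p),
                    stringsAsFactors = FALSE)
  colnames(out) <- paste(map$snp, map$role, sep = ":")
  list(matrix = out, map = map)
}

#' Cross-Model Selection and Averaging (CMSA)
#'
#' Fits the full elastic-net hyper-parameter search in one pass: the
#' training rows are split into `K` stratified folds; for every fold and
#' every `alpha` in the grid a regularization path is fitted on the other
#' K-1 folds with the held-out fold as validation set (early-stopping the
#' path); each fold's best `(alpha, lambda)` is the validation-deviance
#' minimizer across all its paths; and the K winning models are arithmetic-
#' averaged (intercepts and raw-scale coefficients, structural zeros
#' included) into one final sparse model. No refit is performed.
#'
#' @param X raw-scale design matrix (allele counts, or a [triple_encode()]
#'   matrix).
#' @param y response (0/1 for logistic).
#' @param family `"logistic"` or `"linear"`.
#' @param alpha_grid elastic-net mixing grid; default `c(1, 0.5, 0.05,
#'   0.001)`.
#' @param K number of folds (default 10).
#' @param patience early-stopping window per path (default 10).
#' @param n_lambda,lambda_min_ratio,tol,max_iter,dfmax passed to
#'   [fit_path()].
#' @param unpenalized_cols columns exempt from the penalty.
#' @param encoding recorded encoding label (`"additive"` or `"triple"`).
#' @param seed integer seed controlling the fold split.
#' @return A `cmsa_model`: list with `intercept`, `coefficients` (length
#'   p, raw scale), `n_predictors`, `fold_summary` (data.frame: fold, alpha,
#'   lambda, validation loss, n_nonzero), `fold_fits`, `family`, `encoding`.
#' @export
cmsa_fit <- function(X, y, family = c("logistic", "linear"),
                     alpha_grid = c(1, 0.5, 0.05, 0.001),
                     K = 10L, patience = 10L,
                     n_lambda = 200L, lambda_min_ratio = NULL,
                     tol = 1e-7, max_iter = 1e5, dfmax = Inf,
                     unpenalized_cols = integer(0),
                     encoding = c("additive", "triple"), seed = 1L) {
  family <- match.arg(family)
  encoding <- match.arg(encoding)
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(K >= 2, length(y) == n, length(alpha_grid) >= 1)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  folds <- .stratified_folds(y, K, family)

  fold_rows <- list()
  coef_sum <- numeric(p)
  b0_sum <- 0
  for (k in seq_len(K)) {
    val_idx <- which(folds == k)
    trn_idx <- which(folds != k)
    if (family == "logistic" &&
        (length(unique(y[val_idx])) < 2L || length(unique(y[trn_idx])) < 2L))
      stop("a fold contains a single class; use fewer folds")
    # standardize once per fold (training-fold statistics), shared by all
    # alpha paths; coefficients are mapped back to the raw scale below
    Xtr <- X[trn_idx, , drop = FALSE]
    ctr <- colMeans(Xtr)
    scl <- sqrt(pmax(colMeans(Xtr^2) - ctr^2, 0))
    ok <- scl > 1e-12
    s_eff <- ifelse(ok, scl, -1)
    Xtr_s <- scale_columns(Xtr, ctr, s_eff)
    Xval_s <- scale_columns(X[val_idx, , drop = FALSE], ctr, s_eff)
    best <- NULL
    for (a in alpha_grid) {
      pf <- fit_path(Xtr_s, y[trn_idx], alpha = a,
                     family = family, n_lambda = n_lambda,
                     lambda_min_ratio = lambda_min_ratio,
                     validation = list(X = Xval_s, y = y[val_idx]),
                     unpenalized_cols = unpenalized_cols,
                     standardize = FALSE,
                     patience = patience, tol = tol, max_iter = max_iter,
                     dfmax = dfmax)
      i <- pf$best_index
      coef_raw <- pf$coefficients[, i] / ifelse(ok, scl, 1)
      cand <- list(alpha = a, lambda = pf$lambda[i],
                   loss = pf$validation_loss[i],
                   intercept = pf$intercepts[i] - sum(coef_raw * ctr),
                   coefficients = coef_raw,
                   n_nonzero = pf$n_nonzero[i])
      # ties: smaller loss, then larger lambda, then larger alpha (sparser)
      if (is.null(best) ||
          cand$loss < best$loss - 1e-12 ||
          (abs(cand$loss - best$loss) <= 1e-12 &&
           (cand$lambda > best$lambda ||
            (cand$lambda == best$lambda && cand$alpha > best$alpha))))
        best <- cand
    }
    fold_rows[[k]] <- data.frame(fold = k, alpha = best$alpha,
                                 lambda = best$lambda,
                                 validation_loss = best$loss,
                                 n_nonzero = best$n_nonzero)
    coef_sum <- coef_sum + best$coefficients
    b0_sum <- b0_sum + best$intercept
    fold_rows[[k]]$fit <- I(list(best))
  }
  coefficients <- coef_sum / K
  structure(list(intercept = b0_sum / K,
                 coefficients = coefficients,
                 n_predictors = sum(coefficients != 0),
                 fold_summary = do.call(rbind, lapply(fold_rows, function(d)
                   d[, c("fold", "alpha", "lambda", "validation_loss",
                         "n_nonzero")])),
                 fold_fits = lapply(fold_rows, function(d) d$fit[[1]]),
                 family = family, encoding = encoding, K = K, seed = seed),
            class = "cmsa_model")
}

.stratified_folds <- function(y, K, family) {
  n <- length(y)
  folds <- integer(n)
  if (family == "logistic") {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(K), length(idx))
    }
  } else {
    # quantile-stratified for quantitative traits
    idx <- order(y, sample.int(n))
    folds[idx] <- as.vector(t(replicate(ceiling(n / K),
                                        sample.int(K))))[seq_len(n)]
  }
  folds
}

#' @export
print.cmsa_model <- function(x, ...) {
  cat(sprintf(
    "<cmsa_model> %s family, %s encoding, %d folds: %d predictors\n",
    x$family, x$encoding, x$K, x$n_predictors))
  invisible(x)
}

#' Predict from a CMSA-averaged model
#'
#' @param object a `cmsa_model`.
#' @param newdata matrix on the same scale/encoding the model was fitted on
#'   (use [triple_encode()] first for a `"triple"`-encoding model), or a
#'   [genotype_dataset] (encoded automatically).
#' @param type `"link"` (linear predictor; sufficient for AUC) or
#'   `"response"` (probability scale for the logistic family).
#' @param ... unused.
#' @return Numeric score vector.
#' @export
predict.cmsa_model <- function(object, newdata, type = c("link", "response"),
                               ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "genotype_dataset")) {
    if (object$encoding == "triple") triple_encode(newdata)$matrix
    else newdata$genotypes
  } else as.matrix(newdata)
  if (ncol(X) != length(object$coefficients))
    stop("newdata has ", ncol(X), " columns; model expects ",
         length(object$coefficients))
  eta <- drop(object$intercept + X %*% object$coefficients)
  if (type == "response" && object$family == "logistic")
    1 / (1 + exp(-eta))
  else eta
}

#' Fit PLR or PLR3 on a genotype dataset
#'
#' Convenience front end: extracts (and optionally triple-encodes) the
#' genotype matrix for the training rows, appends unpenalized covariates,
#' and runs [cmsa_fit()].
#'
#' @param dataset a [genotype_dataset] without missing values.
#' @param y full-length response vector (subset by `rows`).
#' @param rows training row indices.
#' @param encoding `"additive"` (PLR) or `"triple"` (PLR3).
#' @param covariates optional full-length covariate matrix (pass-through,
#'   unpenalized).
#' @param ... passed to [cmsa_fit()].
#' @return A `cmsa_model` whose `coefficients` cover the encoded genotype
#'   columns followed by any covariate columns (attribute `n_covariates`).
#' @export
plr_fit <- function(dataset, y, rows, encoding = c("additive", "triple"),
                    covariates = NULL, ...) {
  encoding <- match.arg(encoding)
  X <- if (encoding == "triple") triple_encode(dataset)$matrix
       else dataset$genotypes
  Xtr <- X[rows, , drop = FALSE]
  unpen <- integer(0)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    unpen <- ncol(Xtr) + seq_len(ncol(covariates))
    Xtr <- cbind(Xtr, covariates[rows, , drop = FALSE])
  }
  m <- cmsa_fit(Xtr, y[rows], encoding = encoding,
                unpenalized_cols = unpen, ...)
  attr(m, "n_covariates") <- length(unpen)
  m
}
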