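test_that("the objective matches its definition in closed form", {
  set.seed(61)
  X <- matrix(rnorm(40), 10, 4)
  y <- rep(0:1, 5)
  # null model on balanced classes: mean negative log-likelihood = log 2
  expect_equal(objective(0, numeric(4), X, y, lambda = 0.3, alpha = 1),
               log(2))
  # lambda = 0 reduces to the mean NLL
  b <- rnorm(4)
  eta <- drop(0.2 + X %*% b)
  nll <- mean(-y * eta + log1p(exp(eta)))
  expect_equal(objective(0.2, b, X, y, 0, 0.5), nll, tolerance = 1e-12)
  # the two penalty limits
  expect_equal(objective(0.2, b, X, y, 0.7, 1) - nll, 0.7 * sum(abs(b)))
  expect_equal(objective(0.2, b, X, y, 0.7, 1e-12) - nll,
               0.7 * sum(b^2) / 2, tolerance = 1e-9)
  # linear family, unpenalized columns excluded
  yq <- rnorm(10)
  expect_equal(objective(0, b, X, yq, 0.7, 1, family = "linear",
                         unpenalized_cols = c(1, 2)),
               mean((yq - X %*% b)^2) / 2 + 0.7 * sum(abs(b[3:4])))
})

test_that("lambda_max is the exact path entry point (KKT boundary)", {
  set.seed(62)
  for (fam in c("linear", "logistic")) {
    X <- std_pop(matrix(rnorm(60 * 8), 60, 8))
    y <- if (fam == "logistic") rbinom(60, 1, plogis(X[, 1])) else
      drop(X[, 1] + rnorm(60))
    lm0 <- lambda_max(X, y, alpha = 0.5, family = fam)
    above <- fit_path(X, y, 0.5, fam, lambdas = 1.001 * lm0,
                      standardize = FALSE)
    expect_true(all(above$coefficients == 0))
    below <- fit_path(X, y, 0.5, fam, lambdas = c(1.001, 0.99) * lm0,
                      standardize = FALSE)
    expect_gt(sum(below$coefficients[, 2] != 0), 0)
    # 1/alpha homogeneity
    expect_equal(lambda_max(X, y, 0.5, fam), 2 * lambda_max(X, y, 1, fam))
    expect_error(lambda_max(X, y, 0, fam), "alpha")
  }
})

test_that("path solutions satisfy KKT and match the convex oracle", {
  set.seed(63)
  for (i in 1:6) {
    n <- sample(40:100, 1); p <- sample(5:20, 1)
    fam <- c("linear", "logistic")[i %% 2 + 1]
    a <- c(1, 0.5, 0.05, 0.001, 1, 0.5)[i]
    X <- std_pop(matrix(rnorm(n * p), n, p))
    y <- if (fam == "logistic") rbinom(n, 1, plogis(X[, 1] - X[, 2])) else
      drop(X[, 1] - X[, 2] + rnorm(n))
    pf <- fit_path(X, y, a, fam, n_lambda = 5, lambda_min_ratio = 0.05,
                   standardize = FALSE, tol = 1e-9)
    for (k in seq_along(pf$lambda)) {
      expect_lt(kkt_residuals(pf$intercepts[k], pf$coefficients[, k],
                              X, y, pf$lambda[k], a, fam), 1e-6)
    }
    k <- length(pf$lambda)
    o <- fista_elnet(X, y, pf$lambda[k], a, fam)
    expect_lt(max(abs(c(pf$intercepts[k] - o$beta0,
                        pf$coefficients[, k] - o$beta))), 1e-6)
    expect_lt(abs(objective(pf$intercepts[k], pf$coefficients[, k], X, y,
                            pf$lambda[k], a, fam) - o$objective), 1e-9)
  }
})

test_that("lasso path agrees with glmnet where parameterizations coincide", {
  skip_if_not_installed("glmnet")
  set.seed(64)
  n <- 90; p <- 12
  X <- std_pop(matrix(rnorm(n * p), n, p))
  for (fam in c("linear", "logistic")) {
    y <- if (fam == "logistic") rbinom(n, 1, plogis(X[, 1])) else
      drop(X[, 1] + rnorm(n))
    pf <- fit_path(X, y, 1, fam, n_lambda = 8, lambda_min_ratio = 0.05,
                   standardize = FALSE, tol = 1e-10)
    g <- glmnet::glmnet(X, y,
                        family = if (fam == "logistic") "binomial" else "gaussian",
                        alpha = 1, lambda = pf$lambda, standardize = FALSE,
                        thresh = 1e-14)
    expect_lt(max(abs(rbind(pf$intercepts, pf$coefficients) -
                        as.matrix(coef(g)))), 1e-5)
  }
  # logistic elastic net also shares the parameterization
  y <- rbinom(n, 1, plogis(X[, 1]))
  pf <- fit_path(X, y, 0.5, "logistic", n_lambda = 8,
                 lambda_min_ratio = 0.05, standardize = FALSE, tol = 1e-10)
  g <- glmnet::glmnet(X, y, family = "binomial", alpha = 0.5,
                      lambda = pf$lambda, standardize = FALSE, thresh = 1e-14)
  expect_lt(max(abs(rbind(pf$intercepts, pf$coefficients) -
                      as.matrix(coef(g)))), 1e-5)
})

test_that("the strong rule screen never changes a solution", {
  set.seed(65)
  n <- 80; p <- 40
  X <- std_pop(matrix(rnorm(n * p), n, p))
  for (fam in c("linear", "logistic")) {
    y <- if (fam == "logistic") rbinom(n, 1, plogis(X[, 1] - X[, 3])) else
      drop(X[, 1] - X[, 3] + rnorm(n))
    for (a in c(1, 0.05)) {
      on <- fit_path(X, y, a, fam, n_lambda = 12, lambda_min_ratio = 0.05,
                     standardize = FALSE, use_strong = TRUE)
      off <- fit_path(X, y, a, fam, n_lambda = 12, lambda_min_ratio = 0.05,
                      standardize = FALSE, use_strong = FALSE)
      expect_lt(max(abs(on$coefficients - off$coefficients)), 1e-8)
      expect_lt(max(abs(on$intercepts - off$intercepts)), 1e-8)
    }
  }
})

test_that("warm starts do not steer the solution", {
  set.seed(66)
  n <- 70; p <- 15
  X <- std_pop(matrix(rnorm(n * p), n, p))
  y <- rbinom(n, 1, plogis(X[, 2]))
  pf <- fit_path(X, y, 0.5, "logistic", n_lambda = 6,
                 lambda_min_ratio = 0.05, standardize = FALSE, tol = 1e-9)
  for (k in seq_along(pf$lambda)) {
    cold <- fit_path(X, y, 0.5, "logistic", lambdas = pf$lambda[k],
                     standardize = FALSE, tol = 1e-9)
    expect_lt(max(abs(pf$coefficients[, k] - cold$coefficients[, 1])), 1e-6)
  }
})

test_that("the elastic-net grouping effect shows at small alpha", {
  set.seed(67)
  n <- 100
  x <- rnorm(n)
  X <- cbind(x, x, matrix(rnorm(n * 4), n, 4))  # exact duplicates
  Xs <- std_pop(X)
  y <- rbinom(n, 1, plogis(2 * Xs[, 1]))
  near_ridge <- fit_path(Xs, y, 0.001, "logistic", n_lambda = 5,
                         lambda_min_ratio = 0.1, standardize = FALSE,
                         tol = 1e-9)
  b <- near_ridge$coefficients[, 5]
  expect_lt(abs(b[1] - b[2]), 1e-3)   # duplicates share the load
  expect_gt(abs(b[1]), 0)
})

test_that("coefficients are reported back on the raw predictor scale", {
  set.seed(68)
  n <- 120; p <- 10
  X <- matrix(rbinom(n * p, 2, 0.3), n, p) * 1.0
  y <- rbinom(n, 1, plogis(0.8 * scale(X[, 1])))
  pf <- fit_path(X, y, 1, "logistic", n_lambda = 10, lambda_min_ratio = 0.01)
  k <- 10
  eta_raw <- pf$intercepts[k] + drop(X %*% pf$coefficients[, k])
  Xs <- std_pop(X)
  pfs <- fit_path(Xs, y, 1, "logistic", lambdas = pf$lambda,
                  standardize = FALSE)
  eta_std <- pfs$intercepts[k] + drop(Xs %*% pfs$coefficients[, k])
  expect_equal(eta_raw, eta_std, tolerance = 1e-6)
})

test_that("early stopping fires on pure-noise validation data", {
  set.seed(69)
  stops <- sapply(1:10, function(s) {
    set.seed(100 + s)
    n <- 120; p <- 60
    X <- std_pop(matrix(rnorm(n * p), n, p))
    y <- rbinom(n, 1, 0.5)
    Xv <- std_pop(matrix(rnorm(60 * p), 60, p))
    yv <- rbinom(60, 1, 0.5)
    pf <- fit_path(X, y, 1, "logistic", n_lambda = 100,
                   lambda_min_ratio = 1e-2, standardize = FALSE,
                   validation = list(X = Xv, y = yv), patience = 10)
    pf$stopped_at
  })
  expect_gte(sum(stops < 100), 8)
})

test_that("triple encoding maps counts to (additive, recessive, dominant)", {
  G <- matrix(c(0, 1, 2, 2, 0, 1), 2, 3)
  enc <- triple_encode(G)
  expect_equal(ncol(enc$matrix), 9)  # exactly 3p columns
  # count 0 -> (0,0,0); 1 -> (1,0,1); 2 -> (2,1,1)
  expect_equal(unname(enc$matrix[1, 1:3]), c(0, 0, 0))
  expect_equal(unname(enc$matrix[2, 1:3]), c(1, 0, 1))
  expect_equal(unname(enc$matrix[1, 4:6]), c(2, 1, 1))
  expect_equal(enc$map$role[1:3], c("additive", "recessive", "dominant"))
  # monomorphic-in-sample SNP yields constant encoded columns that the
  # standardizer flags for dropping
  Gm <- cbind(c(1, 1, 2), c(0, 1, 2))
  encm <- triple_encode(Gm)
  expect_error(standardize(encm$matrix), "constant")
  expect_error(triple_encode(cbind(c(0.5, 1, 2))), "0/1/2")
  expect_error(triple_encode(cbind(c(NA, 1, 2))), "imputed")
})

test_that("CMSA recovers a dominant signal and averages fold models", {
  set.seed(70)
  ds <- simulate_genotypes(genotype_sim_spec(300, 40, block_size = 1,
                                             within_block_rho = 0, seed = 71))
  liab <- std_pop(ds$genotypes[, 7, drop = FALSE])[, 1] + rnorm(300, 0, 0.1)
  y <- as.integer(liab > quantile(liab, 0.7))
  m <- cmsa_fit(ds$genotypes, y, K = 2, n_lambda = 50, seed = 72)
  expect_equal(which.max(abs(m$coefficients)), 7)
  # averaged coefficients are the arithmetic fold mean, zeros included
  manual <- rowMeans(sapply(m$fold_fits, `[[`, "coefficients"))
  expect_equal(m$coefficients, manual)
  expect_equal(m$n_predictors, sum(m$coefficients != 0))
  expect_equal(nrow(m$fold_summary), 2)
  # deterministic under its seed
  m2 <- cmsa_fit(ds$genotypes, y, K = 2, n_lambda = 50, seed = 72)
  expect_identical(m$coefficients, m2$coefficients)
})

test_that("lasso CMSA on pure noise stays sparse and near chance", {
  # under the L1 penalty a null signal should keep almost nothing; the
  # near-ridge grid members are excluded because ridge never zeroes
  # coefficients, so their null models are dense by construction
  p <- 100
  runs <- lapply(1:5, function(s) {
    set.seed(200 + s)
    n <- 160
    X <- matrix(rbinom(n * p, 2, 0.3), n, p) * 1.0
    y <- rbinom(n, 1, 0.5)
    m <- cmsa_fit(X[1:120, ], y[1:120], alpha_grid = 1, K = 3,
                  n_lambda = 60, seed = s)
    a <- if (m$n_predictors == 0) 0.5 else
      auc(predict(m, X[121:160, ]) + rnorm(40, 0, 1e-12), y[121:160])
    c(m$n_predictors, a)
  })
  npred <- sapply(runs, `[`, 1)
  expect_lte(median(npred), p / 10)   # typically near-empty
  expect_lt(max(npred), p / 2)        # never wholesale inclusion
  aucs <- sapply(runs, `[`, 2)
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})

test_that("lasso fold fits respect the support bound", {
  set.seed(73)
  n <- 60; p <- 200
  X <- matrix(rbinom(n * p, 2, 0.4), n, p) * 1.0
  y <- rbinom(n, 1, 0.5)
  m <- cmsa_fit(X, y, alpha_grid = 1, K = 2, n_lambda = 80, seed = 74)
  for (f in m$fold_fits) expect_lte(f$n_nonzero, n)
})

test_that("CMSA tracks the best single-lambda oracle model", {
  # exhaustive refit-and-test over a fine lambda grid, compared on one split
  set.seed(75)
  ds <- simulate_genotypes(genotype_sim_spec(1200, 300, block_size = 10,
                                             within_block_rho = 0.5,
                                             seed = 76))
  ph <- simulate_phenotype(ds, phenotype_sim_spec(20, heritability = 0.8,
                                                  seed = 77))
  train <- 1:900; test <- 901:1200
  y <- ph$status
  m <- cmsa_fit(ds$genotypes[train, ], y[train], alpha_grid = c(1, 0.5),
                K = 5, n_lambda = 100, seed = 78)
  auc_cmsa <- auc(predict(m, ds$genotypes[test, ]), y[test])
  pf <- fit_path(ds$genotypes[train, ], y[train], alpha = 1,
                 family = "logistic", n_lambda = 100)
  aucs <- apply(pf$coefficients, 2, function(b)
    auc(drop(ds$genotypes[test, ] %*% b) + rnorm(300, 0, 1e-12), y[test]))
  expect_gt(auc_cmsa, max(aucs) - 0.02)
})

test_that("prediction is a monotone link of the linear predictor", {
  set.seed(79)
  X <- matrix(rbinom(300, 2, 0.4), 30, 10) * 1.0
  y <- rbinom(30, 1, 0.5)
  m <- cmsa_fit(X, y, K = 2, n_lambda = 20, seed = 80)
  link <- predict(m, X)
  resp <- predict(m, X, type = "response")
  expect_equal(resp, plogis(link))
  expect_identical(order(link), order(resp))
  perm <- sample(30)
  expect_equal(predict(m, X[perm, ]), link[perm])
  expect_error(predict(m, X[, 1:5]), "columns")
})
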