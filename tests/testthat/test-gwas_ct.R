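test_that("linear-family GWAS matches the least-squares closed form", {
  ds <- make_toy_dataset(n = 60, p = 6, seed = 41)
  set.seed(42)
  y <- rnorm(60) + 0.5 * ds$genotypes[, 2]
  gw <- gwas(ds, y, family = "linear")
  for (j in 1:6) {
    g <- ds$genotypes[, j]
    expect_equal(gw$beta[j], cov(g, y) / var(g), tolerance = 1e-10)
    sm <- summary(lm(y ~ g))$coefficients
    expect_equal(gw$se[j], sm[2, 2], tolerance = 1e-8)
    expect_equal(gw$p[j], sm[2, 4], tolerance = 1e-8)
  }
  # perfect association drives p toward 0 with beta = scale ratio
  ys <- std_pop(ds$genotypes[, 3, drop = FALSE])[, 1]
  gwp <- gwas(ds, ys, family = "linear")
  expect_lt(gwp$p[3], 1e-200)
  expect_equal(gwp$beta[3], 1 / sqrt(var(ds$genotypes[, 3]) * 59 / 60),
               tolerance = 1e-10)
})

test_that("logistic GWAS agrees with glm() and stays calibrated under the null", {
  ds <- make_toy_dataset(n = 150, p = 5, seed = 43)
  set.seed(44)
  y <- rbinom(150, 1, plogis(0.8 * std_pop(ds$genotypes)[, 1]))
  gw <- gwas(ds, y, family = "logistic")
  for (j in 1:5) {
    fit <- suppressWarnings(glm(y ~ ds$genotypes[, j], family = binomial(),
                                control = glm.control(epsilon = 1e-12)))
    sm <- summary(fit)$coefficients
    expect_equal(gw$beta[j], sm[2, 1], tolerance = 1e-6)
    expect_equal(gw$p[j], sm[2, 4], tolerance = 1e-6)
  }
  # null calibration: p-values of permuted-phenotype scans are uniform
  big <- simulate_genotypes(genotype_sim_spec(300, 1000, block_size = 1,
                                              within_block_rho = 0, seed = 45))
  set.seed(46)
  ynull <- sample(rep(0:1, each = 150))
  gnull <- gwas(big, ynull, family = "logistic")
  ks <- suppressWarnings(ks.test(gnull$p, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_true(all(gnull$p > 0 & gnull$p <= 1))
})

test_that("logistic GWAS survives separation via the score test", {
  # SNP perfectly separates the phenotype -> Wald degenerates
  G <- cbind(c(rep(0, 10), rep(2, 10)), rbinom(20, 2, 0.5))
  G[1, 2] <- 1  # avoid constant column
  ds <- genotype_dataset(G, data.frame(id = c("sep", "ok"), chrom = "1",
                                       pos = c(1L, 2L), a1 = "A", a2 = "G"))
  y <- c(rep(0, 10), rep(1, 10))
  gw <- gwas(ds, y, family = "logistic")
  expect_true(is.finite(gw$z[1]))
  expect_lt(gw$p[1], 0.01)   # strong association, finite evidence
  expect_gt(gw$p[1], 1e-10)  # not the degenerate Wald underflow
})

test_that("GWAS respects covariates", {
  ds <- make_toy_dataset(n = 120, p = 4, seed = 47)
  set.seed(48)
  cv <- rnorm(120)
  y <- rnorm(120) + 2 * cv + 0.4 * ds$genotypes[, 1]
  gw <- gwas(ds, y, covariates = cbind(cv), family = "linear")
  sm <- summary(lm(y ~ cv + ds$genotypes[, 1]))$coefficients
  expect_equal(gw$beta[1], sm[3, 1], tolerance = 1e-8)
  expect_equal(gw$p[1], sm[3, 4], tolerance = 1e-8)
  expect_error(gwas(ds, y, covariates = cbind(rep(1, 120)), family = "linear"),
               "collinear")
})

test_that("summary statistics TSV round-trips", {
  ds <- make_toy_dataset(n = 40, p = 5, seed = 49)
  set.seed(50)
  gw <- gwas(ds, rnorm(40), family = "linear")
  tmp <- tempfile(fileext = ".tsv")
  write_gwas_tsv(gw, tmp)
  back <- read_gwas_tsv(tmp)
  expect_equal(back$beta, gw$beta, tolerance = 1e-12)
  expect_equal(back$p, gw$p, tolerance = 1e-12)
  expect_equal(back$id, gw$id)
})

test_that("clumping keeps the stronger of duplicated columns", {
  ds <- make_ld_pair_dataset()
  gw <- data.frame(id = ds$variants$id, chrom = ds$variants$chrom,
                   pos = ds$variants$pos, a1 = "A",
                   beta = c(0.2, 0.3, 0.1), se = 1, z = 1,
                   p = c(1e-4, 1e-8, 0.5))
  cl <- clump(gw, ds, r2_threshold = 0.2, window_kb = 500)
  expect_true(2L %in% cl$kept)      # the 1e-8 duplicate wins
  expect_false(1L %in% cl$kept)
  expect_equal(cl$assigned_to[1], 2L)
  expect_true(3L %in% cl$kept)      # uncorrelated SNP untouched
  # far apart (outside the window) both survive even at r2 = 1
  ds2 <- ds; ds2$variants$pos <- c(1000L, 2000000L, 3000000L)
  gw2 <- gw; gw2$pos <- ds2$variants$pos
  cl2 <- clump(gw2, ds2, r2_threshold = 0.2, window_kb = 500)
  expect_setequal(cl2$kept, 1:3)
})

test_that("uncorrelated SNPs all survive clumping", {
  ds <- simulate_genotypes(genotype_sim_spec(500, 30, block_size = 1,
                                             within_block_rho = 0, seed = 51))
  set.seed(52)
  gw <- gwas(ds, rnorm(500), family = "linear")
  cl <- clump(gw, ds, r2_threshold = 0.9, window_kb = 500)
  expect_setequal(cl$kept, 1:30)
})

test_that("greedy clumping equals the brute-force replay of its definition", {
  for (seed in 1:5) {
    ds <- simulate_genotypes(genotype_sim_spec(300, 25, block_size = 5,
                                               within_block_rho = 0.8,
                                               pos_spacing_bp = 100000L,
                                               n_chromosomes = 2L,
                                               seed = seed))
    set.seed(seed + 100)
    y <- rnorm(300)
    gw <- gwas(ds, y, family = "linear")
    cl <- clump(gw, ds, r2_threshold = 0.2, window_kb = 300)
    R2 <- cor(ds$genotypes)^2
    chrom_id <- as.integer(factor(ds$variants$chrom,
                                  levels = unique(ds$variants$chrom)))
    bf <- clump_bruteforce(R2, chrom_id, ds$variants$pos, gw$p,
                           0.2, 300 * 1000)
    expect_identical(cl$kept, bf$kept)
    expect_identical(as.integer(cl$assigned_to), bf$assigned)
  }
})

test_that("clumping is invariant to storage order given the tie-break rule", {
  # co-located SNPs admit several valid storage orders; with distinct
  # p-values the greedy result must not depend on which one is used
  set.seed(54)
  n <- 150
  G <- matrix(rbinom(n * 6, 2, 0.5), n, 6)
  G[, 2] <- G[, 1]; G[, 5] <- G[, 4]  # two duplicated pairs
  pos <- c(1000L, 1000L, 1000L, 5000L, 5000L, 5000L)
  pv <- c(0.03, 0.001, 0.2, 0.05, 0.004, 0.6)
  base_gw <- function(ord) data.frame(
    id = sprintf("v%d", (1:6)[ord]), chrom = "1", pos = pos[ord], a1 = "A",
    beta = 1, se = 1, z = 1, p = pv[ord])
  mk <- function(ord) genotype_dataset(
    G[, ord], data.frame(id = sprintf("v%d", (1:6)[ord]), chrom = "1",
                         pos = pos[ord], a1 = "A", a2 = "G"))
  kept_ref <- NULL
  for (ord in list(1:6, c(2, 1, 3, 5, 4, 6), c(3, 2, 1, 6, 5, 4))) {
    cl <- clump(base_gw(ord), mk(ord), r2_threshold = 0.2, window_kb = 500)
    ids <- sort(sprintf("v%d", (1:6)[ord])[cl$kept])
    if (is.null(kept_ref)) kept_ref <- ids else expect_identical(ids, kept_ref)
  }
})

test_that("the threshold grid has the documented shape", {
  g <- threshold_grid()
  expect_length(g, 102)
  expect_equal(g[1], 1)
  expect_equal(g[102], 1e-100)
  expect_true(all(diff(g) < 0))
  expect_equal(threshold_grid(3, 1e-4), c(1, 1e-2, 1e-4))
  expect_true(all(diff(threshold_grid(50, 1e-30)) < 0))
})

test_that("PRS scoring is a plain weighted allele-count sum", {
  ds <- make_toy_dataset(n = 3, p = 1, seed = 55)
  ds$genotypes[, 1] <- c(0, 1, 2)
  m <- list(selected = 1L, weights = 0.5)
  expect_equal(prs_score(m, ds), c(0, 0.5, 1.0))
  expect_equal(prs_score(list(selected = integer(0), weights = numeric(0)),
                         ds), c(0, 0, 0))
  # order of selected SNPs is immaterial
  ds2 <- make_toy_dataset(n = 10, p = 4, seed = 56)
  m1 <- list(selected = c(1L, 3L, 4L), weights = c(0.1, -0.2, 0.3))
  m2 <- list(selected = c(4L, 1L, 3L), weights = c(0.3, 0.1, -0.2))
  expect_equal(prs_score(m1, ds2), prs_score(m2, ds2))
})

test_that("C+T variants behave as documented on a signal scenario", {
  ds <- simulate_genotypes(genotype_sim_spec(900, 300, block_size = 10,
                                             within_block_rho = 0.5,
                                             seed = 57))
  ph <- simulate_phenotype(ds, phenotype_sim_spec(10, heritability = 0.8,
                                                  seed = 58))
  train <- 1:600; test <- 601:900
  gw <- gwas(ds, ph$status, train, family = "logistic")
  cl <- clump(gw, ds, ld_rows = test, r2_threshold = 0.2)
  ct <- ct_variants(gw, cl, ds, test, ph$status)
  # C+T-all is exactly the clumped set
  expect_setequal(ct$all$model$selected, cl$kept)
  # nested thresholds select nested sets
  grid <- threshold_grid(20, 1e-20)
  sel <- lapply(grid, function(pt) ct_model(gw, cl, pt)$selected)
  for (k in 2:20) expect_true(all(sel[[k]] %in% sel[[k - 1]]))
  # the argmax dominates any fixed grid member, including 1 and 5e-8
  expect_gte(ct$max$auc, ct$all$auc)
  expect_gte(ct$max$auc, ct$stringent$auc)
  expect_true(ct$max$optimistic)
  # single-point grid returns that model
  one <- ct_variants(gw, cl, ds, test, ph$status, grid = 1e-3)
  expect_equal(one$max$model$p_threshold, 1e-3)
})

test_that("C+T is sensitive to the P-value threshold on sparse architectures", {
  ds <- simulate_genotypes(genotype_sim_spec(1500, 800, block_size = 10,
                                             within_block_rho = 0.5,
                                             seed = 59))
  ph <- simulate_phenotype(ds, phenotype_sim_spec(30, heritability = 0.8,
                                                  seed = 60))
  train <- 1:1100; test <- 1101:1500
  gw <- gwas(ds, ph$status, train, family = "logistic")
  cl <- clump(gw, ds, ld_rows = test, r2_threshold = 0.2)
  ct <- ct_variants(gw, cl, ds, test, ph$status)
  # AUC spread across the grid exceeds 0.1: the threshold matters
  expect_gt(max(ct$max$grid_auc) - min(ct$max$grid_auc), 0.1)
})
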