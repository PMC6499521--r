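#' Specification of a synthetic genotype panel
#'
#' Describes an `n x p` panel of biallelic SNPs in Hardy-Weinberg
#' equilibrium with block-wise linkage disequilibrium. Each haplotype is
#' drawn from a Gaussian copula: within a block the latent variables follow
#' an AR(1) process with parameter `within_block_rho`, thresholded at the
#' per-SNP MAF quantile, so adjacent SNPs are correlated while blocks (and
#' chromosomes) are independent and every SNP keeps an exact
#' Binomial(2, maf) marginal.
#'
#' @param n_samples,n_snps panel dimensions.
#' @param block_size number of SNPs per LD block.
#' @param within_block_rho latent AR(1) correlation in `[0, 1)`; 0 gives
#'   independent SNPs.
#' @param maf_range minor-allele-frequency range, drawn uniformly per SNP.
#' @param n_chromosomes SNPs are split evenly across this many chromosomes,
#'   with strictly increasing positions spaced `pos_spacing_bp` apart.
#' @param pos_spacing_bp base-pair spacing between adjacent SNPs.
#' @param seed integer seed; the panel is a pure function of the spec.
#' @return An object of class `genotype_sim_spec`.
#' @export
genotype_sim_spec <- function(n_samples, n_snps, block_size = 20L,
                              within_block_rho = 0.6,
                              maf_range = c(0.05, 0.5),
                              n_chromosomes = 2L,
                              pos_spacing_bp = 5000L,
                              seed = 1L) {
  stopifnot(n_samples >= 1, n_snps >= 1, block_size >= 1,
            n_snps >= block_size,
            within_block_rho >= 0, within_block_rho < 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            n_chromosomes >= 1, pos_spacing_bp >= 1)
  structure(as.list(environment()), class = "genotype_sim_spec")
}

# one haplotype matrix (n x p_block) from a latent AR(1) Gaussian
.sim_haplotype_block <- function(n, mafs, rho) {
  p <- length(mafs)
  z <- matrix(stats::rnorm(n * p), n, p)
  if (rho > 0 && p > 1) {
    w <- sqrt(1 - rho^2)
    for (j in 2:p) z[, j] <- rho * z[, j - 1] + w * z[, j]
  }
  # allele = 1 where latent below the MAF quantile -> P(allele) = maf exactly
  sweep(z, 2, stats::qnorm(mafs), "<") + 0
}

#' Simulate an LD-structured genotype panel
#'
#' Genotypes are the sum of two independent haplotypes drawn per
#' [genotype_sim_spec], so marginals are exactly Hardy-Weinberg.
#'
#' @param spec a [genotype_sim_spec].
#' @return A [genotype_dataset] with attribute `mafs` (the simulated
#'   allele frequencies of the counted allele).
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "genotype_sim_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  n <- spec$n_samples; p <- spec$n_snps
  mafs <- stats::runif(p, spec$maf_range[1], spec$maf_range[2])
  starts <- seq.int(1L, p, by = spec$block_size)
  G <- matrix(0, n, p)
  for (s in starts) {
    cols <- s:min(s + spec$block_size - 1L, p)
    G[, cols] <- .sim_haplotype_block(n, mafs[cols], spec$within_block_rho) +
      .sim_haplotype_block(n, mafs[cols], spec$within_block_rho)
  }
  per_chr <- ceiling(p / spec$n_chromosomes)
  chrom <- as.character(((seq_len(p) - 1L) %/% per_chr) + 1L)
  pos <- as.integer((seq_len(p) - 1L) %% per_chr + 1L) * spec$pos_spacing_bp
  ds <- genotype_dataset(
    G,
    data.frame(id = sprintf("snp_%d", seq_len(p)), chrom = chrom, pos = pos,
               a1 = "A", a2 = "G", stringsAsFactors = FALSE),
    validate = FALSE)
  attr(ds, "mafs") <- mafs
  ds
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Specification of a simulated phenotype
#'
#' Parameters of the liability threshold model (LTM): `n_causal` SNPs carry
#' effects drawn from a Gaussian `N(0, h2/n_causal)` or a Laplace with
#' matching variance; the liability is the weighted sum of standardized
#' causal genotypes plus `N(0, 1 - h2)` environmental noise, and individuals
#' above the empirical `(1 - prevalence)` liability quantile are cases.
#' Model `ADD` is purely additive; model `COMP` splits the causal set into
#' additive, dominant and pairwise-interaction thirds (a synthetic composite
#' used to probe non-additive architectures).
#'
#' @param n_causal number of causal SNPs.
#' @param causal_placement `"genome_wide"` (uniform over all SNPs) or
#'   `"one_region"` (uniform within `region_window`).
#' @param region_window list/vector `(chrom, start_bp, end_bp)`; required for
#'   `"one_region"`. Default: first quarter of chromosome 1 when missing.
#' @param effect_distribution `"gaussian"` or `"laplace"`.
#' @param heritability liability-scale h2 in (0, 1).
#' @param prevalence case fraction K in (0, 1); default 0.30.
#' @param model `"ADD"` or `"COMP"`.
#' @param seed integer seed.
#' @return An object of class `phenotype_sim_spec`.
#' @export
phenotype_sim_spec <- function(n_causal,
                               causal_placement = c("genome_wide", "one_region"),
                               region_window = NULL,
                               effect_distribution = c("gaussian", "laplace"),
                               heritability = 0.5, prevalence = 0.30,
                               model = c("ADD", "COMP"), seed = 1L) {
  causal_placement <- match.arg(causal_placement)
  effect_distribution <- match.arg(effect_distribution)
  model <- match.arg(model)
  stopifnot(n_causal >= 0, heritability > 0, heritability < 1,
            prevalence > 0, prevalence < 1)
  structure(list(n_causal = n_causal, causal_placement = causal_placement,
                 region_window = region_window,
                 effect_distribution = effect_distribution,
                 heritability = heritability, prevalence = prevalence,
                 model = model, seed = seed),
            class = "phenotype_sim_spec")
}

#' Draw sparse causal effect weights
#'
#' Gaussian weights are `N(0, h2/|S|)`; Laplace weights use scale
#' `b = sqrt(h2 / (2|S|))` so that their variance `2 b^2 = h2/|S|` matches
#' the Gaussian case at equal heritability.
#'
#' @param p total number of SNPs.
#' @param causal_indices indices of the causal set S.
#' @param distribution `"gaussian"` or `"laplace"`.
#' @param h2 heritability.
#' @return Length-`p` numeric vector, zero off the causal set.
#' @export
draw_effects <- function(p, causal_indices,
                         distribution = c("gaussian", "laplace"), h2) {
  distribution <- match.arg(distribution)
  m <- length(causal_indices)
  if (m == 0L) stop("causal set is empty")
  w <- numeric(p)
  if (distribution == "gaussian") {
    w[causal_indices] <- stats::rnorm(m, 0, sqrt(h2 / m))
  } else {
    b <- sqrt(h2 / (2 * m))
    u <- stats::runif(m, -0.5, 0.5)  # inverse-CDF Laplace draw
    w[causal_indices] <- -b * sign(u) * log(1 - 2 * abs(u))
  }
  w
}

.pick_causal <- function(dataset, spec) {
  p <- ncol(dataset$genotypes)
  if (spec$n_causal == 0L) return(integer(0))
  if (spec$causal_placement == "genome_wide") {
    sort(sample.int(p, spec$n_causal))
  } else {
    win <- spec$region_window
    if (is.null(win)) {
      chr1 <- dataset$variants$chrom[1]
      pos1 <- dataset$variants$pos[dataset$variants$chrom == chr1]
      win <- list(chr1, min(pos1), min(pos1) + (max(pos1) - min(pos1)) %/% 4L)
    }
    cand <- which(dataset$variants$chrom == as.character(win[[1]]) &
                    dataset$variants$pos >= as.numeric(win[[2]]) &
                    dataset$variants$pos <= as.numeric(win[[3]]))
    if (length(cand) < spec$n_causal)
      stop(sprintf("region holds %d SNPs < n_causal = %d",
                   length(cand), spec$n_causal))
    sort(sample(cand, spec$n_causal))
  }
}

.finish_phenotype <- function(genetic, spec, causal, weights) {
  n <- length(genetic)
  eps <- stats::rnorm(n, 0, sqrt(1 - spec$heritability))
  y <- genetic + eps
  n_case <- round(spec$prevalence * n)
  # empirical threshold; ties broken by sample index so the case count is exact
  ord <- order(y, seq_len(n), decreasing = TRUE)
  status <- integer(n)
  status[ord[seq_len(n_case)]] <- 1L
  thr <- if (n_case < n) y[ord[n_case + 1L]] else -Inf
  structure(list(liability = y, status = status, causal_indices = causal,
                 weights = weights, threshold = thr,
                 genetic = genetic, spec = spec),
            class = "simulated_phenotype")
}

#' Simulate a phenotype under the liability threshold model
#'
#' @param dataset a [genotype_dataset] without missing values.
#' @param spec a [phenotype_sim_spec].
#' @return A `simulated_phenotype`: list with `liability`, `status` (0/1),
#'   `causal_indices`, `weights` (length p for ADD; for COMP, the additive,
#'   dominant and interaction weights are in attribute-free named elements of
#'   `comp_terms`), `threshold`, and the realized `genetic` component.
#' @export
simulate_phenotype <- function(dataset, spec) {
  stopifnot(inherits(dataset, "genotype_dataset"),
            inherits(spec, "phenotype_sim_spec"))
  if (anyNA(dataset$genotypes))
    stop("simulate_phenotype() requires imputed (non-missing) genotypes")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  if (spec$model == "ADD") .simulate_add(dataset, spec)
  else .simulate_comp(dataset, spec)
}

.simulate_add <- function(dataset, spec) {
  p <- ncol(dataset$genotypes)
  causal <- .pick_causal(dataset, spec)
  if (length(causal) == 0L) {
    return(.finish_phenotype(numeric(nrow(dataset$genotypes)), spec,
                             integer(0), numeric(p)))
  }
  w <- draw_effects(p, causal, spec$effect_distribution, spec$heritability)
  sv <- standardize(dataset$genotypes[, causal, drop = FALSE])
  Gt <- apply_standardization(sv, dataset$genotypes[, causal, drop = FALSE])
  genetic <- drop(Gt %*% w[causal])
  .finish_phenotype(genetic, spec, causal, w)
}

.simulate_comp <- function(dataset, spec) {
  p <- ncol(dataset$genotypes)
  causal <- .pick_causal(dataset, spec)
  m <- length(causal) %/% 3L
  if (m < 1L) stop("COMP model needs at least 3 causal SNPs")
  idx_add <- causal[seq_len(m)]
  idx_dom <- causal[m + seq_len(m)]
  idx_int <- causal[2L * m + seq_len(3L * m - 2L * m)]
  h2 <- spec$heritability
  w_add <- draw_effects(p, idx_add, spec$effect_distribution, h2 / 3)
  w_dom <- draw_effects(p, idx_dom, spec$effect_distribution, h2 / 3)
  n_pair <- length(idx_int) %/% 2L
  w_int <- draw_effects(max(n_pair, 1L), seq_len(max(n_pair, 1L)),
                        spec$effect_distribution, h2 / 3)
  G <- dataset$genotypes
  std_cols <- function(M) {
    sv <- standardize(M)
    apply_standardization(sv, M)
  }
  g_add <- drop(std_cols(G[, idx_add, drop = FALSE]) %*% w_add[idx_add])
  D <- (G[, idx_dom, drop = FALSE] >= 1) + 0
  keep <- apply(D, 2, stats::var) > 0
  g_dom <- if (any(keep))
    drop(std_cols(D[, keep, drop = FALSE]) %*% w_dom[idx_dom][keep])
  else numeric(nrow(G))
  g_int <- numeric(nrow(G))
  if (n_pair >= 1L) {
    Gi <- std_cols(G[, idx_int, drop = FALSE])
    for (k in seq_len(n_pair))
      g_int <- g_int + w_int[k] * Gi[, 2L * k - 1L] * Gi[, 2L * k]
  }
  raw <- g_add + g_dom + g_int
  v <- stats::var(raw) * (length(raw) - 1) / length(raw)
  if (v <= 0) stop("degenerate COMP genetic component")
  genetic <- raw * sqrt(h2 / v)  # exact empirical variance h2
  out <- .finish_phenotype(genetic, spec, causal, w_add)
  out$comp_terms <- list(additive = w_add, dominant = w_dom,
                         interaction_pairs = if (n_pair)
                           cbind(idx_int[2 * seq_len(n_pair) - 1L],
                                 idx_int[2 * seq_len(n_pair)]) else NULL,
                         interaction_weights = if (n_pair)
                           w_int[seq_len(n_pair)] else numeric(0),
                         rescale = sqrt(h2 / v))
  out
}

#' @export
print.simulated_phenotype <- function(x, ...) {
  cat(sprintf(
    "<simulated_phenotype> %s model: n = %d, cases = %d (%.1f%%), %d causal SNPs, h2 = %.2f\n",
    x$spec$model, length(x$status), sum(x$status),
    100 * mean(x$status), length(x$causal_indices), x$spec$heritability))
  invisible(x)
}

#' Write the simulated phenotype and truth tables
#'
#' Writes `prefix_pheno.tsv` (`sample_id`, `liability`, `status`) and
#' `prefix_truth.tsv` (`id`, `weight`, restricted to the causal set).
#'
#' @param phenotype a `simulated_phenotype`.
#' @param dataset the matching [genotype_dataset].
#' @param prefix output path prefix.
#' @export
write_phenotype_tsv <- function(phenotype, dataset, prefix) {
  utils::write.table(
    data.frame(sample_id = dataset$sample_ids,
               liability = phenotype$liability, status = phenotype$status),
    paste0(prefix, "_pheno.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(id = dataset$variants$id[phenotype$causal_indices],
               weight = phenotype$weights[phenotype$causal_indices]),
    paste0(prefix, "_truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
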