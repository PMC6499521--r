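#' Genotype dataset container
#'
#' Bundles an `n x p` matrix of biallelic SNP allele counts with its variant
#' map and sample identifiers. Allele counts are coded 0/1/2 copies of the
#' counted allele (`a1`, the PLINK A1 column); missing genotypes are `NA`.
#' Variants must be sorted by (chromosome, position).
#'
#' @param genotypes numeric matrix, `n` samples x `p` SNPs, entries in
#'   \{0, 1, 2, NA\} (fractional values are allowed after mean imputation).
#' @param variants data.frame with columns `id`, `chrom`, `pos`, `a1`, `a2`;
#'   one row per SNP, `id` unique, `pos` in base pairs (1-based, >= 0).
#' @param sample_ids character vector of length `n`.
#' @param validate check invariants (set `FALSE` for trusted internal calls).
#'
#' @return An object of class `genotype_dataset` with elements `genotypes`,
#'   `variants`, `sample_ids`.
#' @export
genotype_dataset <- function(genotypes, variants, sample_ids = NULL,
                             validate = TRUE) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "double"
  if (is.null(sample_ids)) {
    sample_ids <- if (!is.null(rownames(genotypes))) rownames(genotypes)
                  else sprintf("sample_%d", seq_len(nrow(genotypes)))
  }
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (validate) {
    if (nrow(genotypes) < 1L || ncol(genotypes) < 1L)
      stop("genotype matrix must have at least one sample and one SNP")
    need <- c("id", "chrom", "pos", "a1", "a2")
    if (!all(need %in% names(variants)))
      stop("variant map must have columns: ", paste(need, collapse = ", "))
    if (nrow(variants) != ncol(genotypes))
      stop("variant map rows (", nrow(variants),
           ") must match genotype columns (", ncol(genotypes), ")")
    if (length(sample_ids) != nrow(genotypes))
      stop("sample_ids length must match genotype rows")
    if (anyDuplicated(variants$id))
      stop("variant ids must be unique")
    if (any(variants$pos < 0))
      stop("variant positions must be >= 0")
    r <- rle(as.character(variants$chrom))
    if (anyDuplicated(r$values))
      stop("variants of one chromosome must form a contiguous block")
    if (any(tapply(variants$pos, factor(variants$chrom, levels = r$values),
                   is.unsorted)))
      stop("variant positions must be sorted within each chromosome")
    vals <- genotypes[!is.na(genotypes)]
    if (length(vals) && (min(vals) < 0 || max(vals) > 2))
      stop("allele counts must lie in [0, 2]")
  }
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  structure(
    list(genotypes = genotypes, variants = variants,
         sample_ids = as.character(sample_ids)),
    class = "genotype_dataset"
  )
}

#' @export
print.genotype_dataset <- function(x, ...) {
  n_mis <- sum(is.na(x$genotypes))
  cat(sprintf(
    "<genotype_dataset> %d samples x %d SNPs (%d chromosome%s, %s missing)\n",
    nrow(x$genotypes), ncol(x$genotypes),
    length(unique(x$variants$chrom)),
    if (length(unique(x$variants$chrom)) == 1L) "" else "s",
    format(n_mis, big.mark = ",")))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$genotypes)

# PLINK 1 .bed 2-bit codes, SNP-major, samples packed from the low-order
# bits of each byte: 00 -> 2 copies of A1, 01 -> missing, 10 -> het,
# 11 -> 0 copies of A1.
.bed_code_to_count <- c(`0` = 2, `1` = NA, `2` = 1, `3` = 0)

#' Read a PLINK 1 binary fileset
#'
#' Decodes a SNP-major `.bed` file together with its `.bim` variant map and
#' `.fam` sample table into a [genotype_dataset]. Only the SNP-major mode
#' (magic bytes `0x6C 0x1B 0x01`) is supported.
#'
#' @param bed_path,bim_path,fam_path paths to the three files; `bim_path` and
#'   `fam_path` default to the `.bed` path with the extension swapped.
#' @return A [genotype_dataset]. The `.fam` phenotype column is attached as
#'   attribute `fam` (data.frame with `fid`, `iid`, `pat`, `mat`, `sex`,
#'   `pheno`); phenotypes are recoded 1/2 -> 0/1 and -9/0 -> NA.
#' @export
read_plink <- function(bed_path,
                       bim_path = sub("\\.bed$", ".bim", bed_path),
                       fam_path = sub("\\.bed$", ".fam", bed_path)) {
  for (f in c(bed_path, bim_path, fam_path))
    if (!file.exists(f)) stop("file not found: ", f)
  bim <- utils::read.table(bim_path, header = FALSE,
                           col.names = c("chrom", "id", "cm", "pos", "a1", "a2"),
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  fam <- utils::read.table(fam_path, header = FALSE,
                           col.names = c("fid", "iid", "pat", "mat", "sex", "pheno"),
                           colClasses = c("character", "character", "character",
                                          "character", "integer", "numeric"))
  n <- nrow(fam); p <- nrow(bim)
  raw <- readBin(bed_path, what = "raw", n = file.size(bed_path))
  if (length(raw) < 3L || raw[1] != as.raw(0x6C) || raw[2] != as.raw(0x1B))
    stop("not a PLINK .bed file (bad magic bytes): ", bed_path)
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major .bed files (mode byte 0x01) are supported")
  bytes_per_snp <- ceiling(n / 4)
  body <- raw[-(1:3)]
  if (length(body) != bytes_per_snp * p)
    stop(sprintf(".bed is truncated or padded: expected %d data bytes, found %d",
                 bytes_per_snp * p, length(body)))
  codes <- matrix(as.integer(body), nrow = bytes_per_snp, ncol = p)
  # unpack 4 samples per byte, low-order bits first
  geno <- matrix(NA_real_, nrow = n, ncol = p)
  for (k in 0:3) {
    rows <- seq.int(k + 1L, by = 4L, length.out = bytes_per_snp)
    rows <- rows[rows <= n]
    if (!length(rows)) next
    two_bits <- (codes[seq_along(rows), , drop = FALSE] %/% 4L^k) %% 4L
    geno[rows, ] <- .bed_code_to_count[two_bits + 1L]
  }
  ds <- genotype_dataset(
    geno,
    data.frame(id = bim$id, chrom = bim$chrom, pos = bim$pos,
               a1 = bim$a1, a2 = bim$a2, stringsAsFactors = FALSE),
    sample_ids = fam$iid
  )
  fam$pheno <- ifelse(fam$pheno %in% c(-9, 0), NA,
                      ifelse(fam$pheno == 2, 1, ifelse(fam$pheno == 1, 0, fam$pheno)))
  attr(ds, "fam") <- fam
  ds
}

#' Write a PLINK 1 binary fileset
#'
#' Writes `prefix.bed` (SNP-major), `prefix.bim` and `prefix.fam`.
#' `read_plink(write_plink(ds, prefix))` reproduces the genotype matrix
#' exactly, including missingness. Genotypes must be integer-valued
#' (imputed/fractional datasets cannot be stored in .bed).
#'
#' @param dataset a [genotype_dataset].
#' @param prefix output path prefix.
#' @param phenotype optional numeric vector written to the .fam phenotype
#'   column (binary 0/1 recoded to 1/2; NA to -9).
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(dataset, prefix, phenotype = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  G <- dataset$genotypes
  n <- nrow(G); p <- ncol(G)
  vals <- G[!is.na(G)]
  if (any(vals != round(vals)))
    stop("cannot write fractional (imputed) genotypes to .bed")
  # counts -> 2-bit codes: 2->00, NA->01, 1->10, 0->11
  code <- matrix(3L, n, p)
  code[G == 1] <- 2L
  code[is.na(G)] <- 1L
  code[G == 2] <- 0L
  bytes_per_snp <- ceiling(n / 4)
  padded <- matrix(0L, bytes_per_snp * 4L, p)
  padded[seq_len(n), ] <- code
  shifted <- padded * 4L^((seq_len(bytes_per_snp * 4L) - 1L) %% 4L)
  packed <- rowsum(shifted, group = rep(seq_len(bytes_per_snp), each = 4L))
  body <- as.raw(as.vector(packed))
  writeBin(c(as.raw(c(0x6C, 0x1B, 0x01)), body), paste0(prefix, ".bed"))
  v <- dataset$variants
  utils::write.table(
    data.frame(v$chrom, v$id, 0, v$pos, v$a1, v$a2),
    paste0(prefix, ".bim"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  ph <- if (is.null(phenotype)) rep(-9, n) else {
    stopifnot(length(phenotype) == n)
    ifelse(is.na(phenotype), -9,
           ifelse(phenotype == 1, 2, ifelse(phenotype == 0, 1, phenotype)))
  }
  utils::write.table(
    data.frame(dataset$sample_ids, dataset$sample_ids, 0, 0, 0, ph),
    paste0(prefix, ".fam"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read/write a delimited-text genotype fallback
#'
#' A TSV genotype matrix (rows = samples, first column = sample id) plus a
#' TSV variant map with header (`id`, `chrom`, `pos`, `a1`, `a2`).
#'
#' @param geno_path,variants_path paths to the two TSV files.
#' @return A [genotype_dataset].
#' @export
read_genotype_tsv <- function(geno_path, variants_path) {
  gm <- utils::read.table(geno_path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  variants <- utils::read.table(variants_path, header = TRUE, sep = "\t",
                                colClasses = c(id = "character",
                                               chrom = "character",
                                               pos = "integer",
                                               a1 = "character",
                                               a2 = "character"))
  genotype_dataset(as.matrix(gm[, -1, drop = FALSE]), variants,
                   sample_ids = as.character(gm[[1]]))
}

#' @rdname read_genotype_tsv
#' @param dataset a [genotype_dataset].
#' @param prefix output prefix; writes `prefix_genotypes.tsv` and
#'   `prefix_variants.tsv`.
#' @export
write_genotype_tsv <- function(dataset, prefix) {
  gm <- data.frame(sample_id = dataset$sample_ids, dataset$genotypes,
                   check.names = FALSE)
  colnames(gm) <- c("sample_id", dataset$variants$id)
  utils::write.table(gm, paste0(prefix, "_genotypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$variants, paste0(prefix, "_variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Mean-impute missing genotypes
#'
#' Replaces missing allele counts by the per-SNP mean computed on `fit_rows`
#' only (typically the training rows), so no information leaks from held-out
#' samples. Imputed values may be fractional.
#'
#' @param dataset a [genotype_dataset].
#' @param fit_rows integer indices of rows used to learn the column means;
#'   defaults to all rows.
#' @return A [genotype_dataset] with no missing values.
#' @export
impute_mean <- function(dataset, fit_rows = seq_len(nrow(dataset$genotypes))) {
  G <- dataset$genotypes
  if (!anyNA(G)) return(dataset)
  mu <- colMeans(G[fit_rows, , drop = FALSE], na.rm = TRUE)
  bad <- !is.finite(mu)
  if (any(bad))
    stop("all-missing column(s) on the fitting rows: ",
         paste(dataset$variants$id[bad], collapse = ", "))
  miss <- which(is.na(G), arr.ind = TRUE)
  G[miss] <- mu[miss[, 2]]
  out <- genotype_dataset(G, dataset$variants, dataset$sample_ids,
                          validate = FALSE)
  attr(out, "fam") <- attr(dataset, "fam")
  out
}

#' Column standardization learned on a row subset
#'
#' Computes per-SNP means and scales on `fit_rows` so that the standardized
#' columns have zero mean and unit variance on those rows. The population
#' (divide-by-n) standard deviation is used, which makes the liability
#' simulator's variance bookkeeping exact.
#'
#' @param dataset a [genotype_dataset] or plain numeric matrix (no missing
#'   values allowed).
#' @param fit_rows row indices used to learn means and scales.
#' @return A `standardized_view`: list with `means`, `scales` (length p).
#' @export
standardize <- function(dataset, fit_rows = NULL) {
  X <- if (inherits(dataset, "genotype_dataset")) dataset$genotypes else dataset
  if (is.null(fit_rows)) fit_rows <- seq_len(nrow(X))
  if (anyNA(X[fit_rows, , drop = FALSE]))
    stop("standardize() requires imputed (non-missing) genotypes")
  Xf <- X[fit_rows, , drop = FALSE]
  m <- colMeans(Xf)
  v <- colMeans(Xf^2) - m^2
  s <- sqrt(pmax(v, 0))
  const <- s <= .Machine$double.eps^0.5 * pmax(1, abs(m))
  if (any(const)) {
    ids <- if (inherits(dataset, "genotype_dataset"))
      dataset$variants$id[const] else which(const)
    stop("constant column(s) on the fitting rows: ",
         paste(ids, collapse = ", "))
  }
  structure(list(means = m, scales = s), class = "standardized_view")
}

#' Apply a standardized view to rows of a matrix
#'
#' @param view a `standardized_view` from [standardize()].
#' @param dataset the source [genotype_dataset] or matrix.
#' @param rows row indices to transform (default all).
#' @return Numeric matrix of standardized values.
#' @export
apply_standardization <- function(view, dataset, rows = NULL) {
  X <- if (inherits(dataset, "genotype_dataset")) dataset$genotypes else dataset
  if (is.null(rows)) rows <- seq_len(nrow(X))
  sweep(sweep(X[rows, , drop = FALSE], 2, view$means, "-"),
        2, view$scales, "/")
}
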