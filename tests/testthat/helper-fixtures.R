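# small programmatic fixtures shared across test files

make_toy_dataset <- function(n = 20, p = 8, seed = 1, chrom = NULL,
                             pos = NULL) {
  set.seed(seed)
  G <- matrix(rbinom(n * p, 2, 0.4), n, p)
  # guard against constant columns in tiny draws
  for (j in seq_len(p)) if (length(unique(G[, j])) == 1L) G[1, j] <- (G[1, j] + 1) %% 3
  if (is.null(chrom)) chrom <- rep("1", p)
  if (is.null(pos)) pos <- seq_len(p) * 1000L
  genotype_dataset(G, data.frame(id = sprintf("rs%d", seq_len(p)),
                                 chrom = chrom, pos = pos,
                                 a1 = "A", a2 = "G"))
}

# dataset whose columns have exactly specified correlation structure is hard
# to construct from 0/1/2 counts; duplicated/independent columns suffice for
# the forced clumping cases
make_ld_pair_dataset <- function(n = 40, seed = 2) {
  set.seed(seed)
  base <- rbinom(n, 2, 0.5)
  other <- rbinom(n, 2, 0.5)
  while (abs(cor(base, other)) > 0.3) other <- rbinom(n, 2, 0.5)
  G <- cbind(base, base, other)   # columns 1,2 duplicated (r2 = 1)
  genotype_dataset(G, data.frame(id = c("s1", "s2", "s3"), chrom = "1",
                                 pos = c(1000L, 2000L, 3000L),
                                 a1 = "A", a2 = "G"))
}

std_pop <- function(X) {
  m <- colMeans(X)
  s <- sqrt(colMeans(X^2) - m^2)
  sweep(sweep(X, 2, m, "-"), 2, s, "/")
}
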