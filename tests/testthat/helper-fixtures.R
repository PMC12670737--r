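# small fixture builders and independent oracles used across test files

# genotype matrix from a bare code matrix, one chromosome, positions in order
tiny_gm <- function(codes, chrom = NULL) {
  codes <- as.matrix(codes)
  m <- ncol(codes)
  if (is.null(chrom)) chrom <- rep("1", m)
  genotype_matrix(codes,
                  data.frame(id = paste0("m", seq_len(m)), chrom = chrom,
                             pos = seq_len(m) * 100L),
                  samples = paste0("S", seq_len(nrow(codes))))
}

# Hardy-Weinberg genotypes coded -1/0/1 (+1 = major homozygote)
hw_codes <- function(n, m, seed) {
  set.seed(seed)
  p <- runif(m, 0.1, 0.9)
  sapply(seq_len(m), function(j) {
    g <- rbinom(n, 2, p[j]) - 1          # dosage of one allele, centred
    g
  })
}

# orthogonal +-1 columns (pairwise Pearson r = 0) from an 8x8 Hadamard set
hadamard8 <- function() {
  h2 <- matrix(c(1, 1, 1, -1), 2, 2)
  h4 <- rbind(cbind(h2, h2), cbind(h2, -h2))
  rbind(cbind(h4, h4), cbind(h4, -h4))
}

# independent oracle: RR-BLUP via Henderson's mixed-model equations with
# shrinkage lambda = c * s2R / s2A, prediction b0 + Z a for all samples
rrblup_oracle <- function(y, M, centers, cc, s2a, s2r) {
  tr <- names(y)
  Z <- sweep(M[tr, , drop = FALSE], 2, centers, "-")
  m <- ncol(Z)
  lambda <- cc * s2r / s2a
  C <- rbind(cbind(length(y), t(colSums(Z))),
             cbind(colSums(Z), crossprod(Z) + lambda * diag(m)))
  rhs <- c(sum(y), crossprod(Z, y))
  sol <- solve(C, rhs)
  b0 <- sol[1]; a <- sol[-1]
  Zall <- sweep(M, 2, centers, "-")
  list(pred = drop(b0 + Zall %*% a), a = a, b0 = b0)
}

# signal-bearing toy phenotype on a code matrix (keeps REML off boundaries)
toy_trait <- function(X, h2, seed) {
  set.seed(seed)
  g <- drop(X %*% rnorm(ncol(X)))
  g <- (g - mean(g)) / sd(g) * sqrt(h2)
  setNames(g + rnorm(nrow(X), 0, sqrt(1 - h2)), rownames(X))
}

# independent oracle: Mantel r and permutation p by explicit loop
mantel_oracle <- function(A, B, n_perm, seed) {
  lt <- lower.tri(A)
  r_obs <- cor(A[lt], B[lt])
  set.seed(seed)
  hits <- 0L
  n <- nrow(A)
  for (i in seq_len(n_perm)) {
    pp <- sample.int(n)
    if (cor(A[lt], B[pp, pp][lt]) >= r_obs) hits <- hits + 1L
  }
  list(r = r_obs, p = (hits + 1) / (n_perm + 1))
}

# validity check for emitted haplotype blocks: at most `tolerance` adjacent
# joins below threshold and the final join not below threshold
blocks_valid <- function(bs, G, threshold, tolerance) {
  for (b in bs$blocks) {
    if (b$size < 2) return(FALSE)
    r2s <- vapply(seq_len(b$size - 1), function(i)
      ld_r2(G$codes[, b$markers[i]], G$codes[, b$markers[i + 1]]), numeric(1))
    low <- r2s < threshold
    if (sum(low) > tolerance) return(FALSE)
    if (low[length(low)]) return(FALSE)
  }
  TRUE
}

# fraction of planted within-block adjacent pairs co-assigned by a block set
coassignment <- function(true_blocks, emitted) {
  pair_keys <- function(bs) {
    unlist(lapply(bs$blocks, function(b) {
      if (b$size < 2) return(character(0))
      paste(b$markers[-b$size], b$markers[-1])
    }))
  }
  planted <- pair_keys(true_blocks)
  mean(planted %in% pair_keys(emitted))
}

# the frozen fully-blocked study conditions used by pipeline-level tests
blocked_sim_config <- function(n_samples = 300, seed = 42) {
  sim_config(n_samples = n_samples, n_chromosomes = 5,
             blocks_per_chromosome = 50, markers_per_block = c(6, 10),
             n_variants_per_block = c(2, 2), inter_block_markers = 0,
             within_block_mutation_rate = 0.02, n_subpops = 2,
             subpop_divergence = 0.9, h2 = 0.5, seed = seed)
}

write_tiny_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "1\t100\tm1\tA\tC\t.\tPASS\t.\tGT\t0/1\t0/0\t0/0",
    "1\t200\tm2\tA\tC,T\t.\tPASS\t.\tGT\t0/0\t1/1\t2/2",
    "1\t300\tm3\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/0\t1/1",
    "1\t400\tm4\tT\tG\t.\tPASS\t.\tGT\t1/1\t1/1\t0/0"
  ), path)
  path
}
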