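#' Configuration for the synthetic genotype/trait generator
#'
#' The generator plants contiguous haplotype blocks: every block carries a
#' small number of distinct founder variants, each sample copies one variant
#' per block (independently across blocks), and blocks are separated by
#' mutually independent filler markers. Variants within a block are built
#' from a founder pattern by flipping prefixes at recombination-like cut
#' points, so within-block flanking LD is high (r-squared 1 away from cut
#' points) while between-block LD is near 0. Lines are fully homozygous
#' (codes -1/+1).
#'
#' @param n_samples number of lines (default 300).
#' @param n_chromosomes number of chromosomes (default 5).
#' @param blocks_per_chromosome planted blocks per chromosome (default 10).
#' @param markers_per_block integer range c(min, max) (default c(6, 10)).
#' @param n_variants_per_block integer range (default c(2, 3)).
#' @param inter_block_markers independent filler markers between consecutive
#'   blocks (default 2; 0 gives fully-blocked data).
#' @param within_block_mutation_rate per-call probability of flipping a
#'   within-block code, softening planted LD (default 0).
#' @param inter_block_ld probability that a sample's variant draw for a
#'   block reuses the latent ancestry of the previous block on the same
#'   chromosome (default 0 = independent blocks). Positive values emulate
#'   LD decaying smoothly across block borders, which correlates the
#'   per-block features of neighbouring blocks as in real genomes.
#' @param n_subpops number of subpopulations (default 1 = unstructured).
#'   With more than one, every block's variant frequencies are drawn
#'   separately per subpopulation, emulating the family/population structure
#'   of breeding material; this is what makes per-block features mutually
#'   correlated genome-wide, as observed on real panels.
#' @param subpop_divergence with structured panels, the probability that a
#'   sample carries its subpopulation's preferred block variant (preferred
#'   variants differ between subpopulations, as between divergently selected
#'   heterotic pools). 0 (default) disables the mechanism.
#' @param h2 trait heritability on the realised-variance scale (default 0.5).
#' @param epistatic_fraction fraction of blocks receiving an additional
#'   within-block pairwise interaction term (default 0).
#' @param population "lines" or "hybrids".
#' @param parents_per_side for hybrids, c(parents1, parents2) (default c(20, 20)).
#' @param seed integer seed, required for reproducibility.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(n_samples = 300, n_chromosomes = 5,
                       blocks_per_chromosome = 10,
                       markers_per_block = c(6, 10),
                       n_variants_per_block = c(2, 3),
                       inter_block_markers = 2,
                       within_block_mutation_rate = 0,
                       inter_block_ld = 0,
                       n_subpops = 1, subpop_divergence = 0,
                       h2 = 0.5, epistatic_fraction = 0,
                       population = c("lines", "hybrids"),
                       parents_per_side = c(20, 20),
                       seed = 1L) {
  population <- match.arg(population)
  stopifnot(n_samples >= 2, n_chromosomes >= 1, blocks_per_chromosome >= 1,
            length(markers_per_block) == 2, markers_per_block[1] >= 2,
            length(n_variants_per_block) == 2, n_variants_per_block[1] >= 1,
            inter_block_markers >= 0,
            within_block_mutation_rate >= 0, within_block_mutation_rate <= 1,
            inter_block_ld >= 0, inter_block_ld <= 1, n_subpops >= 1,
            subpop_divergence >= 0, subpop_divergence <= 1,
            h2 >= 0, h2 <= 1, epistatic_fraction >= 0, epistatic_fraction <= 1)
  structure(as.list(environment()), class = "sim_config")
}

# guard against sample(n, 1) scalar expansion when a range is degenerate
sample_range <- function(r) if (r[1] == r[2]) r[1] else sample(seq(r[1], r[2]), 1)

# k distinct variant patterns over nm markers: founder pattern with prefix
# flips at spread-out cut points. k = 2 gives the founder and its complement
# (r2 = 1 at every adjacent pair); each additional variant adds one interior
# cut point where LD drops but stays positive.
make_variant_patterns <- function(nm, k) {
  if (k > 2^nm) stop("infeasible: ", k, " variants over ", nm, " markers")
  base <- sample(c(-1, 1), nm, replace = TRUE)
  cuts <- if (k == 1) 0 else round(seq(0, nm, length.out = k))
  pat <- t(vapply(cuts, function(cpt) {
    v <- base
    if (cpt > 0) v[seq_len(cpt)] <- -v[seq_len(cpt)]
    v
  }, numeric(nm)))
  pat
}

#' Simulate line genotypes with planted haplotype blocks
#'
#' @param cfg a \code{sim_config}.
#' @return list with \code{G} (a complete \code{genotype_matrix}),
#'   \code{true_blocks} (a \code{haploblock_set} of the planted blocks),
#'   \code{variants} (per block, the founder variant patterns), and
#'   \code{assignment} (samples x blocks matrix of copied variant indices).
#' @export
simulate_genotypes <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_samples
  cols <- list(); chroms <- character(0); block_idx <- list()
  variants <- list(); assignment <- list()
  col_at <- 0L
  subpop <- rep_len(seq_len(cfg$n_subpops), n)
  for (chr in seq_len(cfg$n_chromosomes)) {
    # latent ancestry quantile per sample, optionally carried across blocks
    u <- stats::runif(n)
    for (b in seq_len(cfg$blocks_per_chromosome)) {
      nm <- sample_range(cfg$markers_per_block)
      k <- sample_range(cfg$n_variants_per_block)
      pat <- make_variant_patterns(nm, k)
      # Dirichlet-uniform variant frequencies so minor variants exist,
      # drawn per subpopulation when the panel is structured
      W <- vapply(seq_len(cfg$n_subpops), function(q) {
        w <- stats::rgamma(k, 1); w / sum(w)
      }, numeric(k))
      if (b > 1) {
        redraw <- stats::runif(n) >= cfg$inter_block_ld
        u[redraw] <- stats::runif(sum(redraw))
      }
      a <- vapply(seq_len(n), function(i)
        cut(u[i], breaks = c(0, cumsum(W[, subpop[i]])), labels = FALSE,
            include.lowest = TRUE), integer(1))
      if (cfg$n_subpops > 1 && cfg$subpop_divergence > 0) {
        # divergently preferred variants (distinct across subpops when k allows)
        pref <- (sample.int(k) - 1L)[(seq_len(cfg$n_subpops) - 1L) %% k + 1L] + 1L
        hit <- stats::runif(n) < cfg$subpop_divergence
        a[hit] <- pref[subpop[hit]]
      }
      X <- pat[a, , drop = FALSE]
      if (cfg$within_block_mutation_rate > 0) {
        flip <- matrix(stats::runif(n * nm) < cfg$within_block_mutation_rate, n, nm)
        X[flip] <- -X[flip]
      }
      bi <- length(variants) + 1L
      variants[[bi]] <- pat
      assignment[[bi]] <- a
      block_idx[[bi]] <- list(chrom = as.character(chr),
                              markers = col_at + seq_len(nm), size = nm)
      cols[[length(cols) + 1L]] <- X
      chroms <- c(chroms, rep(as.character(chr), nm))
      col_at <- col_at + nm
      if (cfg$inter_block_markers > 0 &&
          !(b == cfg$blocks_per_chromosome)) {
        Fm <- vapply(seq_len(cfg$inter_block_markers), function(i) {
          p <- stats::runif(1, 0.2, 0.8)
          sample(c(1, -1), n, replace = TRUE, prob = c(p, 1 - p))
        }, numeric(n))
        cols[[length(cols) + 1L]] <- Fm
        chroms <- c(chroms, rep(as.character(chr), cfg$inter_block_markers))
        col_at <- col_at + cfg$inter_block_markers
      }
    }
  }
  codes <- do.call(cbind, cols)
  m <- ncol(codes)
  map <- data.frame(id = sprintf("m%05d", seq_len(m)), chrom = chroms,
                    pos = stats::ave(seq_len(m), chroms, FUN = seq_along) * 1000L)
  G <- genotype_matrix(codes, map, samples = sprintf("S%04d", seq_len(n)))
  unassigned <- setdiff(seq_len(m), unlist(lapply(block_idx, `[[`, "markers")))
  true_blocks <- new_haploblock_set(block_idx, unassigned, m)
  list(G = G, true_blocks = true_blocks, variants = variants,
       assignment = do.call(cbind, assignment), subpop = subpop)
}

#' Simulate a quantitative trait on a genotype matrix
#'
#' Additive per-marker effects are drawn Gaussian; for a fraction of blocks a
#' within-block pairwise epistatic term (product of centred codes of a random
#' marker pair) is added. Residual noise is rescaled so the realised ratio
#' Var(g)/Var(y) equals \code{h2} exactly (up to floating point).
#'
#' @param G a complete \code{genotype_matrix}.
#' @param true_blocks a \code{haploblock_set} (used to place epistatic pairs).
#' @param h2 heritability of the realised phenotype.
#' @param epistatic_fraction fraction of blocks with an epistatic pair.
#' @param seed integer seed.
#' @return list with \code{y} (named phenotype vector), \code{g} (genetic
#'   values), \code{marker_effects}, and \code{realised_h2}.
#' @export
simulate_trait <- function(G, true_blocks = NULL, h2 = 0.5,
                           epistatic_fraction = 0, seed = 1L) {
  stopifnot(inherits(G, "genotype_matrix"), !anyNA(G$codes))
  set.seed(seed)
  m <- ncol(G$codes); n <- nrow(G$codes)
  a <- stats::rnorm(m, 0, 1)
  g <- drop(G$codes %*% a)
  if (epistatic_fraction > 0) {
    if (is.null(true_blocks)) stop("epistasis needs a block set")
    nb <- length(true_blocks$blocks)
    chosen <- sample.int(nb, max(1, round(epistatic_fraction * nb)))
    Zc <- scale(G$codes, center = TRUE, scale = FALSE)
    g_epi <- rep(0, n)
    for (b in chosen) {
      mk <- true_blocks$blocks[[b]]$markers
      if (length(mk) < 2) next
      pr <- sample(mk, 2)
      g_epi <- g_epi + stats::rnorm(1) * Zc[, pr[1]] * Zc[, pr[2]]
    }
    # scale the interaction part so a fraction f of blocks contributes
    # f * Var(additive) of (local) epistatic variance
    if (stats::var(g_epi) > 0)
      g <- g + g_epi * sqrt(epistatic_fraction * stats::var(g) /
                              stats::var(g_epi))
  }
  g <- g - mean(g)
  vg <- stats::var(g)
  if (h2 == 0) {
    g <- g * 0
    y <- stats::rnorm(n)
  } else if (h2 == 1) {
    y <- g
  } else {
    if (vg == 0) stop("degenerate genetic values: variance 0")
    e <- stats::rnorm(n)
    # orthogonalise against g so the realised variance ratio is exact
    e <- stats::residuals(stats::lm(e ~ g))
    e <- e * sqrt(vg * (1 - h2) / h2 / stats::var(e))
    y <- g + e
  }
  # standardise to unit phenotypic variance (the ratio h2 is scale-free)
  s <- stats::sd(y)
  if (s > 0) {
    y <- y / s; g <- g / s; a <- a / s
  }
  names(y) <- G$samples
  list(y = y, g = stats::setNames(g, G$samples), marker_effects = a,
       realised_h2 = if (stats::var(y) > 0) stats::var(g) / stats::var(y) else NA_real_)
}

#' Simulate a hybrid factorial with planted GCA/SCA variances
#'
#' Homozygous parents are simulated per side; hybrids are all (or a sampled
#' subset of) parent1 x parent2 crosses. Hybrid phenotypes follow
#' y = mu + gca1 + gca2 + sca + e with gca1 ~ N(0, s2_1 G1),
#' gca2 ~ N(0, s2_2 G2), sca ~ N(0, s2_s (G1 kron G2) restricted to the
#' realised crosses), where G1, G2 are VanRaden method I relationship
#' matrices of the simulated parents.
#'
#' @param cfg a \code{sim_config} with \code{population = "hybrids"}.
#' @param s2_1,s2_2,s2_s,s2_e planted variance components.
#' @param n_crosses number of crosses to sample (default: the full factorial).
#' @return list with \code{parents1}, \code{parents2} (genotype matrices),
#'   \code{crosses} (cross table), \code{hybrids} (hybrid genotype matrix),
#'   \code{y}, and the planted \code{truth} (gca/sca draws and variances).
#' @export
simulate_factorial <- function(cfg = sim_config(population = "hybrids"),
                               s2_1 = 1, s2_2 = 1, s2_s = 0.25, s2_e = 0.5,
                               n_crosses = NULL) {
  stopifnot(inherits(cfg, "sim_config"), cfg$population == "hybrids")
  np1 <- cfg$parents_per_side[1]; np2 <- cfg$parents_per_side[2]
  # one simulated panel split into the two parental pools so both share a map
  cfgp <- cfg; cfgp$n_samples <- np1 + np2; cfgp$population <- "lines"
  simp <- simulate_genotypes(cfgp)
  ids1 <- sprintf("P1_%03d", seq_len(np1))
  ids2 <- sprintf("P2_%03d", seq_len(np2))
  p1 <- genotype_matrix(simp$G$codes[seq_len(np1), , drop = FALSE],
                        simp$G$map, samples = ids1)
  p2 <- genotype_matrix(simp$G$codes[np1 + seq_len(np2), , drop = FALSE],
                        simp$G$map, samples = ids2)
  set.seed(cfg$seed + 2000L)
  all_cr <- expand.grid(parent1 = p1$samples, parent2 = p2$samples,
                        stringsAsFactors = FALSE)
  if (!is.null(n_crosses) && n_crosses < nrow(all_cr))
    all_cr <- all_cr[sort(sample.int(nrow(all_cr), n_crosses)), , drop = FALSE]
  crosses <- data.frame(hybrid = sprintf("H%04d", seq_len(nrow(all_cr))),
                        all_cr, stringsAsFactors = FALSE)
  G1 <- grm_vanraden(p1$codes); G2 <- grm_vanraden(p2$codes)
  draw_mvn <- function(K, s2) {
    ev <- eigen(K$matrix, symmetric = TRUE)
    L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(K$matrix))
    drop(L %*% stats::rnorm(nrow(K$matrix))) * sqrt(s2)
  }
  gca1 <- stats::setNames(draw_mvn(G1, s2_1), p1$samples)
  gca2 <- stats::setNames(draw_mvn(G2, s2_2), p2$samples)
  i1 <- match(crosses$parent1, p1$samples)
  i2 <- match(crosses$parent2, p2$samples)
  Ks <- G1$matrix[i1, i1] * G2$matrix[i2, i2]   # rows of G1 (x) G2 for realised pairs
  evs <- eigen(Ks, symmetric = TRUE)
  sca <- drop(evs$vectors %*% diag(sqrt(pmax(evs$values, 0)), nrow(Ks)) %*%
                stats::rnorm(nrow(Ks))) * sqrt(s2_s)
  e <- stats::rnorm(nrow(crosses), 0, sqrt(s2_e))
  y <- stats::setNames(10 + gca1[crosses$parent1] + gca2[crosses$parent2] +
                         sca + e, crosses$hybrid)
  hybrids <- make_hybrids(p1_p2_union(p1, p2), crosses)
  list(parents1 = p1, parents2 = p2, crosses = crosses, hybrids = hybrids,
       y = y,
       truth = list(gca1 = gca1, gca2 = gca2, sca = stats::setNames(sca, crosses$hybrid),
                    s2_1 = s2_1, s2_2 = s2_2, s2_s = s2_s, s2_e = s2_e))
}

# stack two parental panels sharing a marker map into one genotype matrix
p1_p2_union <- function(p1, p2) {
  stopifnot(identical(p1$map$id, p2$map$id))
  genotype_matrix(rbind(p1$codes, p2$codes), p1$map,
                  samples = c(p1$samples, p2$samples))
}
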