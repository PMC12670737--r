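test_that("variant enumeration matches the planted ground truth", {
  # all samples identical in a block -> one variant with count n
  G <- tiny_gm(matrix(1, 5, 2) * rep(c(1, -1), each = 5 * 0 + 1)[1])
  G$codes[, 2] <- -1
  bs <- haploencoder:::new_haploblock_set(
    list(list(chrom = "1", markers = 1:2, size = 2L)), integer(0), 2L)
  cat1 <- enumerate_variants(G, bs)
  expect_equal(nrow(cat1$variants[[1]]$patterns), 1)
  expect_equal(cat1$variants[[1]]$counts, 5L)
  # homozygous lines: a 2-marker block has at most 4 variants
  set.seed(2)
  G2 <- tiny_gm(matrix(sample(c(-1, 1), 200, TRUE), 100, 2))
  cat2 <- enumerate_variants(G2, bs)
  expect_lte(nrow(cat2$variants[[1]]$patterns), 4)
  expect_equal(sum(cat2$variants[[1]]$counts), 100)
  # planted 3-variant blocks are recovered exactly
  sim <- simulate_genotypes(sim_config(n_samples = 300, n_chromosomes = 1,
                                       blocks_per_chromosome = 4,
                                       n_variants_per_block = c(3, 3),
                                       within_block_mutation_rate = 0,
                                       seed = 5))
  cat3 <- enumerate_variants(sim$G, sim$true_blocks)
  for (b in 1:4)
    expect_equal(nrow(cat3$variants[[b]]$patterns), 3)
})

test_that("autoencoder variant effects equal the hand-computed forward pass", {
  sim <- simulate_genotypes(sim_config(n_samples = 50, n_chromosomes = 1,
                                       blocks_per_chromosome = 2,
                                       n_variants_per_block = c(2, 2),
                                       markers_per_block = c(2, 3), seed = 15))
  tr <- simulate_trait(sim$G, sim$true_blocks, h2 = 1, seed = 16)
  fit <- block_autoencoder(sim$G, sim$true_blocks,
                           block_ae_config(epochs = 10, decoder_hidden = 20,
                                           seed = 8),
                           y = tr$y)
  cat1 <- enumerate_variants(sim$G, sim$true_blocks)
  E <- ae_variant_effects(fit, cat1)
  # manual: for a block without optional layer, z = pat %*% W + b, eff = z * wz
  b <- 1
  e <- fit$enc[[b]]
  expect_false(e$optional)
  pat <- cat1$variants[[b]]$patterns
  manual <- (drop(pat %*% e$W) + e$b) * fit$wz[b]
  expect_equal(E$effect_ae[[b]], manual, tolerance = 1e-10)
  # zero yield-head weight silences a block
  fit0 <- fit; fit0$wz[1] <- 0
  E0 <- ae_variant_effects(fit0, cat1)
  expect_true(all(E0$effect_ae[[1]] == 0))
  # unseen variants still get finite effects
  novel <- cat1
  novel$variants[[1]]$patterns <- -cat1$variants[[1]]$patterns
  En <- ae_variant_effects(fit, novel)
  expect_true(all(is.finite(En$effect_ae[[1]])))
  # a model without yield head is refused
  un <- block_autoencoder(sim$G, sim$true_blocks,
                          block_ae_config(epochs = 1, decoder_hidden = 20, seed = 8))
  expect_error(ae_variant_effects(un, cat1), "yield head")
})

test_that("method comparison reports 1 for identical and -1 for negated effects", {
  bs <- haploencoder:::new_haploblock_set(
    list(list(chrom = "1", markers = 1:2, size = 2L),
         list(chrom = "1", markers = 3:4, size = 2L)), integer(0), 4L)
  variants <- list(
    list(patterns = rbind(c(1, 1), c(-1, -1), c(1, -1)), counts = c(2L, 2L, 1L),
         members = list(1:2, 3:4, 5L)),
    list(patterns = rbind(c(1, 1), c(-1, -1)), counts = c(3L, 2L),
         members = list(1:3, 4:5)))
  E <- haploencoder:::new_block_variant_effects(
    bs, variants,
    effect_ae = list(c(1, 2, 4), c(1, 2)),
    effect_sum = list(c(1, 2, 4), c(1, 2)))
  cmp <- compare_effect_methods(E)
  expect_equal(cmp$correlation[1], 1)
  expect_false(cmp$defined[2])          # only 2 variants
  E$effect_ae <- lapply(E$effect_sum, function(v) -v)
  cmp2 <- compare_effect_methods(E)
  expect_equal(cmp2$correlation[1], -1)
  # with the filter lowered, 2-variant blocks become defined
  cmp3 <- compare_effect_methods(E, min_variants = 2)
  expect_equal(cmp3$correlation[2], -1)
  expect_error(compare_effect_methods(
    haploencoder:::new_block_variant_effects(bs, variants,
                                             effect_ae = E$effect_ae)),
    "both methods")
})

test_that("effect scaling divides by the largest magnitude and is idempotent", {
  bs <- haploencoder:::new_haploblock_set(
    list(list(chrom = "1", markers = 1:2, size = 2L)), integer(0), 2L)
  variants <- list(list(patterns = rbind(c(1, 1), c(-1, -1)),
                        counts = c(1L, 1L), members = list(1L, 2L)))
  E <- haploencoder:::new_block_variant_effects(bs, variants,
                                                effect_ae = list(c(2, -1)),
                                                effect_sum = list(c(-3)))
  S <- scale_effects(E)
  expect_equal(S$effect_ae[[1]], c(1, -0.5))
  expect_equal(S$effect_sum[[1]], -1)     # signs preserved
  expect_equal(scale_effects(S)$effect_ae, S$effect_ae)
  mx <- max(abs(unlist(S$effect_ae)))
  expect_equal(mx, 1)
  Ez <- haploencoder:::new_block_variant_effects(bs, variants,
                                                 effect_ae = list(c(0, 0)))
  expect_error(scale_effects(Ez), "zero")
})

test_that("AE and summed effects agree in direction on additive simulations", {
  sim <- simulate_genotypes(sim_config(n_samples = 200, n_chromosomes = 2,
                                       blocks_per_chromosome = 10,
                                       n_variants_per_block = c(3, 4),
                                       inter_block_markers = 0,
                                       within_block_mutation_rate = 0.02,
                                       seed = 25))
  tr <- simulate_trait(sim$G, sim$true_blocks, h2 = 0.8, seed = 26)
  bs <- build_blocks(sim$G)
  fit <- block_autoencoder(sim$G, bs,
                           block_ae_config(epochs = 100, decoder_hidden = 500,
                                           seed = 9),
                           y = tr$y)
  cat1 <- enumerate_variants(sim$G, bs)
  gfit <- gblup(tr$y, grm_vanraden(sim$G))
  me <- marker_effects(gfit, sim$G)
  E <- blockwise_effect_sums(me, bs, cat1)
  E <- ae_variant_effects(fit, cat1, effects = E)
  cmp <- compare_effect_methods(E)
  expect_gt(attr(cmp, "summary")$median, 0)
  tab <- effects_table(E)
  expect_true(all(c("variant", "count", "effect_ae", "effect_sum") %in% names(tab)))
})
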