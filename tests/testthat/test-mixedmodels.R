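test_that("VanRaden I matches hand computation and known properties", {
  # 2x2 toy: both columns at p = 0.5, codes +-1 -> c = 1, G = ZZ'
  M <- rbind(A = c(1, -1), B = c(-1, 1))
  g <- grm_vanraden(M)
  expect_equal(g$c, 1)
  expect_equal(unname(g$matrix), matrix(c(2, -2, -2, 2), 2))
  # identical rows are indistinguishable
  M2 <- rbind(A = c(1, -1, 1), B = c(1, -1, 1), C = c(-1, 1, -1))
  g2 <- grm_vanraden(M2)
  expect_equal(g2$matrix["A", "A"], g2$matrix["A", "B"])
  expect_equal(g2$matrix["A", "A"], g2$matrix["B", "B"])
  expect_error(grm_vanraden(matrix(1, 3, 4)), "monomorphic")
  # mean diagonal ~ 1 under Hardy-Weinberg
  X <- hw_codes(500, 1000, seed = 31)
  expect_equal(mean(diag(grm_vanraden(X)$matrix)), 1, tolerance = 0.05)
})

test_that("relationship matrices round-trip through the delimited format", {
  X <- hw_codes(10, 40, seed = 77)
  rownames(X) <- paste0("S", 1:10)
  G <- grm_vanraden(X)
  f <- tempfile()
  write_grm(G, f)
  expect_equal(read_grm(f), G$matrix, tolerance = 1e-12)
})

test_that("line GBLUP handles the degenerate constant-phenotype boundary", {
  X <- hw_codes(20, 50, seed = 1)
  rownames(X) <- paste0("S", 1:20)
  y <- setNames(rep(5, 20), rownames(X))
  fit <- gblup(y, grm_vanraden(X))
  expect_equal(fit$sigma2[["A"]], 0)
  expect_equal(unname(predict(fit)), rep(5, 20))
})

test_that("REML recovers heritability from simulated data", {
  h2_hat <- sapply(1:8, function(r) {
    X <- hw_codes(400, 300, seed = 100 + r)
    rownames(X) <- paste0("S", 1:400)
    G <- tiny_gm(X)
    tr <- simulate_trait(G, h2 = 0.5, seed = 200 + r)
    fit <- gblup(tr$y, grm_vanraden(X))
    fit$sigma2[["A"]] / sum(fit$sigma2)
  })
  expect_gt(median(h2_hat), 0.35)
  expect_lt(median(h2_hat), 0.65)
})

test_that("GBLUP equals the RR-BLUP oracle and back-transformation is exact", {
  set.seed(50)
  for (rep in 1:10) {
    X <- hw_codes(20, 50, seed = 300 + rep)
    rownames(X) <- paste0("S", 1:20)
    G <- grm_vanraden(X)
    y <- toy_trait(X, h2 = 0.5, seed = 400 + rep)
    fit <- gblup(y, G, sigma2 = c(A = 2, R = 0.5))
    or <- rrblup_oracle(y, X, G$centers, G$c, 2, 0.5)
    expect_lt(max(abs(predict(fit) - or$pred)), 1e-6)
    me <- marker_effects(fit, X)
    expect_lt(max(abs(me$a - or$a)), 1e-6)
    # reconstruction identity: Z a reproduces the BLUPs
    Z <- sweep(X, 2, G$centers, "-")
    expect_lt(max(abs(drop(Z %*% me$a) - fit$u)), 1e-8)
  }
  # zero BLUPs give zero marker effects
  X <- hw_codes(20, 30, seed = 999); rownames(X) <- paste0("S", 1:20)
  G <- grm_vanraden(X)
  fit <- gblup(setNames(rep(1, 20), rownames(X)), G)
  expect_true(all(marker_effects(fit, X)$a == 0))
})

test_that("predictions for unphenotyped samples flow through their G rows", {
  X <- hw_codes(60, 200, seed = 41)
  rownames(X) <- paste0("S", 1:60)
  G <- tiny_gm(X)
  tr <- simulate_trait(G, h2 = 0.9, seed = 42)
  fit <- gblup(tr$y[1:45], grm_vanraden(X))
  pred <- predict(fit, paste0("S", 46:60))
  expect_gt(cor(pred, tr$y[46:60]), 0.3)
  expect_error(predict(fit, "nope"), "unknown sample")
})

test_that("GCA/SCA model recovers planted variance components", {
  cfg <- sim_config(n_samples = 10, n_chromosomes = 2, blocks_per_chromosome = 8,
                    population = "hybrids", parents_per_side = c(25, 25),
                    seed = 61)
  fac <- simulate_factorial(cfg, s2_1 = 1, s2_2 = 1, s2_s = 0.25, s2_e = 0.5,
                            n_crosses = 450)
  G1 <- grm_vanraden(fac$parents1); G2 <- grm_vanraden(fac$parents2)
  fit <- gblup_gca_sca(fac$y, G1, G2, fac$crosses)
  expect_lt(abs(fit$sigma2[["gca1"]] - 1) / 1, 0.5)
  expect_lt(abs(fit$sigma2[["gca2"]] - 1) / 1, 0.5)
  expect_lt(abs(fit$sigma2[["R"]] - 0.5) / 0.5, 0.5)
  expect_gt(cor(fit$fitted, fac$y), 0.8)
  # unknown parents are refused
  bad <- data.frame(hybrid = "HX", parent1 = "nope", parent2 = fac$crosses$parent2[1])
  yb <- setNames(1:3, c("HX", fac$crosses$hybrid[1:2]))
  expect_error(gblup_gca_sca(yb, G1, G2, rbind(bad, fac$crosses[1:2, ])),
               "unknown parent")
})

test_that("EM iterations never decrease the restricted likelihood", {
  cfg <- sim_config(n_samples = 10, n_chromosomes = 1, blocks_per_chromosome = 6,
                    population = "hybrids", parents_per_side = c(10, 10),
                    seed = 71)
  fac <- simulate_factorial(cfg, n_crosses = 80)
  fit <- gblup_gca_sca(fac$y, grm_vanraden(fac$parents1),
                       grm_vanraden(fac$parents2), fac$crosses,
                       method = "em", tol = 1e-6)
  expect_true(all(diff(fit$trace) > -1e-6))
})

test_that("the SCA covariance factorises over parents and stays PSD", {
  cfg <- sim_config(n_samples = 10, n_chromosomes = 1, blocks_per_chromosome = 6,
                    population = "hybrids", parents_per_side = c(8, 8), seed = 81)
  fac <- simulate_factorial(cfg, n_crosses = 40)
  G1 <- grm_vanraden(fac$parents1); G2 <- grm_vanraden(fac$parents2)
  i1 <- match(fac$crosses$parent1, G1$samples)
  i2 <- match(fac$crosses$parent2, G2$samples)
  Ks <- G1$matrix[i1, i1] * G2$matrix[i2, i2]
  expect_gt(min(eigen(Ks, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  # entries factorise exactly as G1[i,k] * G2[j,l]
  expect_equal(Ks[1, 2],
               G1$matrix[i1[1], i1[2]] * G2$matrix[i2[1], i2[2]])
})

test_that("block-wise sums reproduce hand results and conserve the BLUPs", {
  # hand example: 2-marker block, a = (0.5, -0.25), centred variant (1, 1)
  me <- structure(list(a = c(m1 = 0.5, m2 = -0.25), centers = c(0, 0), c = 1,
                       train = "S1"), class = "marker_effects")
  bs <- haploencoder:::new_haploblock_set(
    list(list(chrom = "1", markers = 1:2, size = 2L)), integer(0), 2L)
  cat_b <- structure(list(variants = list(list(
    patterns = rbind(c(1, 1), c(-1, -1)), counts = c(1L, 1L),
    members = list(1L, 2L))), n_samples = 2, blocks = bs),
    class = "variant_catalogue")
  E <- blockwise_effect_sums(me, bs, cat_b)
  expect_equal(E$effect_sum[[1]], c(0.25, -0.25))
  # conservation: block sums at each sample's own variants + unassigned
  # contributions reconstruct the genotype BLUPs
  sim <- simulate_genotypes(sim_config(n_samples = 100, n_chromosomes = 2,
                                       blocks_per_chromosome = 5,
                                       inter_block_markers = 2, seed = 91))
  tr <- simulate_trait(sim$G, sim$true_blocks, h2 = 0.7, seed = 92)
  G <- grm_vanraden(sim$G)
  fit <- gblup(tr$y, G)
  me2 <- marker_effects(fit, sim$G)
  bs2 <- sim$true_blocks
  cat2 <- enumerate_variants(sim$G, bs2)
  E2 <- blockwise_effect_sums(me2, bs2, cat2)
  Zc <- sweep(sim$G$codes, 2, G$centers, "-")
  u_rebuilt <- rep(0, 100)
  for (b in seq_along(bs2$blocks)) {
    for (v in seq_along(cat2$variants[[b]]$counts)) {
      idx <- cat2$variants[[b]]$members[[v]]
      u_rebuilt[idx] <- u_rebuilt[idx] + E2$effect_sum[[b]][v]
    }
  }
  u_rebuilt <- u_rebuilt +
    drop(Zc[, bs2$unassigned, drop = FALSE] %*% me2$a[bs2$unassigned])
  expect_lt(max(abs(u_rebuilt - fit$u)), 1e-6)
})
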