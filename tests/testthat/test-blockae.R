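make_two_block_set <- function(sizes, total) {
  at <- 0L
  blocks <- lapply(sizes, function(s) {
    b <- list(chrom = "1", markers = at + seq_len(s), size = as.integer(s))
    at <<- at + s
    b
  })
  haploencoder:::new_haploblock_set(blocks, setdiff(seq_len(total), seq_len(at)),
                                    total)
}

test_that("architecture follows the block-size contract", {
  cfg <- block_ae_config(seed = 1)
  bs <- make_two_block_set(c(3, 5), 10)
  m <- build_block_ae(bs, 10, cfg)
  # block of 3: direct 3 -> 1; block of 5: 5 -> 2 -> 1
  expect_false(m$enc[[1]]$optional)
  expect_equal(dim(m$enc[[1]]$W), c(3, 1))
  expect_true(m$enc[[2]]$optional)
  expect_equal(dim(m$enc[[2]]$W1), c(5, 2))
  expect_equal(dim(m$enc[[2]]$W2), c(2, 1))
  # block layer width 2, decoder 2 -> 1000 -> 10
  expect_equal(dim(m$Wd1), c(2, 1000))
  expect_equal(dim(m$Wd2), c(1000, 10))
  # boundary cases for the optional layer
  m2 <- build_block_ae(make_two_block_set(c(2), 2), 2, cfg)
  expect_false(m2$enc[[1]]$optional)
  m4 <- build_block_ae(make_two_block_set(c(4), 4), 4, cfg)
  expect_true(m4$enc[[1]]$optional)
  expect_equal(ncol(m4$enc[[1]]$W1), 2)
})

test_that("loss functions match their closed forms", {
  expect_equal(ae_loss_unsupervised(matrix(1), matrix(1)), 0)
  expect_equal(ae_loss_unsupervised(matrix(1), matrix(0)), 1)
  expect_equal(ae_loss_unsupervised(matrix(c(1, -1), 1), matrix(c(0, 0), 1)), 1)
  expect_error(ae_loss_unsupervised(matrix(1), matrix(1, 2, 2)), "shape")
  y <- c(1, 2, 3)
  X <- matrix(c(1, -1, 0), 1)
  # perfect fit: 0 - 1 + 0 + lambda * ||w||^2
  expect_equal(ae_loss_semisupervised(X, X, y, y, w_z = c(0, 0), lambda = 0.001), -1)
  expect_equal(ae_loss_semisupervised(X, X, y, y, w_z = c(2, 0), lambda = 0.001),
               -1 + 0.004)
  # anti-correlated predictions: -(-1) + MSE >= 1
  expect_gte(ae_loss_semisupervised(X, X, y, -y + 4, w_z = 0, lambda = 0), 1)
  # constant predictions: correlation term set to 0
  expect_equal(ae_loss_semisupervised(X, X, y, c(2, 2, 2), w_z = 0, lambda = 0),
               0 + mean((y - 2)^2))
  expect_error(ae_loss_semisupervised(X, X, y, y, 0, -1), "lambda")
  expect_error(ae_loss_semisupervised(X, X, y[1:2], y[1:2], 0, 0), "at least 3")
})

test_that("training descends, is seed-deterministic, and 0 epochs is a no-op", {
  sim <- simulate_genotypes(sim_config(n_samples = 200, n_chromosomes = 1,
                                       blocks_per_chromosome = 5,
                                       n_variants_per_block = c(2, 2),
                                       seed = 13))
  cfg <- block_ae_config(epochs = 100, decoder_hidden = 100, seed = 2)
  m0 <- build_block_ae(sim$true_blocks, ncol(sim$G$codes),
                       block_ae_config(epochs = 0, decoder_hidden = 100, seed = 2))
  t0 <- train_block_ae(m0, sim$G)
  expect_identical(haploencoder:::flatten_params(t0),
                   haploencoder:::flatten_params(m0))
  fit <- block_autoencoder(sim$G, sim$true_blocks, cfg)
  expect_lt(fit$trace[length(fit$trace)], fit$trace[1])
  fit2 <- block_autoencoder(sim$G, sim$true_blocks, cfg)
  expect_identical(fit$trace, fit2$trace)
  expect_identical(extract_features(fit, sim$G), extract_features(fit2, sim$G))
})

test_that("cross-block weights are exactly zero before and after training", {
  sim <- simulate_genotypes(sim_config(n_samples = 80, n_chromosomes = 1,
                                       blocks_per_chromosome = 4, seed = 3))
  fit <- block_autoencoder(sim$G, sim$true_blocks,
                           block_ae_config(epochs = 20, decoder_hidden = 50,
                                           seed = 4))
  W <- encoder_weight_matrices(fit)
  expect_equal(max(abs(W$stage1[!W$mask1])), 0)
  expect_equal(max(abs(W$stage2[!W$mask2])), 0)
})

test_that("block-layer features are block-local and reconstructions stay in (-1, 1)", {
  sim <- simulate_genotypes(sim_config(n_samples = 60, n_chromosomes = 1,
                                       blocks_per_chromosome = 3,
                                       inter_block_markers = 2, seed = 8))
  fit <- block_autoencoder(sim$G, sim$true_blocks,
                           block_ae_config(epochs = 30, decoder_hidden = 50,
                                           seed = 5))
  F1 <- extract_features(fit, sim$G)
  expect_equal(dim(F1), c(60, 3))
  # perturb everything except block 1's markers: column 1 must not move
  X2 <- sim$G$codes
  out1 <- setdiff(seq_len(ncol(X2)), sim$true_blocks$blocks[[1]]$markers)
  X2[, out1] <- X2[sample(nrow(X2)), out1]
  F2 <- predict(fit, X2, type = "features")
  expect_identical(unname(F1[, 1]), unname(F2[, 1]))
  # identical codes in a block give identical features
  i_dup <- which(duplicated(sim$G$codes[, sim$true_blocks$blocks[[2]]$markers]))[1]
  if (!is.na(i_dup)) {
    key <- apply(sim$G$codes[, sim$true_blocks$blocks[[2]]$markers], 1, paste,
                 collapse = ",")
    twin <- which(key == key[i_dup])[1]
    expect_equal(F1[i_dup, 2], F1[twin, 2])
  }
  R <- predict(fit, sim$G, type = "reconstruction")
  expect_true(all(R > -1 & R < 1))
  expect_error(predict(fit, sim$G$codes[, 1:5], type = "features"),
               "marker count mismatch")
})

test_that("semi-supervised training learns the trait and the ridge shrinks w_Z", {
  sim <- simulate_genotypes(sim_config(n_samples = 150, n_chromosomes = 2,
                                       blocks_per_chromosome = 8,
                                       n_variants_per_block = c(2, 2),
                                       inter_block_markers = 0, seed = 17))
  tr <- simulate_trait(sim$G, sim$true_blocks, h2 = 0.8, seed = 18)
  bs <- build_blocks(sim$G)
  cfg0 <- block_ae_config(epochs = 100, decoder_hidden = 500, seed = 6,
                          lambda_ridge = 0)
  train_ids <- sim$G$samples[1:120]
  fit0 <- block_autoencoder(sim$G, bs, cfg0, y = tr$y, train_ids = train_ids)
  yh <- predict_yield(fit0, sim$G)
  expect_gt(cor(tr$y[train_ids], yh[train_ids]), 0.5)
  # enormous ridge shrinks the yield-head norm relative to no ridge
  cfgL <- cfg0; cfgL$lambda_ridge <- 1e6
  fitL <- block_autoencoder(sim$G, bs, cfgL, y = tr$y, train_ids = train_ids)
  expect_lt(sqrt(sum(fitL$wz^2)), sqrt(sum(fit0$wz^2)))
  expect_error(block_autoencoder(sim$G, bs, cfg0, y = tr$y,
                                 train_ids = train_ids[1:2]), "at least 3")
})

test_that("the yield head is a linear, intercept-free map of the block layer", {
  sim <- simulate_genotypes(sim_config(n_samples = 40, n_chromosomes = 1,
                                       blocks_per_chromosome = 2,
                                       n_variants_per_block = c(2, 2), seed = 9))
  tr <- simulate_trait(sim$G, sim$true_blocks, h2 = 1, seed = 10)
  fit <- block_autoencoder(sim$G, sim$true_blocks,
                           block_ae_config(epochs = 5, decoder_hidden = 20, seed = 7),
                           y = tr$y)
  B <- extract_features(fit, sim$G)
  expect_equal(unname(predict_yield(fit, sim$G)), unname(drop(B %*% fit$wz)),
               tolerance = 1e-12)
  fit2 <- fit; fit2$wz <- 2 * fit$wz
  expect_equal(predict_yield(fit2, sim$G), 2 * predict_yield(fit, sim$G),
               tolerance = 1e-12)
  fit3 <- fit; fit3$wz <- fit$wz * 0
  expect_true(all(predict_yield(fit3, sim$G) == 0))
  un <- block_autoencoder(sim$G, sim$true_blocks,
                          block_ae_config(epochs = 1, decoder_hidden = 20, seed = 7))
  expect_error(predict_yield(un, sim$G), "yield head")
})

test_that("the second reduction halves duplicated features and degrades gracefully", {
  set.seed(12)
  base <- matrix(rnorm(50 * 4), 50, 4)
  F1 <- base[, rep(1:4, each = 2)]          # adjacent duplicate pairs
  colnames(F1) <- paste0("B", 1:8)
  red <- reduce_second_step(F1, block_ae_config(epochs = 10, decoder_hidden = 20,
                                                seed = 3))
  expect_true(red$reduced)
  expect_equal(ncol(red$features), 4)
  # mutually uncorrelated features cannot be reduced
  F2 <- matrix(rnorm(50 * 4), 50, 4)
  expect_warning(red2 <- reduce_second_step(F2, block_ae_config(epochs = 5,
                                                                decoder_hidden = 10,
                                                                seed = 3)),
                 "no meta-block")
  expect_false(red2$reduced)
  expect_equal(red2$features, F2, ignore_attr = TRUE)
})
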