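#' Hyperparameters of the block-masked autoencoder
#'
#' @param epochs full-batch Adam steps (default 100).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param leaky_slope negative slope of the leaky ReLU (default 0.1).
#' @param decoder_hidden units in the decoder hidden layer (default 1000).
#' @param optional_layer_min_block blocks with at least this many markers get
#'   an extra floor(n/2)-unit encoder layer (default 4).
#' @param lambda_ridge ridge penalty on the yield-head weights in the
#'   semi-supervised loss (default 0.001).
#' @param seed integer seed for weight initialisation (required for
#'   reproducibility).
#' @param batch "full" (default; the correlation term of the semi-supervised
#'   loss is then well defined at every step) or a sample count for
#'   minibatch training.
#' @param block_activation "linear" (default: block-layer features and the
#'   yield head see unsquashed values) or "leaky".
#' @param center_y centre phenotypes before semi-supervised training
#'   (default FALSE; the yield head has no intercept).
#' @return a \code{block_ae_config} list.
#' @export
block_ae_config <- function(epochs = 100, learning_rate = 0.001,
                            leaky_slope = 0.1, decoder_hidden = 1000,
                            optional_layer_min_block = 4,
                            lambda_ridge = 0.001, seed = 1L, batch = "full",
                            block_activation = c("linear", "leaky"),
                            center_y = FALSE) {
  block_activation <- match.arg(block_activation)
  stopifnot(epochs >= 0, learning_rate > 0, decoder_hidden >= 1,
            lambda_ridge >= 0, optional_layer_min_block >= 2)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 leaky_slope = leaky_slope,
                 decoder_hidden = as.integer(decoder_hidden),
                 optional_layer_min_block = as.integer(optional_layer_min_block),
                 lambda_ridge = lambda_ridge, seed = as.integer(seed),
                 batch = batch, block_activation = block_activation,
                 center_y = isTRUE(center_y)),
            class = "block_ae_config")
}

# PyTorch-Linear-style init: U(-1/sqrt(fan_in), 1/sqrt(fan_in))
.init_mat <- function(nr, nc, fan_in) {
  matrix(stats::runif(nr * nc, -1, 1) / sqrt(fan_in), nr, nc)
}

leaky_relu <- function(x, slope) ifelse(x > 0, x, slope * x)
leaky_relu_grad <- function(x, slope) ifelse(x > 0, 1, slope)

#' Build an untrained block-masked autoencoder
#'
#' Architecture per block of size n: a direct n -> 1 encoder stage, or, for
#' n >= \code{optional_layer_min_block}, an n -> floor(n/2) stage followed by
#' leaky ReLU and a floor(n/2) -> 1 stage. The block layer (one unit per
#' block, linear by default) is densely connected to a
#' \code{decoder_hidden}-unit layer (leaky ReLU) and on to a tanh
#' reconstruction layer covering all \code{total_markers} markers, including
#' those without block assignment. Encoder connectivity never crosses block
#' borders; the per-block weight groups realise an exactly masked network.
#' An optional yield head is a single linear unit on the block layer with no
#' intercept.
#'
#' @param blocks a \code{haploblock_set}; block marker indices refer to
#'   columns of the genotype matrix the model will be trained on.
#' @param total_markers width of the reconstruction layer.
#' @param cfg a \code{block_ae_config}.
#' @param yield_head add the supervised yield unit.
#' @return an untrained object of class \code{block_ae}.
#' @export
build_block_ae <- function(blocks, total_markers, cfg = block_ae_config(),
                           yield_head = FALSE) {
  stopifnot(inherits(blocks, "haploblock_set"))
  if (length(blocks$blocks) == 0) stop("block set is empty")
  sizes <- block_sizes(blocks)
  if (any(sizes < 2)) stop("block with fewer than 2 markers")
  k <- length(blocks$blocks)
  set.seed(cfg$seed)
  enc <- lapply(blocks$blocks, function(b) {
    n <- b$size
    if (n >= cfg$optional_layer_min_block) {
      h <- n %/% 2
      list(W1 = .init_mat(n, h, n), b1 = drop(.init_mat(1, h, n)),
           W2 = .init_mat(h, 1, h), b2 = drop(.init_mat(1, 1, h)),
           optional = TRUE)
    } else {
      list(W = .init_mat(n, 1, n), b = drop(.init_mat(1, 1, n)),
           optional = FALSE)
    }
  })
  H <- cfg$decoder_hidden
  model <- structure(list(
    blocks = blocks, k = k, m_out = as.integer(total_markers), cfg = cfg,
    enc = enc,
    Wd1 = .init_mat(k, H, k), bd1 = drop(.init_mat(1, H, k)),
    Wd2 = .init_mat(H, total_markers, H), bd2 = drop(.init_mat(1, total_markers, H)),
    wz = if (yield_head) drop(.init_mat(k, 1, k)) else NULL,
    trained = FALSE, trace = NULL),
    class = "block_ae")
  model
}

#' @export
print.block_ae <- function(x, ...) {
  sizes <- block_sizes(x$blocks)
  cat("block_ae: ", x$k, " blocks (sizes ", min(sizes), "-", max(sizes),
      "), input ", sum(sizes), " markers, reconstruction ", x$m_out,
      " markers\n  decoder hidden: ", x$cfg$decoder_hidden,
      "; yield head: ", if (is.null(x$wz)) "no" else "yes",
      "; trained: ", if (isTRUE(x$trained)) "yes" else "no", "\n", sep = "")
  if (!is.null(x$trace))
    cat("  loss: ", signif(x$trace[1], 5), " -> ",
        signif(x$trace[length(x$trace)], 5), " over ",
        length(x$trace), " epochs\n", sep = "")
  invisible(x)
}

#' @export
summary.block_ae <- function(object, ...) {
  print(object)
  sizes <- block_sizes(object$blocks)
  cat("  optional encoder layer on ",
      sum(sizes >= object$cfg$optional_layer_min_block), " of ", object$k,
      " blocks\n  parameters: ", length(unlist(flatten_params(object))),
      "\n", sep = "")
  invisible(object)
}

# forward pass; returns cached intermediates for backprop
ae_forward <- function(model, X) {
  cfg <- model$cfg
  n <- nrow(X)
  B <- matrix(0, n, model$k)
  cache <- vector("list", model$k)
  for (b in seq_len(model$k)) {
    mk <- model$blocks$blocks[[b]]$markers
    Xb <- X[, mk, drop = FALSE]
    e <- model$enc[[b]]
    if (e$optional) {
      preA <- sweep(Xb %*% e$W1, 2, e$b1, "+")
      A <- leaky_relu(preA, cfg$leaky_slope)
      z <- drop(A %*% e$W2) + e$b2
      cache[[b]] <- list(Xb = Xb, preA = preA, A = A)
    } else {
      z <- drop(Xb %*% e$W) + e$b
      cache[[b]] <- list(Xb = Xb)
    }
    B[, b] <- z
  }
  Bact <- if (cfg$block_activation == "leaky") leaky_relu(B, cfg$leaky_slope) else B
  preH <- sweep(Bact %*% model$Wd1, 2, model$bd1, "+")
  Hm <- leaky_relu(preH, cfg$leaky_slope)
  preO <- sweep(Hm %*% model$Wd2, 2, model$bd2, "+")
  O <- tanh(preO)
  yhat <- if (!is.null(model$wz)) drop(Bact %*% model$wz) else NULL
  list(B = B, Bact = Bact, preH = preH, H = Hm, O = O, yhat = yhat,
       cache = cache)
}

#' Mean squared reconstruction error
#'
#' The unsupervised autoencoder loss: mean of squared differences over all
#' entries of the code matrix and its reconstruction.
#'
#' @param X code matrix.
#' @param Xhat reconstruction of the same shape.
#' @return scalar MSE.
#' @export
ae_loss_unsupervised <- function(X, Xhat) {
  if (!identical(dim(as.matrix(X)), dim(as.matrix(Xhat))))
    stop("shape mismatch between X and Xhat")
  mean((X - Xhat)^2)
}

#' Semi-supervised autoencoder loss
#'
#' MSE(X, Xhat) - cor(y, yhat) + MSE(y, yhat) + lambda * ||w_z||^2.
#' The correlation term is set to 0 when yhat is constant. At a perfect fit
#' (Xhat = X, yhat = y) the loss equals -1 + lambda * ||w_z||^2.
#'
#' @param X,Xhat code matrix and reconstruction (all samples).
#' @param y,yhat observed and predicted phenotypes (training samples only).
#' @param w_z yield-head weight vector.
#' @param lambda ridge parameter (>= 0).
#' @return scalar loss.
#' @export
ae_loss_semisupervised <- function(X, Xhat, y, yhat, w_z, lambda) {
  if (lambda < 0) stop("lambda must be >= 0")
  if (length(y) < 3) stop("need at least 3 labelled samples")
  cr <- if (stats::sd(yhat) > 0 && stats::sd(y) > 0) stats::cor(y, yhat) else 0
  ae_loss_unsupervised(X, Xhat) - cr + mean((y - yhat)^2) +
    lambda * sum(w_z^2)
}

flatten_params <- function(model) {
  p <- list()
  for (b in seq_len(model$k)) {
    e <- model$enc[[b]]
    if (e$optional) {
      p[[paste0("enc", b, ".W1")]] <- e$W1
      p[[paste0("enc", b, ".b1")]] <- e$b1
      p[[paste0("enc", b, ".W2")]] <- e$W2
      p[[paste0("enc", b, ".b2")]] <- e$b2
    } else {
      p[[paste0("enc", b, ".W")]] <- e$W
      p[[paste0("enc", b, ".b")]] <- e$b
    }
  }
  p$Wd1 <- model$Wd1; p$bd1 <- model$bd1
  p$Wd2 <- model$Wd2; p$bd2 <- model$bd2
  if (!is.null(model$wz)) p$wz <- model$wz
  p
}

unflatten_params <- function(model, p) {
  for (b in seq_len(model$k)) {
    e <- model$enc[[b]]
    if (e$optional) {
      model$enc[[b]]$W1 <- p[[paste0("enc", b, ".W1")]]
      model$enc[[b]]$b1 <- p[[paste0("enc", b, ".b1")]]
      model$enc[[b]]$W2 <- p[[paste0("enc", b, ".W2")]]
      model$enc[[b]]$b2 <- p[[paste0("enc", b, ".b2")]]
    } else {
      model$enc[[b]]$W <- p[[paste0("enc", b, ".W")]]
      model$enc[[b]]$b <- p[[paste0("enc", b, ".b")]]
    }
  }
  model$Wd1 <- p$Wd1; model$bd1 <- p$bd1
  model$Wd2 <- p$Wd2; model$bd2 <- p$bd2
  if (!is.null(model$wz)) model$wz <- p$wz
  model
}

# gradients of the (semi-)supervised loss w.r.t. all parameters.
# X: input codes (all samples), Xt: reconstruction target, train_rows: index
# of labelled rows (NULL for unsupervised), y: labels on train_rows.
ae_backward <- function(model, X, Xt, fw, train_rows = NULL, y = NULL) {
  cfg <- model$cfg
  n <- nrow(X); m <- ncol(Xt)
  g <- list()
  dO <- 2 * (fw$O - Xt) / (n * m)
  dpreO <- dO * (1 - fw$O^2)
  g$Wd2 <- crossprod(fw$H, dpreO)
  g$bd2 <- colSums(dpreO)
  dH <- tcrossprod(dpreO, model$Wd2)
  dpreH <- dH * leaky_relu_grad(fw$preH, cfg$leaky_slope)
  g$Wd1 <- crossprod(fw$Bact, dpreH)
  g$bd1 <- colSums(dpreH)
  dBact <- tcrossprod(dpreH, model$Wd1)
  if (!is.null(train_rows)) {
    yhat_t <- fw$yhat[train_rows]
    t_n <- length(train_rows)
    # MSE(y, yhat) term
    dyhat <- 2 * (yhat_t - y) / t_n
    # -cor(y, yhat) term (0 gradient when yhat is constant)
    u <- y - mean(y); v <- yhat_t - mean(yhat_t)
    su <- sqrt(sum(u^2)); sv <- sqrt(sum(v^2))
    if (su > 0 && sv > 1e-12) {
      r <- sum(u * v) / (su * sv)
      dyhat <- dyhat - (u / (su * sv) - r * v / sv^2)
    }
    dB_yield <- matrix(0, n, model$k)
    dB_yield[train_rows, ] <- outer(dyhat, model$wz)
    dBact <- dBact + dB_yield
    g$wz <- drop(crossprod(fw$Bact[train_rows, , drop = FALSE], dyhat)) +
      2 * cfg$lambda_ridge * model$wz
  }
  dB <- if (cfg$block_activation == "leaky")
    dBact * leaky_relu_grad(fw$B, cfg$leaky_slope) else dBact
  for (b in seq_len(model$k)) {
    e <- model$enc[[b]]
    cb <- fw$cache[[b]]
    dz <- dB[, b]
    if (e$optional) {
      g[[paste0("enc", b, ".W2")]] <- crossprod(cb$A, dz)
      g[[paste0("enc", b, ".b2")]] <- sum(dz)
      dA <- tcrossprod(dz, drop(e$W2)) *
        leaky_relu_grad(cb$preA, cfg$leaky_slope)
      g[[paste0("enc", b, ".W1")]] <- crossprod(cb$Xb, dA)
      g[[paste0("enc", b, ".b1")]] <- colSums(dA)
    } else {
      g[[paste0("enc", b, ".W")]] <- crossprod(cb$Xb, dz)
      g[[paste0("enc", b, ".b")]] <- sum(dz)
    }
  }
  g
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    gr <- grads[[nm]]
    if (is.null(gr)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train a block-masked autoencoder
#'
#' Full-batch Adam on the reconstruction loss, or, when phenotypes are
#' given, on the semi-supervised loss in which reconstruction uses all
#' samples while the yield terms use only the labelled training samples.
#' Training is deterministic given the configuration seed in full-batch
#' mode.
#'
#' @param model an untrained (or previously trained) \code{block_ae}.
#' @param G a complete \code{genotype_matrix} whose columns align with the
#'   model's block set, or a bare numeric matrix.
#' @param y named phenotype vector (semi-supervised mode; requires a yield
#'   head).
#' @param train_ids samples whose phenotypes drive the supervised terms
#'   (default: all names of y).
#' @return the trained \code{block_ae}; element \code{trace} holds the
#'   per-epoch loss.
#' @export
train_block_ae <- function(model, G, y = NULL, train_ids = NULL) {
  stopifnot(inherits(model, "block_ae"))
  X <- if (inherits(G, "genotype_matrix")) G$codes else as.matrix(G)
  if (ncol(X) != model$m_out)
    stop("marker count mismatch: model reconstructs ", model$m_out,
         " markers, data has ", ncol(X))
  if (anyNA(X)) stop("missing values; impute first")
  cfg <- model$cfg
  semi <- !is.null(y)
  train_rows <- NULL
  if (semi) {
    if (is.null(model$wz)) stop("semi-supervised training needs a yield head")
    if (is.null(train_ids)) train_ids <- names(y)
    if (length(train_ids) < 3)
      stop("need at least 3 labelled training samples (correlation undefined)")
    train_rows <- match(train_ids, rownames(X))
    if (anyNA(train_rows)) stop("train id(s) not in the data")
    y <- y[train_ids]
    if (cfg$center_y) y <- y - mean(y)
  }
  params <- flatten_params(model)
  state <- adam_init(params)
  trace <- numeric(cfg$epochs)
  full_batch <- identical(cfg$batch, "full")
  if (!full_batch) set.seed(cfg$seed + 1L)
  n <- nrow(X)
  for (ep in seq_len(cfg$epochs)) {
    model <- unflatten_params(model, params)
    if (full_batch) {
      fw <- ae_forward(model, X)
      loss <- if (semi)
        ae_loss_semisupervised(X, fw$O, y, fw$yhat[train_rows], model$wz,
                               cfg$lambda_ridge)
      else ae_loss_unsupervised(X, fw$O)
      if (!is.finite(loss))
        stop("non-finite loss at epoch ", ep, " (", signif(loss, 4), ")")
      g <- ae_backward(model, X, X, fw, train_rows, y)
      up <- adam_step(params, g, state, cfg$learning_rate)
      params <- up$params; state <- up$state
      trace[ep] <- loss
    } else {
      idx <- sample.int(n)
      bs <- as.integer(cfg$batch)
      losses <- c()
      for (start in seq(1, n, by = bs)) {
        rows <- idx[start:min(start + bs - 1, n)]
        tr_b <- intersect(rows, train_rows)
        model <- unflatten_params(model, params)
        fw <- ae_forward(model, X[rows, , drop = FALSE])
        tr_loc <- match(tr_b, rows)
        y_b <- if (semi) y[match(tr_b, train_rows)] else NULL
        loss <- if (semi && length(tr_b) >= 3)
          ae_loss_semisupervised(X[rows, , drop = FALSE], fw$O, y_b,
                                 fw$yhat[tr_loc], model$wz, cfg$lambda_ridge)
        else ae_loss_unsupervised(X[rows, , drop = FALSE], fw$O)
        g <- ae_backward(model, X[rows, , drop = FALSE],
                         X[rows, , drop = FALSE], fw,
                         if (semi && length(tr_b) >= 3) tr_loc else NULL, y_b)
        up <- adam_step(params, g, state, cfg$learning_rate)
        params <- up$params; state <- up$state
        losses <- c(losses, loss)
      }
      trace[ep] <- mean(losses)
    }
  }
  model <- unflatten_params(model, params)
  model$trained <- cfg$epochs > 0 || isTRUE(model$trained)
  model$trace <- if (is.null(model$trace)) trace else c(model$trace, trace)
  model$sample_names <- rownames(X)
  model
}

#' Fit a block-masked autoencoder to genotype data
#'
#' The main fitting entry point: builds the architecture from the block set
#' and trains it. Without phenotypes this is the unsupervised model used for
#' dimensionality reduction; with phenotypes a yield head is added and the
#' semi-supervised loss is optimised (reconstruction on all samples, yield
#' terms on the labelled training samples only).
#'
#' @param G a complete \code{genotype_matrix}.
#' @param blocks a \code{haploblock_set} over the columns of \code{G} (built
#'   with \code{\link{build_blocks}} if omitted).
#' @param config a \code{block_ae_config}.
#' @param y optional named phenotype vector; triggers semi-supervised mode.
#' @param train_ids labelled samples (default: all names of \code{y}).
#' @return a trained \code{block_ae}.
#' @examples
#' sim <- simulate_genotypes(sim_config(n_samples = 60, n_chromosomes = 1,
#'                                      blocks_per_chromosome = 3, seed = 7))
#' fit <- block_autoencoder(sim$G, sim$true_blocks,
#'                          block_ae_config(epochs = 5, seed = 7))
#' dim(extract_features(fit, sim$G))
#' @export
block_autoencoder <- function(G, blocks = NULL, config = block_ae_config(),
                              y = NULL, train_ids = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (is.null(blocks)) blocks <- build_blocks(G)
  model <- build_block_ae(blocks, ncol(G$codes), config,
                          yield_head = !is.null(y))
  train_block_ae(model, G, y = y, train_ids = train_ids)
}

#' Extract block-layer features (AE1)
#'
#' Forward pass up to and including the block layer: one feature column per
#' block, rows aligned with the samples of \code{G}.
#'
#' @param model a trained \code{block_ae}.
#' @param G a complete \code{genotype_matrix} (or bare matrix) with the same
#'   marker columns the model was trained on.
#' @return numeric matrix (samples x blocks) with attributes
#'   \code{provenance} ("AE1") and \code{source_blocks} (block indices), and
#'   per-block chromosome labels in attribute \code{chrom}.
#' @export
extract_features <- function(model, G) {
  stopifnot(inherits(model, "block_ae"))
  X <- if (inherits(G, "genotype_matrix")) G$codes else as.matrix(G)
  if (ncol(X) != model$m_out)
    stop("marker count mismatch: model expects ", model$m_out, " markers")
  fw <- ae_forward(model, X)
  F_mat <- fw$Bact
  dimnames(F_mat) <- list(rownames(X), paste0("B", seq_len(model$k)))
  attr(F_mat, "provenance") <- "AE1"
  attr(F_mat, "source_blocks") <- seq_len(model$k)
  attr(F_mat, "chrom") <- vapply(model$blocks$blocks, `[[`, character(1), "chrom")
  F_mat
}

#' Predict from a block autoencoder
#'
#' @param object a trained \code{block_ae}.
#' @param newdata a complete \code{genotype_matrix} or code matrix.
#' @param type "features" (block layer), "reconstruction" (tanh output), or
#'   "yield" (linear yield head, semi-supervised models only).
#' @param ... unused.
#' @return matrix of features or reconstructions, or a named vector of yield
#'   predictions.
#' @export
predict.block_ae <- function(object, newdata,
                             type = c("features", "reconstruction", "yield"),
                             ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "genotype_matrix")) newdata$codes else as.matrix(newdata)
  if (ncol(X) != object$m_out)
    stop("marker count mismatch: model expects ", object$m_out, " markers")
  if (type == "yield" && is.null(object$wz))
    stop("model has no yield head (unsupervised-only model)")
  fw <- ae_forward(object, X)
  switch(type,
         features = {
           Fm <- fw$Bact
           dimnames(Fm) <- list(rownames(X), paste0("B", seq_len(object$k)))
           Fm
         },
         reconstruction = {
           O <- fw$O
           rownames(O) <- rownames(X)
           O
         },
         yield = stats::setNames(fw$yhat, rownames(X)))
}

#' Predict yield through the supervised head
#'
#' Linear, intercept-free combination of the block-layer outputs with the
#' yield-head weights.
#'
#' @param model a semi-supervised \code{block_ae}.
#' @param G a complete \code{genotype_matrix} or code matrix.
#' @return named vector of predictions.
#' @export
predict_yield <- function(model, G) predict(model, G, type = "yield")

#' Second dimensionality-reduction step (AE2)
#'
#' Groups AE1 features whose adjacent absolute correlation exceeds 0.7 into
#' meta-blocks and trains a fresh autoencoder of the same architecture on
#' them (reconstruction target: all AE1 features). When no meta-block of
#' size >= 2 exists, no reduction is possible and the AE1 features are
#' returned unchanged with \code{reduced = FALSE}.
#'
#' @param F_ae1 AE1 feature matrix from \code{\link{extract_features}}.
#' @param config a \code{block_ae_config} for the second autoencoder.
#' @param threshold meta-block correlation threshold (default 0.7, strict).
#' @return list with \code{features} (AE2 matrix, provenance attribute
#'   "AE2"), \code{meta_blocks}, \code{model} (NULL when not reduced) and
#'   \code{reduced}.
#' @export
reduce_second_step <- function(F_ae1, config = block_ae_config(),
                               threshold = 0.7) {
  F_ae1 <- as.matrix(F_ae1)
  chrom <- attr(F_ae1, "chrom")
  mb <- build_meta_blocks(F_ae1, threshold = threshold, chrom = chrom)
  if (length(mb$blocks) == 0) {
    warning("no meta-block of size >= 2; returning AE1 features unreduced")
    out <- F_ae1
    attr(out, "provenance") <- "AE1"
    return(list(features = out, meta_blocks = mb, model = NULL,
                reduced = FALSE))
  }
  model <- build_block_ae(mb, ncol(F_ae1), config, yield_head = FALSE)
  model <- train_block_ae(model, F_ae1)
  Fm <- predict(model, F_ae1, type = "features")
  colnames(Fm) <- paste0("MB", seq_len(ncol(Fm)))
  attr(Fm, "provenance") <- "AE2"
  attr(Fm, "source_blocks") <- lapply(mb$blocks, `[[`, "markers")
  list(features = Fm, meta_blocks = mb, model = model, reduced = TRUE)
}

#' Materialise the masked encoder weight matrices
#'
#' Returns the two encoder stages as full dense matrices in which every
#' cross-block weight is exactly zero, for mask-conservation checks. Stage 1
#' maps model inputs to the per-block hidden units (blocks without the
#' optional layer pass via stage 2 only); stage 2 maps hidden units (or
#' inputs directly) to the block layer.
#'
#' @param model a \code{block_ae}.
#' @return list with \code{stage1} ((input markers) x (hidden units)) and
#'   \code{stage2} ((hidden units or direct inputs) x k) matrices plus the
#'   logical masks \code{mask1}, \code{mask2}.
#' @export
encoder_weight_matrices <- function(model) {
  stopifnot(inherits(model, "block_ae"))
  in_idx <- unlist(lapply(model$blocks$blocks, `[[`, "markers"))
  m_in <- length(in_idx)
  col_of <- stats::setNames(seq_len(m_in), in_idx)
  h_tot <- sum(vapply(model$enc, function(e)
    if (e$optional) ncol(e$W1) else 1L, integer(1)))
  W1 <- matrix(0, m_in, h_tot); M1 <- matrix(FALSE, m_in, h_tot)
  W2 <- matrix(0, h_tot, model$k); M2 <- matrix(FALSE, h_tot, model$k)
  at <- 0L
  for (b in seq_len(model$k)) {
    rows <- col_of[as.character(model$blocks$blocks[[b]]$markers)]
    e <- model$enc[[b]]
    if (e$optional) {
      h <- ncol(e$W1)
      W1[rows, at + seq_len(h)] <- e$W1
      M1[rows, at + seq_len(h)] <- TRUE
      W2[at + seq_len(h), b] <- e$W2
      M2[at + seq_len(h), b] <- TRUE
      at <- at + h
    } else {
      W1[rows, at + 1L] <- e$W      # identity-style passthrough slot
      M1[rows, at + 1L] <- TRUE
      W2[at + 1L, b] <- 1
      M2[at + 1L, b] <- TRUE
      at <- at + 1L
    }
  }
  list(stage1 = W1, stage2 = W2, mask1 = M1, mask2 = M2)
}
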