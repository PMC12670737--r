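#' Enumerate observed block variants
#'
#' For every block, the distinct marker-code combinations (variants)
#' observed across samples, with counts and sample membership.
#'
#' @param G a complete \code{genotype_matrix}.
#' @param blocks a \code{haploblock_set} over the columns of \code{G}.
#' @return a \code{variant_catalogue}: element \code{variants} holds, per
#'   block, \code{patterns} (variants x block size matrix of -1/0/1 codes),
#'   \code{counts}, and \code{members} (list of sample-index vectors).
#' @export
enumerate_variants <- function(G, blocks) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(blocks, "haploblock_set"))
  if (anyNA(G$codes)) stop("missing values; impute first")
  variants <- lapply(blocks$blocks, function(b) {
    Xb <- G$codes[, b$markers, drop = FALSE]
    key <- apply(Xb, 1, paste, collapse = ",")
    first <- !duplicated(key)
    patterns <- Xb[first, , drop = FALSE]
    rownames(patterns) <- NULL
    members <- split(seq_len(nrow(Xb)), factor(key, levels = key[first]))
    list(patterns = patterns,
         counts = as.integer(lengths(members)),
         members = unname(members))
  })
  structure(list(variants = variants, n_samples = nrow(G$codes),
                 blocks = blocks),
            class = "variant_catalogue")
}

#' @export
print.variant_catalogue <- function(x, ...) {
  nv <- vapply(x$variants, function(v) nrow(v$patterns), integer(1))
  cat("variant_catalogue: ", length(nv), " blocks; variants per block: min ",
      min(nv), ", median ", stats::median(nv), ", max ", max(nv), "\n", sep = "")
  invisible(x)
}

new_block_variant_effects <- function(blocks, variants, effect_ae = NULL,
                                      effect_sum = NULL) {
  structure(list(blocks = blocks, variants = variants,
                 effect_ae = effect_ae, effect_sum = effect_sum),
            class = "block_variant_effects")
}

#' @export
print.block_variant_effects <- function(x, ...) {
  cat("block_variant_effects: ", length(x$variants), " blocks; methods: ",
      paste(c(if (!is.null(x$effect_ae)) "ae",
              if (!is.null(x$effect_sum)) "sum"), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Autoencoder-based block variant effects
#'
#' The contribution of a block variant to the trait: the block-layer output
#' of the variant's block unit, evaluated on the variant's raw -1/0/1 codes,
#' times the yield-head weight of that block. By block-locality the effect
#' depends only on the variant's own codes, so effects exist for variants
#' never seen in training.
#'
#' @param model a semi-supervised \code{block_ae} (with yield head).
#' @param catalogue a \code{variant_catalogue} aligned with the model's
#'   blocks.
#' @param effects optional existing \code{block_variant_effects} (e.g. from
#'   \code{\link{blockwise_effect_sums}}) to augment.
#' @return a \code{block_variant_effects} with method "ae" filled in.
#' @export
ae_variant_effects <- function(model, catalogue, effects = NULL) {
  stopifnot(inherits(model, "block_ae"), inherits(catalogue, "variant_catalogue"))
  if (is.null(model$wz)) stop("model has no yield head; train semi-supervised")
  if (length(catalogue$variants) != model$k)
    stop("catalogue has ", length(catalogue$variants), " blocks, model has ",
         model$k)
  cfg <- model$cfg
  eff <- lapply(seq_len(model$k), function(b) {
    pat <- catalogue$variants[[b]]$patterns
    e <- model$enc[[b]]
    if (e$optional) {
      A <- leaky_relu(sweep(pat %*% e$W1, 2, e$b1, "+"), cfg$leaky_slope)
      z <- drop(A %*% e$W2) + e$b2
    } else {
      z <- drop(pat %*% e$W) + e$b
    }
    if (cfg$block_activation == "leaky") z <- leaky_relu(z, cfg$leaky_slope)
    z * model$wz[b]
  })
  if (is.null(effects))
    new_block_variant_effects(catalogue$blocks, catalogue$variants,
                              effect_ae = eff)
  else {
    stopifnot(inherits(effects, "block_variant_effects"))
    effects$effect_ae <- eff
    effects
  }
}

#' Compare the two block-effect estimation methods
#'
#' For every block with at least \code{min_variants} distinct variants and
#' non-constant effects under both methods, the Pearson correlation across
#' variants between autoencoder-based effects and summed marker effects.
#' Blocks failing the requirement are flagged undefined (NA), never dropped
#' silently.
#'
#' @param E a \code{block_variant_effects} with both methods present.
#' @param min_variants minimum distinct variants for a defined correlation
#'   (default 3; a 2-point Pearson correlation is always +-1).
#' @return a data.frame (block, n_variants, correlation, defined) with the
#'   pooled summary (median of defined correlations, histogram counts over
#'   bins of width 0.2) in attribute \code{summary}.
#' @export
compare_effect_methods <- function(E, min_variants = 3) {
  stopifnot(inherits(E, "block_variant_effects"))
  if (is.null(E$effect_ae) || is.null(E$effect_sum))
    stop("both methods (ae, sum) must be present")
  nb <- length(E$variants)
  res <- data.frame(block = seq_len(nb),
                    n_variants = vapply(E$variants, function(v)
                      nrow(v$patterns), integer(1)),
                    correlation = NA_real_, defined = FALSE)
  for (b in seq_len(nb)) {
    ga <- E$effect_ae[[b]]; gs <- E$effect_sum[[b]]
    if (res$n_variants[b] >= min_variants &&
        stats::sd(ga) > 0 && stats::sd(gs) > 0) {
      res$correlation[b] <- stats::cor(ga, gs)
      res$defined[b] <- TRUE
    }
  }
  def <- res$correlation[res$defined]
  breaks <- seq(-1, 1, by = 0.2)
  attr(res, "summary") <- list(
    median = if (length(def) > 0) stats::median(def) else NA_real_,
    n_defined = length(def), n_blocks = nb,
    histogram = if (length(def) > 0)
      graphics::hist(def, breaks = breaks, plot = FALSE)$counts
    else rep(0L, length(breaks) - 1))
  res
}

#' Scale block variant effects to [-1, 1]
#'
#' Per method, every effect is divided by the method's largest absolute
#' effect, so signs are preserved, values lie in [-1, 1], and at least one
#' effect has magnitude 1. Idempotent.
#'
#' @param E a \code{block_variant_effects}.
#' @return the scaled \code{block_variant_effects}.
#' @export
scale_effects <- function(E) {
  stopifnot(inherits(E, "block_variant_effects"))
  scale1 <- function(effs, label) {
    if (is.null(effs)) return(NULL)
    mx <- max(abs(unlist(effs)))
    if (mx == 0) stop("all ", label, " effects are zero; cannot scale")
    lapply(effs, function(v) v / mx)
  }
  E$effect_ae <- scale1(E$effect_ae, "ae")
  E$effect_sum <- scale1(E$effect_sum, "sum")
  E
}

#' Flatten block variant effects into a table
#'
#' @param E a \code{block_variant_effects}.
#' @return data.frame with block id, chromosome, variant pattern (comma
#'   joined codes), observation count and one column per available method.
#' @export
effects_table <- function(E) {
  stopifnot(inherits(E, "block_variant_effects"))
  rows <- lapply(seq_along(E$variants), function(b) {
    v <- E$variants[[b]]
    data.frame(block = b, chrom = E$blocks$blocks[[b]]$chrom,
               variant = apply(v$patterns, 1, paste, collapse = ","),
               count = v$counts,
               effect_ae = if (!is.null(E$effect_ae)) E$effect_ae[[b]] else NA,
               effect_sum = if (!is.null(E$effect_sum)) E$effect_sum[[b]] else NA,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
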