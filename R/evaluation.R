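#' Mantel test between two genomic relationship matrices
#'
#' Pearson correlation of the off-diagonal elements with a permutation
#' p-value (rows and columns of the second matrix permuted jointly),
#' computed with \code{vegan::mantel}. The correlation is invariant to the
#' affine conversion between similarity and distance, so GRMs are compared
#' directly.
#'
#' @param A,B \code{grm} objects (or bare symmetric matrices) over the same
#'   samples in the same order, n >= 4.
#' @param n_perm permutation count (default 999; p-value resolution
#'   1/(n_perm+1)).
#' @param seed integer seed for the permutations.
#' @return a \code{mantel_result}: \code{r}, \code{p}, \code{n_perm},
#'   \code{seed}.
#' @export
mantel_grm <- function(A, B, n_perm = 999, seed = 1L) {
  Am <- if (inherits(A, "grm")) A$matrix else as.matrix(A)
  Bm <- if (inherits(B, "grm")) B$matrix else as.matrix(B)
  if (!identical(dim(Am), dim(Bm))) stop("dimension mismatch")
  if (nrow(Am) < 4) stop("need at least 4 samples")
  if (!is.null(rownames(Am)) && !is.null(rownames(Bm)) &&
      !identical(rownames(Am), rownames(Bm)))
    stop("sample id mismatch between the two matrices")
  set.seed(seed)
  mt <- vegan::mantel(stats::as.dist(Am), stats::as.dist(Bm),
                      method = "pearson", permutations = n_perm)
  structure(list(r = unname(mt$statistic), p = unname(mt$signif),
                 n_perm = n_perm, seed = seed),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat("Mantel test: r = ", signif(x$r, 4), ", p = ", signif(x$p, 4),
      " (", x$n_perm, " permutations)\n", sep = "")
  invisible(x)
}

#' Rescale feature columns to [-1, 1]
#'
#' Column-wise min-max map onto [-1, 1], the coding expected by the
#' VanRaden relationship matrix; constant columns map to 0.
#'
#' @param F_mat numeric feature matrix.
#' @return rescaled matrix (provenance/chrom attributes preserved).
#' @export
rescale_features <- function(F_mat) {
  Fm <- as.matrix(F_mat)
  if (any(!is.finite(Fm))) stop("non-finite feature values")
  lo <- apply(Fm, 2, min); hi <- apply(Fm, 2, max)
  rng <- hi - lo
  out <- Fm
  const <- rng == 0
  if (any(!const))
    out[, !const] <- sweep(sweep(Fm[, !const, drop = FALSE], 2, lo[!const], "-"),
                           2, rng[!const], "/") * 2 - 1
  if (any(const)) out[, const] <- 0
  for (a in c("provenance", "chrom", "source_blocks"))
    attr(out, a) <- attr(F_mat, a)
  out
}

#' Repeated random cross-validation splits
#'
#' @param samples character vector of sample ids.
#' @param reps number of replicates (default 100).
#' @param test_fraction fraction held out per replicate (default 0.2;
#'   |test| = round(test_fraction * n)).
#' @param seed integer seed.
#' @return a \code{cv_plan}: list of replicates, each with \code{train} and
#'   \code{test} id vectors; scenario "standard".
#' @export
make_cv_plan <- function(samples, reps = 100, test_fraction = 0.2, seed = 1L) {
  n <- length(samples)
  if (n < 5) stop("need at least 5 samples")
  set.seed(seed)
  n_test <- round(test_fraction * n)
  splits <- lapply(seq_len(reps), function(r) {
    te <- sample(samples, n_test)
    list(train = setdiff(samples, te), test = te)
  })
  structure(list(splits = splits, scenario = "standard", seed = seed,
                 test_fraction = test_fraction),
            class = "cv_plan")
}

#' Leave-parents-out (T0) cross-validation splits for hybrids
#'
#' Per replicate, a subset of parents is sampled on each side; the test set
#' consists of hybrids whose parents are both in the sampled subsets (T0
#' hybrids relative to the training set), the training set of hybrids with
#' neither parent sampled; hybrids with exactly one sampled parent are
#' discarded for that replicate. Subset sizes are chosen so the expected
#' test share approximates \code{test_fraction}.
#'
#' @param crosses cross table (hybrid, parent1, parent2).
#' @param reps replicates (default 100).
#' @param test_fraction target test share (default 0.2).
#' @param seed integer seed.
#' @return a \code{cv_plan} with scenario "t0"; each replicate also records
#'   the sampled \code{test_parents1}/\code{test_parents2}.
#' @export
make_t0_plan <- function(crosses, reps = 100, test_fraction = 0.2, seed = 1L) {
  crosses <- as.data.frame(crosses, stringsAsFactors = FALSE)
  p1 <- unique(crosses$parent1); p2 <- unique(crosses$parent2)
  if (length(p1) < 4 || length(p2) < 4)
    stop("T0 plan needs at least 4 parents per side")
  set.seed(seed)
  k1 <- max(2, round(length(p1) * sqrt(test_fraction)))
  k2 <- max(2, round(length(p2) * sqrt(test_fraction)))
  splits <- lapply(seq_len(reps), function(r) {
    s1 <- sample(p1, k1); s2 <- sample(p2, k2)
    in1 <- crosses$parent1 %in% s1; in2 <- crosses$parent2 %in% s2
    te <- crosses$hybrid[in1 & in2]
    tr <- crosses$hybrid[!in1 & !in2]
    if (length(te) == 0)
      stop("factorial structure cannot yield a nonempty T0 test set")
    list(train = tr, test = te, test_parents1 = s1, test_parents2 = s2)
  })
  structure(list(splits = splits, scenario = "t0", seed = seed,
                 test_fraction = test_fraction, crosses = crosses),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  sz <- vapply(x$splits, function(s) length(s$test), integer(1))
  cat("cv_plan (", x$scenario, "): ", length(x$splits),
      " replicates; test size ", min(sz), "-", max(sz), "\n", sep = "")
  invisible(x)
}

#' Run cross-validation with a predictor factory
#'
#' Per replicate the predictor is trained on the training ids and asked for
#' predictions on the test ids; accuracy is the Pearson correlation of
#' observed and predicted phenotypes on the test set. Replicates where the
#' predictions are constant are recorded as NA (undefined), never dropped
#' silently.
#'
#' @param plan a \code{cv_plan}.
#' @param predictor function(train_ids, test_ids) returning a vector of
#'   predictions named by (or ordered as) test_ids.
#' @param y named phenotype vector covering all samples in the plan.
#' @return a \code{cv_result}: data.frame (replicate, n_test, accuracy) with
#'   a summary (median, quartiles, n_undefined) in attribute \code{summary}.
#' @export
run_cv <- function(plan, predictor, y) {
  stopifnot(inherits(plan, "cv_plan"))
  acc <- vapply(seq_along(plan$splits), function(r) {
    s <- plan$splits[[r]]
    pred <- predictor(s$train, s$test)
    if (!is.null(names(pred))) pred <- pred[s$test]
    obs <- y[s$test]
    if (stats::sd(pred) == 0 || stats::sd(obs) == 0) return(NA_real_)
    stats::cor(obs, pred)
  }, numeric(1))
  res <- data.frame(replicate = seq_along(plan$splits),
                    n_test = vapply(plan$splits, function(s)
                      length(s$test), integer(1)),
                    accuracy = acc)
  qs <- stats::quantile(acc, c(0.25, 0.5, 0.75), na.rm = TRUE)
  attr(res, "summary") <- list(median = unname(qs[2]), q1 = unname(qs[1]),
                               q3 = unname(qs[3]),
                               n_undefined = sum(is.na(acc)))
  class(res) <- c("cv_result", "data.frame")
  res
}

#' @export
print.cv_result <- function(x, ...) {
  s <- attr(x, "summary")
  cat("cv_result: ", nrow(x), " replicates; median accuracy ",
      signif(s$median, 4), " [Q1 ", signif(s$q1, 4), ", Q3 ",
      signif(s$q3, 4), "]", sep = "")
  if (s$n_undefined > 0) cat("; ", s$n_undefined, " undefined", sep = "")
  cat("\n")
  invisible(x)
}

#' GBLUP predictor factory for cross-validation
#'
#' Returns a closure suitable for \code{\link{run_cv}} that fits a line
#' GBLUP on the training samples using the given relationship matrix and
#' predicts the test samples through their G rows.
#'
#' @param G a \code{grm} covering all samples.
#' @param y named phenotype vector.
#' @return function(train_ids, test_ids) -> named predictions.
#' @export
gblup_predictor <- function(G, y) {
  force(G); force(y)
  function(train_ids, test_ids) {
    fit <- gblup(y[train_ids], G)
    predict(fit, test_ids)
  }
}
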