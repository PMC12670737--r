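#' VanRaden method I genomic relationship matrix
#'
#' G = ZZ'/c with Z the column-centred code matrix and c = 2 * sum p(1-p).
#' For -1/0/1 genotype codes the column "allele frequency" p is the
#' major-allele frequency (mean+1)/2; the same convention is applied to
#' rescaled autoencoder features in [-1, 1], where p is a formal frequency
#' derived from the column mean.
#'
#' @param M numeric matrix (samples x markers/features), values in [-1, 1],
#'   complete, or a \code{genotype_matrix}.
#' @return an object of class \code{grm}: \code{matrix} (n x n), \code{samples},
#'   scaling constant \code{c}, column frequencies \code{p} and column centres.
#' @export
grm_vanraden <- function(M) {
  if (inherits(M, "genotype_matrix")) M <- M$codes
  M <- as.matrix(M)
  if (anyNA(M)) stop("GRM needs a complete matrix; impute first")
  if (min(M) < -1 - 1e-9 || max(M) > 1 + 1e-9) stop("values must lie in [-1, 1]")
  p <- (colMeans(M) + 1) / 2
  cc <- 2 * sum(p * (1 - p))
  if (cc <= 0) stop("all columns monomorphic: scaling constant c = 0")
  Z <- sweep(M, 2, 2 * (p - 0.5), "-")
  G <- tcrossprod(Z) / cc
  samples <- rownames(M)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(M)))
  dimnames(G) <- list(samples, samples)
  structure(list(matrix = G, samples = samples, c = cc, p = p,
                 centers = 2 * (p - 0.5)),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("grm (VanRaden I): ", length(x$samples), " samples, c = ",
      signif(x$c, 5), ", mean diagonal = ",
      signif(mean(diag(x$matrix)), 4), "\n", sep = "")
  invisible(x)
}

# restricted log-likelihood pieces for the 1-kernel model in the eigen basis
.reml1_profile <- function(log_lambda, d, ystar, xstar) {
  lambda <- exp(log_lambda)
  w <- 1 / (lambda * d + 1)
  xtx <- sum(xstar^2 * w)
  beta <- sum(xstar * ystar * w) / xtx
  r <- ystar - xstar * beta
  np <- length(ystar) - 1
  s2r <- sum(r^2 * w) / np
  ll <- -0.5 * (np * log(s2r) + sum(log(lambda * d + 1)) + log(xtx) + np)
  list(ll = ll, beta = beta, s2r = s2r, lambda = lambda)
}

#' Write / read a relationship matrix as a delimited symmetric table
#'
#' @param G a \code{grm} (or bare symmetric matrix with dimnames).
#' @param path file path; sample ids form the header and first column.
#' @export
write_grm <- function(G, path) {
  Gm <- if (inherits(G, "grm")) G$matrix else as.matrix(G)
  utils::write.table(data.frame(sample = rownames(Gm), Gm, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grm
#' @return \code{read_grm}: the symmetric matrix with dimnames.
#' @export
read_grm <- function(path) {
  tab <- utils::read.table(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  Gm <- as.matrix(tab[, -1, drop = FALSE])
  rownames(Gm) <- as.character(tab[[1]])
  Gm
}

#' GBLUP for inbred lines
#'
#' Fits y = 1 b0 + u + e with u ~ N(0, s2A G) and e ~ N(0, s2R I) on the
#' phenotyped samples (the names of \code{y}); variance components by exact
#' REML profiled over the variance ratio in the eigen basis of G. BLUPs are
#' returned for every sample of the relationship matrix, so unphenotyped
#' samples are predicted through their G rows.
#'
#' @param y named phenotype vector; names must be samples of \code{G}.
#' @param G a \code{grm} (or bare symmetric matrix with dimnames).
#' @param sigma2 optional named vector c(A = , R = ) of fixed variance
#'   components; when given, REML is skipped and BLUPs are computed at these
#'   values (both must be > 0).
#' @return an object of class \code{gblup_fit} with elements \code{beta0},
#'   \code{sigma2} (named c(A, R)), \code{u} (BLUPs for all samples of G),
#'   \code{fitted} (b0 + u), \code{loglik}, \code{train}, \code{G}.
#' @export
gblup <- function(y, G, sigma2 = NULL) {
  Gm <- if (inherits(G, "grm")) G$matrix else as.matrix(G)
  if (is.null(names(y))) stop("y must be named by sample id")
  tr <- names(y)
  if (!all(tr %in% rownames(Gm))) stop("phenotyped sample(s) missing from G")
  n <- length(y)
  if (n < 3) stop("need at least 3 phenotyped samples")
  Gtt <- Gm[tr, tr]
  if (stats::var(y) < 1e-12) {
    u <- stats::setNames(rep(0, nrow(Gm)), rownames(Gm))
    fit <- structure(list(beta0 = mean(y), sigma2 = c(A = 0, R = 0), u = u,
                          fitted = u + mean(y), loglik = NA_real_, train = tr,
                          y_train = y, G = G, kind = "line", vinv_r = NULL),
                     class = "gblup_fit")
    return(fit)
  }
  ev <- eigen(Gtt, symmetric = TRUE)
  d <- pmax(ev$values, 0)
  ystar <- drop(crossprod(ev$vectors, y))
  xstar <- drop(crossprod(ev$vectors, rep(1, n)))
  if (is.null(sigma2)) {
    opt <- stats::optimize(function(l) .reml1_profile(l, d, ystar, xstar)$ll,
                           interval = c(-25, 25), maximum = TRUE, tol = 1e-10)
    prof <- .reml1_profile(opt$maximum, d, ystar, xstar)
    s2r <- prof$s2r
    s2a <- prof$lambda * s2r
    beta0 <- prof$beta
    ll <- prof$ll
  } else {
    stopifnot(all(c("A", "R") %in% names(sigma2)), sigma2[["R"]] > 0)
    s2a <- sigma2[["A"]]; s2r <- sigma2[["R"]]
    prof <- .reml1_profile(log(s2a / s2r), d, ystar, xstar)
    beta0 <- prof$beta
    ll <- prof$ll
  }
  # BLUPs for every sample through V^{-1}(y - 1 b0) on the training block
  Vi_r <- ev$vectors %*% ((ystar - xstar * beta0) / (s2a * d + s2r))
  u_all <- drop(s2a * Gm[, tr, drop = FALSE] %*% Vi_r)
  names(u_all) <- rownames(Gm)
  structure(list(beta0 = beta0, sigma2 = c(A = s2a, R = s2r), u = u_all,
                 fitted = beta0 + u_all, loglik = ll, train = tr,
                 y_train = y, G = G, kind = "line",
                 vinv_r = stats::setNames(drop(Vi_r), tr)),
            class = "gblup_fit")
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat("gblup_fit (", x$kind, "): ", length(x$train), " phenotyped samples\n",
      "  intercept: ", signif(x$beta0, 5), "\n", sep = "")
  cat("  variance components:\n")
  print(signif(x$sigma2, 5))
  if (x$kind == "line" && x$sigma2[["A"]] + x$sigma2[["R"]] > 0)
    cat("  h2 (ratio scale): ",
        signif(x$sigma2[["A"]] / sum(x$sigma2[c("A", "R")]), 4), "\n", sep = "")
  invisible(x)
}

#' @export
summary.gblup_fit <- function(object, ...) {
  print(object)
  cat("  REML log-likelihood: ", signif(object$loglik, 8), "\n", sep = "")
  invisible(object)
}

#' @export
coef.gblup_fit <- function(object, ...) c(`(Intercept)` = object$beta0)

#' Predict genotypic values from a GBLUP fit
#'
#' @param object a \code{gblup_fit}.
#' @param ids sample ids (line model) or a cross table with columns
#'   \code{hybrid}, \code{parent1}, \code{parent2} (GCA/SCA model); default:
#'   all samples known to the fit.
#' @param ... unused.
#' @return named vector of predictions (intercept + BLUPs).
#' @export
predict.gblup_fit <- function(object, ids = NULL, ...) {
  if (object$kind == "line") {
    if (is.null(ids)) return(object$fitted)
    if (!all(ids %in% names(object$fitted))) {
      Gm <- if (inherits(object$G, "grm")) object$G$matrix else object$G
      stop("unknown sample id(s): ",
           paste(setdiff(ids, rownames(Gm)), collapse = ", "))
    }
    object$fitted[ids]
  } else {
    predict_gca_sca(object, ids)
  }
}

#' @export
fitted.gblup_fit <- function(object, ...) object$fitted[object$train]

#' @export
residuals.gblup_fit <- function(object, ...) {
  object$y_train - object$fitted[object$train]
}

# Multi-kernel REML: y = 1 b0 + sum_k u_k + e, var(y) = sum th_k K_k + th_R I.
# AI-REML steps with EM fallback (EM is monotone in the restricted
# likelihood); convergence on relative log-likelihood change < 1e-8.
fit_reml_kernels <- function(y, kernels, method = c("ai", "em"),
                             max_iter = 200, tol = 1e-8) {
  method <- match.arg(method)
  n <- length(y)
  nk <- length(kernels)
  vy <- stats::var(y)
  theta <- rep(vy / (nk + 1), nk + 1)      # kernels..., residual last
  X <- matrix(1, n, 1)
  Ks <- c(kernels, list(diag(n)))
  lower <- 1e-10
  eval_state <- function(theta) {
    V <- Reduce(`+`, Map(function(t, K) t * K, theta, Ks))
    Vi <- tryCatch(solve(V), error = function(e) solve(V + diag(1e-6 * vy, n)))
    XtVi <- crossprod(X, Vi)
    XtViX <- XtVi %*% X
    P <- Vi - t(XtVi) %*% solve(XtViX) %*% XtVi
    Py <- drop(P %*% y)
    ll <- -0.5 * (determinant(V, logarithm = TRUE)$modulus +
                    determinant(XtViX, logarithm = TRUE)$modulus +
                    sum(y * Py))
    list(P = P, Py = Py, ll = as.numeric(ll))
  }
  st <- eval_state(theta)
  trace_ll <- st$ll
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    PK <- lapply(Ks, function(K) st$P %*% K)
    KPy <- lapply(Ks, function(K) drop(K %*% st$Py))
    score <- vapply(seq_along(Ks), function(k)
      -0.5 * (sum(diag(PK[[k]])) - sum(st$Py * KPy[[k]])), numeric(1))
    em_step <- function() {
      pmax(theta + theta^2 / n *
             vapply(seq_along(Ks), function(k)
               sum(st$Py * KPy[[k]]) - sum(diag(PK[[k]])), numeric(1)),
           lower)
    }
    if (method == "ai") {
      PKPy <- lapply(seq_along(Ks), function(k) drop(st$P %*% KPy[[k]]))
      AI <- matrix(0, nk + 1, nk + 1)
      for (a in seq_along(Ks)) for (b in a:length(Ks)) {
        AI[a, b] <- AI[b, a] <- 0.5 * sum(PKPy[[a]] * KPy[[b]])
      }
      step <- tryCatch(solve(AI, score), error = function(e) NULL)
      theta_new <- if (!is.null(step)) pmax(theta + step, lower) else em_step()
      st_new <- eval_state(theta_new)
      if (st_new$ll < st$ll - 1e-8) {        # AI overshoot: fall back to EM
        theta_new <- em_step()
        st_new <- eval_state(theta_new)
      }
    } else {
      theta_new <- em_step()
      st_new <- eval_state(theta_new)
    }
    trace_ll <- c(trace_ll, st_new$ll)
    done <- abs(st_new$ll - st$ll) / (abs(st$ll) + 1) < tol
    theta <- theta_new
    st <- st_new
    if (done) { converged <- TRUE; break }
  }
  if (!converged)
    stop("REML did not converge in ", max_iter,
         " iterations; log-likelihood trace: ",
         paste(signif(utils::tail(trace_ll, 5), 6), collapse = ", "))
  XtVi <- crossprod(X, chol2inv(chol(
    Reduce(`+`, Map(function(t, K) t * K, theta, Ks)) + diag(0, n))))
  beta0 <- drop(XtVi %*% y) / drop(XtVi %*% X)
  list(theta = theta, beta0 = beta0, ll = st$ll, trace = trace_ll,
       Py = st$Py, n_iter = length(trace_ll) - 1)
}

#' GBLUP for hybrids with GCA and SCA effects
#'
#' Fits y = 1 b0 + Z1 u1 + Z2 u2 + Zs us + e where u1, u2 are general
#' combining abilities of the two parental pools with covariances s2_1 G1 and
#' s2_2 G2, and us are specific combining abilities with covariance
#' s2_s (G1 kron G2) restricted to the realised parent pairs, so the SCA
#' covariance of hybrids (i,j) and (k,l) is G1[i,k] * G2[j,l]. Variance
#' components by AI-REML with a monotone EM fallback.
#'
#' @param y named phenotype vector over hybrid ids.
#' @param G1,G2 \code{grm} objects over parents 1 and 2.
#' @param crosses cross table (hybrid, parent1, parent2) covering at least
#'   the phenotyped hybrids.
#' @param method "ai" (default) or "em" (pure EM iterations).
#' @param max_iter,tol REML convergence controls.
#' @return a \code{gblup_fit} of kind "gca_sca" with \code{sigma2}
#'   (named c(gca1, gca2, sca, R)), BLUPs \code{u1}, \code{u2}, \code{us},
#'   the REML log-likelihood \code{trace}, and prediction bookkeeping.
#' @export
gblup_gca_sca <- function(y, G1, G2, crosses, method = c("ai", "em"),
                          max_iter = 200, tol = 1e-8) {
  method <- match.arg(method)
  stopifnot(inherits(G1, "grm"), inherits(G2, "grm"))
  crosses <- as.data.frame(crosses, stringsAsFactors = FALSE)
  if (is.null(names(y))) stop("y must be named by hybrid id")
  cr <- crosses[match(names(y), crosses$hybrid), , drop = FALSE]
  if (anyNA(cr$hybrid)) stop("phenotyped hybrid(s) missing from cross table")
  unknown <- setdiff(c(cr$parent1, cr$parent2), c(G1$samples, G2$samples))
  if (!all(cr$parent1 %in% G1$samples) || !all(cr$parent2 %in% G2$samples))
    stop("hybrid with unknown parent: ", paste(unknown, collapse = ", "))
  i1 <- match(cr$parent1, G1$samples)
  i2 <- match(cr$parent2, G2$samples)
  K1 <- G1$matrix[i1, i1, drop = FALSE]
  K2 <- G2$matrix[i2, i2, drop = FALSE]
  Ks <- K1 * K2
  fit <- fit_reml_kernels(y, list(K1, K2, Ks), method = method,
                          max_iter = max_iter, tol = tol)
  th <- fit$theta
  Py <- fit$Py          # P y = V^{-1}(y - X b0) for the REML projection
  # BLUPs on all parents / realised pairs
  u1 <- drop(th[1] * G1$matrix[, i1, drop = FALSE] %*% Py)
  names(u1) <- G1$samples
  u2 <- drop(th[2] * G2$matrix[, i2, drop = FALSE] %*% Py)
  names(u2) <- G2$samples
  us <- drop(th[3] * Ks %*% Py)
  names(us) <- names(y)
  structure(list(beta0 = fit$beta0,
                 sigma2 = c(gca1 = th[1], gca2 = th[2], sca = th[3], R = th[4]),
                 u = us, u1 = u1, u2 = u2, us = us,
                 fitted = fit$beta0 + u1[cr$parent1] + u2[cr$parent2] + us,
                 loglik = fit$ll, trace = fit$trace, n_iter = fit$n_iter,
                 train = names(y), y_train = y, crosses = cr,
                 G = list(G1 = G1, G2 = G2), Py = Py, kind = "gca_sca"),
            class = "gblup_fit")
}

# predictions for arbitrary parent pairs, including unobserved (T0) pairs
predict_gca_sca <- function(fit, crosses_new) {
  if (is.null(crosses_new)) return(fit$fitted)
  crosses_new <- as.data.frame(crosses_new, stringsAsFactors = FALSE)
  G1 <- fit$G$G1; G2 <- fit$G$G2
  if (!all(crosses_new$parent1 %in% G1$samples) ||
      !all(crosses_new$parent2 %in% G2$samples))
    stop("prediction requested for unknown parent id(s)")
  th <- fit$sigma2
  i1t <- match(fit$crosses$parent1, G1$samples)
  i2t <- match(fit$crosses$parent2, G2$samples)
  a <- match(crosses_new$parent1, G1$samples)
  b <- match(crosses_new$parent2, G2$samples)
  C1 <- G1$matrix[a, i1t, drop = FALSE]
  C2 <- G2$matrix[b, i2t, drop = FALSE]
  u1 <- drop(th[["gca1"]] * C1 %*% fit$Py)
  u2 <- drop(th[["gca2"]] * C2 %*% fit$Py)
  us <- drop(th[["sca"]] * (C1 * C2) %*% fit$Py)
  stats::setNames(fit$beta0 + u1 + u2 + us, crosses_new$hybrid)
}

#' Back-transform GBLUP genotype effects to marker effects
#'
#' Uses the mathematical equivalence of GBLUP and RR-BLUP: with Z the centred
#' code matrix and G = ZZ'/c, the ridge-regression marker effects are
#' a = Z' G^{-1} u / c, evaluated on the training samples. A pseudo-inverse
#' (eigen decomposition, small eigenvalues dropped) is used when G is
#' singular.
#'
#' @param fit a line-model \code{gblup_fit}.
#' @param M the code matrix (samples x markers) the GRM was built from, or a
#'   \code{genotype_matrix}.
#' @return an object of class \code{marker_effects}: per-marker additive
#'   effects \code{a}, the column \code{centers} used, and the GRM scaling
#'   constant \code{c}.
#' @export
marker_effects <- function(fit, M) {
  stopifnot(inherits(fit, "gblup_fit"))
  if (fit$kind != "line")
    stop("back-transformation is defined for the line (single-kernel) model; ",
         "fit a single-kernel GBLUP on the hybrid code matrix instead")
  if (inherits(M, "genotype_matrix")) M <- M$codes
  M <- as.matrix(M)
  G <- fit$G
  if (!inherits(G, "grm"))
    stop("fit must carry the grm object it was fitted with")
  tr <- fit$train
  if (!all(tr %in% rownames(M))) stop("training samples missing from M")
  Z <- sweep(M[tr, , drop = FALSE], 2, G$centers, "-")
  u <- fit$u[tr]
  Gtt <- G$matrix[tr, tr]
  # a column-centred GRM is always rank-deficient by one; use the
  # pseudo-inverse and only warn when the BLUPs are not reproduced
  ev <- eigen(Gtt, symmetric = TRUE)
  keep <- ev$values > max(ev$values) * 1e-10
  Giu <- ev$vectors[, keep, drop = FALSE] %*%
    (crossprod(ev$vectors[, keep, drop = FALSE], u) / ev$values[keep])
  a <- drop(crossprod(Z, Giu)) / G$c
  resid <- max(abs(drop(Z %*% a) - u))
  if (resid > 1e-6 * max(1, max(abs(u))))
    warning("BLUPs outside the GRM column space; marker effects are a ",
            "least-squares approximation (max deviation ", signif(resid, 3), ")")
  structure(list(a = stats::setNames(a, colnames(M)), centers = G$centers,
                 c = G$c, train = tr),
            class = "marker_effects")
}

#' @export
print.marker_effects <- function(x, ...) {
  cat("marker_effects: ", length(x$a), " markers; |a| range [",
      signif(min(abs(x$a)), 3), ", ", signif(max(abs(x$a)), 3), "]\n", sep = "")
  invisible(x)
}

#' Block-wise sums of marker effects per block variant
#'
#' The baseline haplotype-block-variant effect: for block b and variant v
#' (a marker-code pattern over b's markers), the effect is the sum of
#' centred codes times the per-marker effects, sum_j (v_j - center_j) a_j.
#' Unassigned markers contribute to no block.
#'
#' @param me a \code{marker_effects} object.
#' @param blocks a \code{haploblock_set}.
#' @param catalogue a variant catalogue from \code{\link{enumerate_variants}}.
#' @return a \code{block_variant_effects} object with method "sum" filled in.
#' @export
blockwise_effect_sums <- function(me, blocks, catalogue) {
  stopifnot(inherits(me, "marker_effects"), inherits(blocks, "haploblock_set"))
  effs <- lapply(seq_along(blocks$blocks), function(bi) {
    b <- blocks$blocks[[bi]]
    cat_b <- catalogue$variants[[bi]]
    if (ncol(cat_b$patterns) != b$size)
      stop("variant length ", ncol(cat_b$patterns), " != block size ", b$size)
    Zv <- sweep(cat_b$patterns, 2, me$centers[b$markers], "-")
    drop(Zv %*% me$a[b$markers])
  })
  structure(list(blocks = blocks, variants = catalogue$variants,
                 effect_sum = effs, effect_ae = NULL),
            class = "block_variant_effects")
}
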