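#' Squared Pearson correlation between two genotype-code vectors
#'
#' The r-squared linkage-disequilibrium measure used for block building:
#' the squared Pearson correlation of dosage codes (composite LD, valid for
#' unphased data; equal to haplotype r-squared for fully homozygous lines).
#' Returns 0 when either vector is constant.
#'
#' @param x,y numeric vectors of equal length >= 2, no missing values.
#' @return value in [0, 1].
#' @export
ld_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 2) stop("need length >= 2")
  if (anyNA(x) || anyNA(y)) stop("missing values; impute first")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)^2
}

#' Block-building thresholds
#'
#' @param ld_threshold adjacent-pair r-squared needed for a marker to join a
#'   block (default 0.7, inclusive).
#' @param tolerance number of sub-threshold adjacent joins allowed within one
#'   block (default 1).
#' @return a \code{block_build_config} list.
#' @export
block_build_config <- function(ld_threshold = 0.7, tolerance = 1L) {
  stopifnot(ld_threshold > 0, ld_threshold <= 1, tolerance >= 0)
  structure(list(ld_threshold = ld_threshold, tolerance = as.integer(tolerance)),
            class = "block_build_config")
}

new_haploblock_set <- function(blocks, unassigned, source_dim) {
  structure(list(blocks = blocks,
                 unassigned = as.integer(sort(unassigned)),
                 source_dim = as.integer(source_dim)),
            class = "haploblock_set")
}

#' @export
print.haploblock_set <- function(x, ...) {
  sizes <- vapply(x$blocks, function(b) b$size, integer(1))
  cat("haploblock_set: ", length(x$blocks), " blocks covering ",
      sum(sizes), "/", x$source_dim, " variables; ",
      length(x$unassigned), " unassigned\n", sep = "")
  if (length(sizes) > 0)
    cat("  block sizes: min ", min(sizes), ", median ",
        stats::median(sizes), ", max ", max(sizes), "\n", sep = "")
  invisible(x)
}

#' @export
length.haploblock_set <- function(x) length(x$blocks)

#' Sizes of the blocks in a haploblock set
#' @param bs a \code{haploblock_set}.
#' @return integer vector of block sizes.
#' @export
block_sizes <- function(bs) vapply(bs$blocks, function(b) b$size, integer(1))

# Greedy left-to-right scan over one chromosome's adjacency.
# join_ok[i] says whether variables i and i+1 may join freely; tolerance
# sub-threshold joins are allowed per block but a block may not end on one
# (trailing tolerated joins are trimmed; the trimmed variable restarts the
# scan). Returns list(blocks = list of index vectors, unassigned = indices).
greedy_scan <- function(idx, join_ok, tolerance) {
  blocks <- list()
  unassigned <- integer(0)
  n <- length(idx)
  close_candidate <- function(members, tolerated) {
    # trim trailing tolerated joins
    n_trim <- 0L
    while (length(members) >= 2 && tolerated[length(members) - 1L]) {
      members <- members[-length(members)]
      tolerated <- tolerated[-length(tolerated)]
      n_trim <- n_trim + 1L
    }
    list(members = members, n_trim = n_trim)
  }
  s <- 1L
  members <- idx[1]
  tolerated <- logical(0)
  tol_used <- 0L
  pos <- 1L  # position (within idx) of the last member
  while (TRUE) {
    if (pos == n) {
      cc <- close_candidate(members, tolerated)
      if (length(cc$members) >= 2) blocks[[length(blocks) + 1L]] <- cc$members
      else unassigned <- c(unassigned, cc$members)
      if (cc$n_trim > 0) {
        # restart at the first trimmed variable
        s <- pos - cc$n_trim + 1L
        pos <- s
        members <- idx[s]
        tolerated <- logical(0)
        tol_used <- 0L
        if (s == n) { # single trailing variable left
          unassigned <- c(unassigned, idx[s])
          break
        }
        next
      }
      break
    }
    ok <- join_ok[pos]
    if (ok) {
      members <- c(members, idx[pos + 1L])
      tolerated <- c(tolerated, FALSE)
      pos <- pos + 1L
    } else if (tol_used < tolerance) {
      members <- c(members, idx[pos + 1L])
      tolerated <- c(tolerated, TRUE)
      tol_used <- tol_used + 1L
      pos <- pos + 1L
    } else {
      cc <- close_candidate(members, tolerated)
      if (length(cc$members) >= 2) blocks[[length(blocks) + 1L]] <- cc$members
      else unassigned <- c(unassigned, cc$members)
      # new candidate starts at first trimmed variable, or at the refused one
      s <- if (cc$n_trim > 0) pos - cc$n_trim + 1L else pos + 1L
      pos <- s
      members <- idx[s]
      tolerated <- logical(0)
      tol_used <- 0L
      if (s == n) {
        unassigned <- c(unassigned, idx[s])
        break
      }
    }
  }
  list(blocks = blocks, unassigned = unassigned)
}

#' Build LD-based haplotype blocks
#'
#' Scans each chromosome left to right in map order. A candidate block starts
#' at the first unassigned marker; the next marker joins if the r-squared
#' between it and the block's current last marker reaches
#' \code{ld_threshold}, or (up to \code{tolerance} times per block) the
#' sub-threshold join is tolerated. A closed block never ends on a tolerated
#' join, and blocks of a single marker are left unassigned.
#'
#' @param G a complete \code{genotype_matrix} (markers sorted by map).
#' @param cfg a \code{block_build_config}.
#' @return a \code{haploblock_set}; block marker indices refer to columns of
#'   \code{G$codes}.
#' @export
build_blocks <- function(G, cfg = block_build_config()) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (anyNA(G$codes)) stop("missing values; run impute_missing first")
  blocks <- list()
  unassigned <- integer(0)
  for (chr in unique(G$map$chrom)) {
    idx <- which(G$map$chrom == chr)
    if (length(idx) == 1) {
      unassigned <- c(unassigned, idx)
      next
    }
    r2_adj <- vapply(seq_len(length(idx) - 1L), function(i)
      ld_r2(G$codes[, idx[i]], G$codes[, idx[i + 1L]]), numeric(1))
    sc <- greedy_scan(idx, r2_adj >= cfg$ld_threshold, cfg$tolerance)
    for (b in sc$blocks)
      blocks[[length(blocks) + 1L]] <- list(chrom = chr, markers = b,
                                            size = length(b))
    unassigned <- c(unassigned, sc$unassigned)
  }
  new_haploblock_set(blocks, unassigned, ncol(G$codes))
}

#' Group autoencoder features into meta-blocks by adjacent correlation
#'
#' Same greedy scan as \code{\link{build_blocks}} but over feature columns in
#' their genome (provenance) order: an adjacent feature joins when the
#' absolute Pearson correlation strictly exceeds \code{threshold}
#' (tolerance 0). Chromosome boundaries of the source blocks are respected.
#' Constant columns correlate 0 with their neighbours. Singletons stay
#' unassigned.
#'
#' @param F_mat numeric feature matrix (samples x features) in genome order.
#' @param threshold correlation threshold (default 0.7, strict).
#' @param chrom optional chromosome label per feature column.
#' @return a \code{haploblock_set} over feature columns.
#' @export
build_meta_blocks <- function(F_mat, threshold = 0.7, chrom = NULL) {
  F_mat <- as.matrix(F_mat)
  if (anyNA(F_mat)) stop("missing values in feature matrix")
  if (is.null(chrom)) chrom <- rep("1", ncol(F_mat))
  blocks <- list()
  unassigned <- integer(0)
  abs_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
    abs(stats::cor(x, y))
  }
  for (chr in unique(chrom)) {
    idx <- which(chrom == chr)
    if (length(idx) == 1) {
      unassigned <- c(unassigned, idx)
      next
    }
    r_adj <- vapply(seq_len(length(idx) - 1L), function(i)
      abs_cor(F_mat[, idx[i]], F_mat[, idx[i + 1L]]), numeric(1))
    sc <- greedy_scan(idx, r_adj > threshold, 0L)
    for (b in sc$blocks)
      blocks[[length(blocks) + 1L]] <- list(chrom = chr, markers = b,
                                            size = length(b))
    unassigned <- c(unassigned, sc$unassigned)
  }
  new_haploblock_set(blocks, unassigned, ncol(F_mat))
}

#' Full pairwise r-squared matrix (diagnostics)
#'
#' @param G a complete \code{genotype_matrix}.
#' @return m x m matrix of pairwise squared correlations (1 on the diagonal
#'   for non-constant markers).
#' @export
pairwise_ld <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (anyNA(G$codes)) stop("missing values; run impute_missing first")
  sds <- apply(G$codes, 2, stats::sd)
  cc <- suppressWarnings(stats::cor(G$codes))
  cc[is.na(cc)] <- 0
  cc[sds == 0, ] <- 0
  cc[, sds == 0] <- 0
  r2 <- cc^2
  dimnames(r2) <- list(G$map$id, G$map$id)
  r2
}

#' Write a haploblock set as a delimited table
#'
#' One row per block (block id, chromosome, comma-joined marker indices,
#' size) followed by rows with block id "unassigned" for unassigned markers.
#'
#' @param bs a \code{haploblock_set}.
#' @param path output file.
#' @export
write_blocks <- function(bs, path) {
  rows <- lapply(seq_along(bs$blocks), function(i) {
    b <- bs$blocks[[i]]
    data.frame(block = paste0("B", i), chrom = b$chrom,
               markers = paste(b$markers, collapse = ","), size = b$size)
  })
  if (length(bs$unassigned) > 0)
    rows[[length(rows) + 1L]] <- data.frame(
      block = "unassigned", chrom = NA,
      markers = paste(bs$unassigned, collapse = ","),
      size = length(bs$unassigned))
  tab <- do.call(rbind, rows)
  attr_line <- paste0("# source_dim=", bs$source_dim)
  writeLines(attr_line, path)
  suppressWarnings(utils::write.table(tab, path, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  invisible(path)
}

#' Read a haploblock set written by \code{write_blocks}
#' @param path input file.
#' @return a \code{haploblock_set}.
#' @export
read_blocks <- function(path) {
  first <- readLines(path, n = 1)
  source_dim <- as.integer(sub("# source_dim=", "", first, fixed = TRUE))
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  is_un <- tab$block == "unassigned"
  blocks <- lapply(which(!is_un), function(i) {
    m <- as.integer(strsplit(tab$markers[i], ",")[[1]])
    list(chrom = as.character(tab$chrom[i]), markers = m, size = length(m))
  })
  unassigned <- if (any(is_un))
    as.integer(strsplit(tab$markers[is_un][1], ",")[[1]]) else integer(0)
  new_haploblock_set(blocks, unassigned, source_dim)
}
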