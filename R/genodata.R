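#' Construct a genotype matrix object
#'
#' Bundles a numeric sample-by-marker matrix of genotype dosage codes with its
#' marker map. Codes follow the minor/heterozygote/major convention:
#' \code{+1} = homozygous for the major (more frequent) allele, \code{-1} =
#' homozygous for the minor allele, \code{0} = heterozygous. Missing calls are
#' \code{NA}.
#'
#' @param codes numeric matrix, n samples x m markers, entries in
#'   \{-1, 0, 1\} or \code{NA}. Row names are taken as sample ids if
#'   \code{samples} is missing.
#' @param map data.frame with columns \code{id}, \code{chrom}, \code{pos}
#'   (integer base pairs), one row per marker column of \code{codes}.
#' @param samples character vector of sample identifiers.
#' @return An object of class \code{genotype_matrix} with elements
#'   \code{codes}, \code{map}, \code{samples}. Markers are sorted by
#'   (chromosome, position).
#' @export
genotype_matrix <- function(codes, map, samples = rownames(codes)) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "double"
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(codes)))
  samples <- as.character(samples)
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  if (!all(c("id", "chrom", "pos") %in% names(map)))
    stop("marker map needs columns id, chrom, pos")
  map$id <- as.character(map$id)
  map$chrom <- as.character(map$chrom)
  map$pos <- as.integer(map$pos)
  if (nrow(map) != ncol(codes))
    stop("map has ", nrow(map), " rows but codes has ", ncol(codes), " columns")
  if (nrow(codes) < 2 || ncol(codes) < 1)
    stop("need at least 2 samples and 1 marker")
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  bad <- !(codes %in% c(-1, 0, 1)) & !is.na(codes)
  if (any(bad)) stop("genotype codes must be -1, 0, 1 or NA")
  if (anyDuplicated(map[, c("chrom", "pos", "id")]))
    stop("duplicate (chrom, pos, id) in marker map")
  # sort markers by (chromosome, position); stable so input order breaks ties
  ord <- order(map$chrom, map$pos)
  map <- map[ord, , drop = FALSE]
  codes <- codes[, ord, drop = FALSE]
  rownames(map) <- NULL
  dimnames(codes) <- list(samples, map$id)
  structure(list(codes = codes, map = map, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  nm <- sum(is.na(x$codes))
  cat("genotype_matrix: ", length(x$samples), " samples x ", nrow(x$map),
      " markers on ", length(unique(x$map$chrom)), " chromosome(s)",
      if (nm > 0) paste0("; ", nm, " missing calls"), "\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$codes)

#' Filtering thresholds for genotype data
#'
#' @param max_sample_missing samples with a missing-call fraction strictly
#'   above this are removed first (default 0.60).
#' @param max_marker_missing markers with a missing fraction at or above this
#'   are removed (default 0.10; "10 percent or more").
#' @param min_expected_het markers with expected heterozygosity
#'   \eqn{2p(1-p)} strictly below this are removed (default 0.05).
#' @param biallelic_only drop multi-allelic sites when reading VCF.
#' @return a \code{filter_config} list.
#' @export
filter_config <- function(max_sample_missing = 0.60,
                          max_marker_missing = 0.10,
                          min_expected_het = 0.05,
                          biallelic_only = TRUE) {
  stopifnot(max_sample_missing >= 0, max_sample_missing <= 1,
            max_marker_missing >= 0, max_marker_missing <= 1,
            min_expected_het >= 0, min_expected_het <= 1)
  structure(list(max_sample_missing = max_sample_missing,
                 max_marker_missing = max_marker_missing,
                 min_expected_het = min_expected_het,
                 biallelic_only = isTRUE(biallelic_only)),
            class = "filter_config")
}

#' Major-allele frequency of one marker
#'
#' Frequency of the allele coded +1, from non-missing calls; heterozygotes
#' contribute one copy of each allele.
#' @param v genotype code vector.
#' @return frequency in [0, 1], or NA if all calls missing.
#' @keywords internal
major_allele_freq <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) == 0) return(NA_real_)
  mean(v + 1) / 2
}

#' Filter samples and markers
#'
#' Applies, in order: (1) remove samples whose missing fraction exceeds
#' \code{max_sample_missing}; (2) remove markers whose missing fraction is at
#' least \code{max_marker_missing}; (3) remove markers whose expected
#' heterozygosity \eqn{2p(1-p)} (p = major-allele frequency over non-missing
#' calls) is below \code{min_expected_het}. Retained row/column order is
#' preserved. The operation is idempotent.
#'
#' The three rules are re-applied until nothing more is removed (marker
#' removal can raise a remaining sample's missing fraction and vice versa),
#' so the returned object is a fixed point of the filter.
#'
#' @param G a \code{genotype_matrix}.
#' @param cfg a \code{filter_config}.
#' @return the filtered \code{genotype_matrix}.
#' @export
filter_genotypes <- function(G, cfg = filter_config()) {
  stopifnot(inherits(G, "genotype_matrix"))
  codes <- G$codes
  samples <- G$samples
  map <- G$map
  repeat {
    miss_s <- rowMeans(is.na(codes))
    keep_s <- miss_s <= cfg$max_sample_missing
    codes <- codes[keep_s, , drop = FALSE]
    samples <- samples[keep_s]
    if (nrow(codes) < 2) stop("all data filtered: fewer than 2 samples remain")
    miss_m <- colMeans(is.na(codes))
    keep_m <- miss_m < cfg$max_marker_missing
    p <- apply(codes, 2, major_allele_freq)
    he <- 2 * p * (1 - p)
    keep_m <- keep_m & !is.na(he) & he >= cfg$min_expected_het
    if (!any(keep_m)) stop("all data filtered: no markers remain")
    codes <- codes[, keep_m, drop = FALSE]
    map <- map[keep_m, , drop = FALSE]
    if (all(keep_s) && all(keep_m)) break
  }
  genotype_matrix(codes, map, samples)
}

#' Impute missing genotype calls by per-marker mode
#'
#' Each missing call is replaced by the most frequent code of its marker.
#' Ties are broken deterministically toward 0, then +1, then -1.
#'
#' @param G a filtered \code{genotype_matrix}.
#' @param seed integer; reserved for sampling-based imputers, the mode imputer
#'   is deterministic.
#' @return a complete \code{genotype_matrix}.
#' @export
impute_missing <- function(G, seed = 1L) {
  stopifnot(inherits(G, "genotype_matrix"))
  codes <- G$codes
  na_cols <- which(colSums(is.na(codes)) > 0)
  for (j in na_cols) {
    v <- codes[, j]
    obs <- v[!is.na(v)]
    if (length(obs) == 0)
      stop("marker ", G$map$id[j], " has no observed calls; filter first")
    # tie order 0, +1, -1
    cnt <- c(`0` = sum(obs == 0), `1` = sum(obs == 1), `-1` = sum(obs == -1))
    mode_code <- as.numeric(names(cnt)[which.max(cnt)])
    v[is.na(v)] <- mode_code
    codes[, j] <- v
  }
  G$codes <- codes
  G
}

#' Build hybrid genotypes from homozygous parents
#'
#' Each hybrid's code at a marker is the mean of its two parents' codes:
#' identical homozygous parents give the shared homozygote, opposite
#' homozygotes give a heterozygote (0). Parents must be fully homozygous.
#'
#' @param parents a complete \code{genotype_matrix} of parental lines.
#' @param crosses data.frame with columns \code{hybrid}, \code{parent1},
#'   \code{parent2}.
#' @return a \code{genotype_matrix} of hybrids (marker map inherited).
#' @export
make_hybrids <- function(parents, crosses) {
  stopifnot(inherits(parents, "genotype_matrix"))
  crosses <- as.data.frame(crosses, stringsAsFactors = FALSE)
  if (!all(c("hybrid", "parent1", "parent2") %in% names(crosses)))
    stop("crosses needs columns hybrid, parent1, parent2")
  if (anyDuplicated(crosses$hybrid)) stop("duplicate hybrid ids")
  if (anyNA(parents$codes)) stop("parental genotypes contain missing calls; impute first")
  het <- which(parents$codes == 0, arr.ind = TRUE)
  if (nrow(het) > 0)
    stop("heterozygous parent call: sample ", parents$samples[het[1, 1]],
         " at marker ", parents$map$id[het[1, 2]])
  unknown <- setdiff(c(crosses$parent1, crosses$parent2), parents$samples)
  if (length(unknown) > 0)
    stop("cross table references unknown parent id(s): ",
         paste(unknown, collapse = ", "))
  i1 <- match(crosses$parent1, parents$samples)
  i2 <- match(crosses$parent2, parents$samples)
  codes <- (parents$codes[i1, , drop = FALSE] +
            parents$codes[i2, , drop = FALSE]) / 2
  genotype_matrix(codes, parents$map, samples = as.character(crosses$hybrid))
}

#' Read genotypes from VCF or delimited matrix
#'
#' VCF: biallelic SNPs are encoded from GT fields; the major allele (higher
#' frequency across the file, REF on ties) maps to +1 homozygote. Sites with
#' more than one ALT allele are dropped when \code{biallelic_only}.
#' Matrix format: tab/whitespace-delimited numeric matrix (samples x markers,
#' sample ids in the first column, marker ids as header) plus a 3-column map
#' sidecar (id, chrom, pos) given via \code{map_path}.
#'
#' @param path file path.
#' @param format "vcf" or "matrix".
#' @param map_path marker map path (matrix format only).
#' @param biallelic_only drop multi-allelic VCF sites (default TRUE).
#' @return a \code{genotype_matrix}.
#' @export
read_genotypes <- function(path, format = c("vcf", "matrix"),
                           map_path = NULL, biallelic_only = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") {
    vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                    error = function(e) stop("unparseable VCF: ", conditionMessage(e)))
    fix <- vcfR::getFIX(vcf)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
    keep <- rep(TRUE, nrow(fix))
    if (biallelic_only) keep <- !grepl(",", fix[, "ALT"]) & !is.na(fix[, "ALT"])
    gt <- vcfR::extract.gt(vcf, element = "GT")
    if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                       dimnames = list(rownames(gt), colnames(gt)))
    gt <- gt[keep, , drop = FALSE]
    fix <- fix[keep, , drop = FALSE]
    if (nrow(fix) == 0) stop("no biallelic sites in VCF")
    # allele dosage of ALT from GT strings
    alt_dose <- function(g) {
      if (is.na(g)) return(NA_real_)
      a <- strsplit(g, "[/|]")[[1]]
      if (any(a == ".")) return(NA_real_)
      sum(a == "1")
    }
    d <- apply(gt, c(1, 2), alt_dose)           # markers x samples, ALT dosage 0/1/2
    # orient: +1 homozygous major. p_alt from data; REF major on ties.
    p_alt <- rowMeans(d, na.rm = TRUE) / 2
    codes <- d - 1                               # ALT-dosage coding: -1 REF hom, +1 ALT hom
    flip <- !is.na(p_alt) & p_alt <= 0.5         # REF is major (or tie) -> flip sign
    codes[flip, ] <- -codes[flip, , drop = FALSE]
    ids <- fix[, "ID"]
    ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(ids) | ids == "."]
    map <- data.frame(id = ids, chrom = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]), stringsAsFactors = FALSE)
    genotype_matrix(t(codes), map, samples = colnames(gt))
  } else {
    if (is.null(map_path)) stop("matrix format needs a marker map (map_path)")
    if (!file.exists(map_path)) stop("map file not found: ", map_path)
    tab <- utils::read.table(path, header = TRUE, check.names = FALSE,
                             stringsAsFactors = FALSE)
    samples <- as.character(tab[[1]])
    codes <- as.matrix(tab[, -1, drop = FALSE])
    map <- utils::read.table(map_path, header = TRUE, stringsAsFactors = FALSE)
    names(map)[1:3] <- c("id", "chrom", "pos")
    if (!setequal(colnames(codes), map$id))
      stop("marker with no map entry (or map/matrix id mismatch)")
    codes <- codes[, map$id, drop = FALSE]
    genotype_matrix(codes, map, samples = samples)
  }
}

#' Write a genotype matrix as delimited matrix + map
#'
#' @param G a \code{genotype_matrix}.
#' @param path matrix file path.
#' @param map_path map file path.
#' @export
write_genotypes <- function(G, path, map_path) {
  stopifnot(inherits(G, "genotype_matrix"))
  tab <- data.frame(sample = G$samples, G$codes, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(G$map, map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column phenotype table
#' @param path delimited file: sample id, value (header optional but expected).
#' @return named numeric vector.
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  stats::setNames(as.numeric(tab[[2]]), as.character(tab[[1]]))
}

#' Read a three-column cross table (hybrid, parent1, parent2)
#' @param path delimited file.
#' @return data.frame with columns hybrid, parent1, parent2.
#' @export
read_crosses <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  names(tab)[1:3] <- c("hybrid", "parent1", "parent2")
  tab
}
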