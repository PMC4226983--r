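#' Marker map for a single chromosome
#'
#' Ordered biallelic marker coordinates on one chromosome, in base pairs and
#' in Morgan. Genetic positions are derived from physical positions with a
#' constant conversion factor; the default of 1e-8 Morgan per base pair
#' corresponds to the usual livestock convention that 1 Mb equals 1 cM.
#'
#' @param chrom chromosome label (recycled to one value per marker).
#' @param pos_bp strictly increasing integer positions (1-based).
#' @param morgan_per_bp Morgan per base pair used to derive `pos_morgan`.
#' @param ref,alt allele labels per marker.
#' @return A `marker_map`: a data.frame with columns `chrom`, `pos_bp`,
#'   `pos_morgan`, `ref`, `alt` and attribute `morgan_per_bp`.
#' @export
marker_map <- function(chrom, pos_bp, morgan_per_bp = 1e-8,
                       ref = "A", alt = "B") {
  pos_bp <- as.integer(pos_bp)
  if (length(pos_bp) == 0L) stop("marker map must contain at least one marker")
  if (any(pos_bp <= 0L)) stop("positions must be positive (1-based)")
  if (any(diff(pos_bp) <= 0L)) stop("positions must be strictly increasing")
  if (!is.numeric(morgan_per_bp) || morgan_per_bp < 0)
    stop("morgan_per_bp must be a nonnegative number")
  m <- data.frame(
    chrom = rep_len(as.character(chrom), length(pos_bp)),
    pos_bp = pos_bp,
    pos_morgan = pos_bp * morgan_per_bp,
    ref = rep_len(as.character(ref), length(pos_bp)),
    alt = rep_len(as.character(alt), length(pos_bp)),
    stringsAsFactors = FALSE
  )
  attr(m, "morgan_per_bp") <- morgan_per_bp
  class(m) <- c("marker_map", "data.frame")
  m
}

#' Number of markers in a map or marker-indexed object
#' @param x a `marker_map`, `haplotype_set`, `genotype_matrix` or
#'   `dosage_matrix`.
#' @return integer marker count.
#' @export
n_markers <- function(x) {
  if (inherits(x, "marker_map")) return(nrow(x))
  if (!is.null(x$marker_map)) return(nrow(x$marker_map))
  stop("no marker map attached")
}

same_map <- function(a, b) {
  isTRUE(all.equal(a$pos_bp, b$pos_bp)) &&
    identical(as.character(a$chrom), as.character(b$chrom))
}

subset_map <- function(map, idx) {
  m <- map[idx, , drop = FALSE]
  rownames(m) <- NULL
  attr(m, "morgan_per_bp") <- attr(map, "morgan_per_bp")
  class(m) <- c("marker_map", "data.frame")
  m
}

#' Set of binary haplotypes over a marker map
#'
#' @param alleles H x L matrix with entries in \{0, 1\}.
#' @param map a [marker_map()] with L markers.
#' @param ids haplotype labels (default `hap1..hapH`).
#' @return A `haplotype_set` (list with `alleles`, `haplotype_ids`,
#'   `marker_map`).
#' @export
haplotype_set <- function(alleles, map, ids = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (!inherits(map, "marker_map")) stop("map must be a marker_map")
  if (ncol(alleles) != nrow(map))
    stop("allele matrix has ", ncol(alleles), " columns but map has ",
         nrow(map), " markers")
  if (any(is.na(alleles)) || any(alleles != 0L & alleles != 1L))
    stop("haplotype alleles must be 0 or 1")
  if (is.null(ids)) ids <- sprintf("hap%d", seq_len(nrow(alleles)))
  structure(list(alleles = alleles, haplotype_ids = ids, marker_map = map),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("haplotype_set:", nrow(x$alleles), "haplotypes x",
      ncol(x$alleles), "markers\n")
  invisible(x)
}

#' Diploid genotype matrix
#'
#' Genotypes are counts of the B allele: 0 (AA), 1 (AB), 2 (BB); `NA` marks
#' a masked/untyped marker.
#'
#' @param genotypes N x L matrix with entries in \{0, 1, 2, NA\}.
#' @param map a [marker_map()] with L markers.
#' @param ids individual labels.
#' @param hap_index optional N x 2 matrix of source haplotype row indices
#'   (back-reference into the generating [haplotype_set()]).
#' @return A `genotype_matrix`.
#' @export
genotype_matrix <- function(genotypes, map, ids = NULL, hap_index = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (!inherits(map, "marker_map")) stop("map must be a marker_map")
  if (ncol(genotypes) != nrow(map))
    stop("genotype matrix has ", ncol(genotypes), " columns but map has ",
         nrow(map), " markers")
  ok <- is.na(genotypes) | (genotypes >= 0L & genotypes <= 2L)
  if (!all(ok)) stop("non-missing genotypes must be 0, 1 or 2")
  if (is.null(ids)) ids <- sprintf("ind%d", seq_len(nrow(genotypes)))
  if (!is.null(hap_index)) {
    hap_index <- as.matrix(hap_index)
    stopifnot(nrow(hap_index) == nrow(genotypes), ncol(hap_index) == 2L)
  }
  structure(list(genotypes = genotypes, individual_ids = ids,
                 marker_map = map, hap_index = hap_index),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$genotypes), "individuals x",
      ncol(x$genotypes), "markers;",
      sum(is.na(x$genotypes)), "missing cells\n")
  invisible(x)
}

#' Imputed B-allele dosages with posterior genotype probabilities
#'
#' The dosage at every cell is the posterior mean B-allele count
#' `0*P(AA) + 1*P(AB) + 2*P(BB)`, a real value in \[0, 2\].
#'
#' @param probs N x L x 3 array of posterior P(AA), P(AB), P(BB); each triple
#'   must sum to 1 within 1e-9.
#' @param map a [marker_map()] with L markers.
#' @param ids individual labels.
#' @return A `dosage_matrix` (list with `dosages`, `genotype_probs`,
#'   `individual_ids`, `marker_map`).
#' @export
dosage_matrix <- function(probs, map, ids = NULL) {
  stopifnot(length(dim(probs)) == 3L, dim(probs)[3] == 3L)
  if (!inherits(map, "marker_map")) stop("map must be a marker_map")
  if (dim(probs)[2] != nrow(map))
    stop("probability array and marker map disagree on marker count")
  if (any(probs < -1e-12)) stop("genotype probabilities must be nonnegative")
  tot <- probs[, , 1] + probs[, , 2] + probs[, , 3]
  if (any(abs(tot - 1) > 1e-9))
    stop("genotype probabilities must sum to 1 (max deviation ",
         format(max(abs(tot - 1))), ")")
  dos <- probs[, , 2] + 2 * probs[, , 3]
  dos <- matrix(dos, nrow = dim(probs)[1])
  if (is.null(ids)) ids <- sprintf("ind%d", seq_len(nrow(dos)))
  structure(list(dosages = dos, genotype_probs = probs,
                 individual_ids = ids, marker_map = map),
            class = "dosage_matrix")
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat("dosage_matrix:", nrow(x$dosages), "individuals x",
      ncol(x$dosages), "markers\n")
  invisible(x)
}

#' Minor allele frequency per marker
#'
#' For a `haplotype_set` the allele frequency is the mean allele over
#' haplotypes; for a `genotype_matrix` it is half the mean genotype over
#' individuals (missing cells excluded). The minor allele frequency is
#' `min(f, 1 - f)` and lies in \[0, 0.5\].
#'
#' @param x a `haplotype_set` or `genotype_matrix`.
#' @return numeric vector of per-marker MAF.
#' @export
maf <- function(x) UseMethod("maf")

#' @export
maf.haplotype_set <- function(x) {
  f <- colMeans(x$alleles)
  pmin(f, 1 - f)
}

#' @export
maf.genotype_matrix <- function(x) {
  f <- colMeans(x$genotypes, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}
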