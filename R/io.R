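vcf_meta <- function(with_dosage) {
  m <- c("##fileformat=VCFv4.2",
         "##source=seqimp",
         "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  if (with_dosage) {
    m <- c(m,
      "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Estimated B-allele dosage\">",
      "##FORMAT=<ID=GP,Number=3,Type=Float,Description=\"Posterior genotype probabilities P(AA),P(AB),P(BB)\">")
  }
  m
}

vcf_fix <- function(map) {
  cbind(CHROM = as.character(map$chrom),
        POS = as.character(map$pos_bp),
        ID = ".",
        REF = map$ref,
        ALT = map$alt,
        QUAL = ".",
        FILTER = "PASS",
        INFO = ".")
}

gt_string <- function(g) {
  out <- rep("./.", length(g))
  out[!is.na(g) & g == 0L] <- "0/0"
  out[!is.na(g) & g == 1L] <- "0/1"
  out[!is.na(g) & g == 2L] <- "1/1"
  out
}

#' Write genotypes or dosages to VCF
#'
#' Genotype matrices are written with a `GT` field; dosage matrices
#' additionally carry `DS` (B-allele dosage, 4 decimals) and `GP`
#' (posterior genotype probabilities, 6 decimals), with `GT` holding the
#' most likely genotype. Positions are 1-based; records are biallelic.
#' The file is gzip-compressed (conventional `.vcf.gz`).
#'
#' @param x a [genotype_matrix()] or [dosage_matrix()].
#' @param file output path (a `.gz` suffix is appended if absent).
#' @return the path written, invisibly.
#' @export
write_vcf <- function(x, file) {
  if (!grepl("\\.gz$", file)) file <- paste0(file, ".gz")
  map <- x$marker_map
  if (inherits(x, "genotype_matrix")) {
    body <- apply(x$genotypes, 1L, gt_string)  # L x N
    format <- "GT"
  } else if (inherits(x, "dosage_matrix")) {
    hc <- hard_call(x)
    N <- nrow(x$dosages)
    L <- ncol(x$dosages)
    body <- matrix("", L, N)
    for (i in seq_len(N)) {
      gp <- sprintf("%.6f,%.6f,%.6f", x$genotype_probs[i, , 1L],
                    x$genotype_probs[i, , 2L], x$genotype_probs[i, , 3L])
      body[, i] <- sprintf("%s:%.4f:%s", gt_string(hc$genotypes[i, ]),
                           x$dosages[i, ], gp)
    }
    format <- "GT:DS:GP"
  } else stop("x must be a genotype_matrix or dosage_matrix")
  gt <- cbind(FORMAT = format, body)
  colnames(gt) <- c("FORMAT", x$individual_ids)
  v <- methods::new("vcfR", meta = vcf_meta(format != "GT"),
                    fix = vcf_fix(map), gt = gt)
  vcfR::write.vcf(v, file)
  invisible(file)
}

#' Read a biallelic single-chromosome VCF
#'
#' Returns a [genotype_matrix()] when only `GT` is present, or a
#' [dosage_matrix()] when `DS`/`GP` fields are found (posterior
#' probabilities are renormalised against rounding, and dosages recomputed
#' from them). Multi-allelic records and records without a position are
#' rejected with the offending record named.
#'
#' @param file path to a `.vcf` or `.vcf.gz` file.
#' @param morgan_per_bp conversion used to rebuild genetic positions.
#' @return A [genotype_matrix()] or [dosage_matrix()].
#' @export
read_vcf <- function(file, morgan_per_bp = 1e-8) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (any(is.na(fix[, "POS"])))
    stop("record without position at row ",
         which(is.na(fix[, "POS"]))[1L])
  multi <- grepl(",", fix[, "ALT"]) | is.na(fix[, "ALT"])
  if (any(multi))
    stop("multi-allelic record at ", fix[which(multi)[1L], "CHROM"], ":",
         fix[which(multi)[1L], "POS"])
  map <- marker_map(fix[, "CHROM"], as.integer(fix[, "POS"]),
                    morgan_per_bp = morgan_per_bp,
                    ref = fix[, "REF"], alt = fix[, "ALT"])
  gt_chr <- vcfR::extract.gt(v, element = "GT")
  code <- function(s) {
    out <- rep(NA_integer_, length(s))
    out[s %in% c("0/0", "0|0")] <- 0L
    out[s %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    out[s %in% c("1/1", "1|1")] <- 2L
    out
  }
  geno <- t(apply(gt_chr, 2L, code))  # N x L
  ids <- colnames(gt_chr)
  has_gp <- grepl("GP", v@gt[1L, "FORMAT"], fixed = TRUE)
  if (!has_gp)
    return(genotype_matrix(geno, map, ids = ids))
  gp_chr <- vcfR::extract.gt(v, element = "GP")
  N <- ncol(gp_chr)
  L <- nrow(gp_chr)
  probs <- array(NA_real_, c(N, L, 3L))
  for (i in seq_len(N)) {
    m <- matrix(as.numeric(unlist(strsplit(gp_chr[, i], ",", fixed = TRUE))),
                ncol = 3L, byrow = TRUE)
    m <- m / rowSums(m)  # renormalise against fixed-precision rounding
    probs[i, , ] <- m
  }
  dosage_matrix(probs, map, ids = ids)
}

#' Write a panel definition to TSV
#'
#' Columns `chrom`, `pos_bp` (1-based) and `name`; round-trips exactly via
#' [read_panel_tsv()].
#'
#' @param panel a [panel_definition()].
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_panel_tsv <- function(panel, file) {
  stopifnot(inherits(panel, "panel_definition"))
  out <- data.frame(chrom = panel$chrom, pos_bp = panel$positions_bp,
                    name = panel$name)
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a panel definition from TSV
#'
#' @param file path written by [write_panel_tsv()].
#' @param map the [marker_map()] the panel refers to; every panel position
#'   must be present in the map.
#' @return A [panel_definition()].
#' @export
read_panel_tsv <- function(file, map) {
  d <- utils::read.table(file, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  idx <- match(d$pos_bp, map$pos_bp)
  if (any(is.na(idx)))
    stop("panel position ", d$pos_bp[which(is.na(idx))[1L]],
         " not found in the marker map")
  panel_definition(d$name[1L], sort(idx), map)
}

#' Write a tabular result to TSV
#' @param df a data.frame.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_results_tsv <- function(df, file) {
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a tabular result written by [write_results_tsv()]
#' @param file input path.
#' @return a data.frame.
#' @export
read_results_tsv <- function(file) {
  utils::read.table(file, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
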