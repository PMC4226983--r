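#' Remove markers that are fixed within any validation group
#'
#' A correlation between observed and imputed genotypes is only defined
#' when both vary, so a marker is kept if and only if, within every
#' validation group, both the observed genotypes and the imputed dosages
#' are non-constant. A marker constant in even one group is removed.
#'
#' @param observed N x L matrix of observed genotypes.
#' @param dosages N x L matrix of imputed dosages, aligned with `observed`.
#' @param groups list of validation groups, each an index vector into rows.
#' @return logical vector of length L; `TRUE` marks a kept marker.
#' @export
filter_informative <- function(observed, dosages, groups) {
  observed <- as.matrix(observed)
  dosages <- as.matrix(dosages)
  stopifnot(identical(dim(observed), dim(dosages)))
  keep <- rep(TRUE, ncol(observed))
  for (g in groups) {
    if (length(g) == 0L) stop("empty validation group")
    o <- observed[g, , drop = FALSE]
    d <- dosages[g, , drop = FALSE]
    const_o <- colSums(o != o[rep(1L, nrow(o)), , drop = FALSE]) == 0L
    const_d <- colSums(d != d[rep(1L, nrow(d)), , drop = FALSE]) == 0L
    keep <- keep & !const_o & !const_d
  }
  keep
}

col_cor <- function(x, y) {
  # columnwise Pearson correlation of two aligned matrices
  n <- nrow(x)
  cx <- sweep(x, 2L, colMeans(x))
  cy <- sweep(y, 2L, colMeans(y))
  num <- colSums(cx * cy)
  den <- sqrt(colSums(cx^2) * colSums(cy^2))
  num / den
}

#' Per-SNP imputation accuracy
#'
#' Pearson correlation between observed genotypes (0/1/2) and imputed
#' B-allele dosages, computed per marker and pooled across all validation
#' individuals of the scenario. Accuracy ranges from -1 (opposite genotype
#' imputed) through 0 (random imputation) to +1 (correct genotype).
#'
#' @param observed N x L matrix (or single column) of observed genotypes.
#' @param dosages aligned matrix (or column) of dosages in \[0, 2\].
#' @return numeric vector of per-marker correlations.
#' @export
accuracy_per_snp <- function(observed, dosages) {
  observed <- as.matrix(observed)
  dosages <- as.matrix(dosages)
  stopifnot(identical(dim(observed), dim(dosages)))
  r <- col_cor(observed, dosages)
  if (any(!is.finite(r)))
    stop("constant column reached accuracy_per_snp; ",
         "apply filter_informative first")
  r
}

#' Per-individual imputation accuracy
#'
#' Pearson correlation between an individual's observed genotypes and
#' imputed dosages across markers. `mode = "raw"` is the plain correlation;
#' `"centered"` subtracts the per-marker mean observed genotype from both
#' vectors before correlating (removing the allele-frequency contribution);
#' `"standardized"` additionally divides both by the per-marker observed
#' genotype standard deviation. Centering statistics default to the
#' observed matrix itself (the validation individuals of the fold).
#'
#' @param observed N x L observed genotype matrix (validation individuals).
#' @param dosages aligned dosage matrix.
#' @param mode `"raw"`, `"centered"` or `"standardized"`.
#' @param marker_means,marker_sds optional per-marker centering statistics;
#'   computed from `observed` when omitted.
#' @return numeric vector of per-individual correlations; `NA` where the
#'   individual's vectors are constant (undefined correlation).
#' @export
accuracy_per_individual <- function(observed, dosages,
                                    mode = c("raw", "centered",
                                             "standardized"),
                                    marker_means = NULL, marker_sds = NULL) {
  mode <- match.arg(mode)
  observed <- as.matrix(observed)
  dosages <- as.matrix(dosages)
  stopifnot(identical(dim(observed), dim(dosages)))
  if (ncol(observed) < 2L) stop("need at least 2 markers per individual")
  o <- observed
  d <- dosages
  if (mode != "raw") {
    if (is.null(marker_means)) marker_means <- colMeans(observed)
    o <- sweep(o, 2L, marker_means)
    d <- sweep(d, 2L, marker_means)
    if (mode == "standardized") {
      if (is.null(marker_sds)) marker_sds <- apply(observed, 2L, stats::sd)
      if (any(marker_sds == 0))
        stop("zero per-marker standard deviation; filter fixed markers first")
      o <- sweep(o, 2L, marker_sds, "/")
      d <- sweep(d, 2L, marker_sds, "/")
    }
  }
  r <- col_cor(t(o), t(d))
  r[!is.finite(r)] <- NA_real_
  r
}

#' Distance and MAF covariates of imputed markers
#'
#' For every non-panel marker: the nearest panel SNP by physical distance
#' (ties broken toward the lower position), that distance in bp and Morgan,
#' the marker's own MAF, and the five nearest panel SNPs with their
#' absolute MAF differences (for the best-of-five neighbor selection).
#'
#' @param map a [marker_map()].
#' @param panel a nonempty [panel_definition()].
#' @param genos a [genotype_matrix()] over the full individual set, used
#'   for MAF.
#' @param n_neighbors neighbors retained per marker (default 5).
#' @return A `marker_stats` list: data.frame `stats` (columns `marker`,
#'   `pos_bp`, `maf`, `nearest_panel_pos`, `distance_bp`,
#'   `distance_morgan`, `dmaf_nearest`) plus matrices `neighbor_pos`,
#'   `neighbor_morgan` (distances), `neighbor_dmaf` (one row per marker,
#'   NA-padded when the panel has fewer than `n_neighbors` markers).
#' @export
compute_marker_stats <- function(map, panel, genos, n_neighbors = 5L) {
  stopifnot(inherits(map, "marker_map"), inherits(panel, "panel_definition"))
  if (length(panel$marker_indices) == 0L) stop("panel is empty")
  fr <- maf(genos)
  pidx <- panel$marker_indices
  ppos <- map$pos_bp[pidx]
  pmorg <- map$pos_morgan[pidx]
  pmaf <- fr[pidx]
  targets <- setdiff(seq_len(nrow(map)), pidx)
  M <- length(targets)
  k <- min(n_neighbors, length(pidx))
  nb_pos <- nb_morg <- nb_dmaf <- matrix(NA_real_, M, n_neighbors)
  nearest_pos <- dist_bp <- dist_morg <- dmaf1 <- numeric(M)
  ins <- findInterval(map$pos_bp[targets], ppos)
  for (j in seq_len(M)) {
    t_bp <- map$pos_bp[targets[j]]
    lo <- max(1L, ins[j] - n_neighbors + 1L)
    hi <- min(length(ppos), ins[j] + n_neighbors)
    cand <- lo:hi
    d <- abs(ppos[cand] - t_bp)
    ord <- order(d, ppos[cand])  # tie -> lower position
    pick <- cand[ord[seq_len(k)]]
    nb_pos[j, seq_len(k)] <- ppos[pick]
    nb_morg[j, seq_len(k)] <- abs(pmorg[pick] - map$pos_morgan[targets[j]])
    nb_dmaf[j, seq_len(k)] <- abs(pmaf[pick] - fr[targets[j]])
    nearest_pos[j] <- ppos[pick[1L]]
    dist_bp[j] <- abs(ppos[pick[1L]] - t_bp)
    dist_morg[j] <- nb_morg[j, 1L]
    dmaf1[j] <- nb_dmaf[j, 1L]
  }
  stats <- data.frame(
    marker = targets,
    pos_bp = map$pos_bp[targets],
    maf = fr[targets],
    nearest_panel_pos = nearest_pos,
    distance_bp = dist_bp,
    distance_morgan = dist_morg,
    dmaf_nearest = dmaf1
  )
  structure(list(stats = stats, neighbor_pos = nb_pos,
                 neighbor_morgan = nb_morg, neighbor_dmaf = nb_dmaf,
                 panel = panel$name),
            class = "marker_stats")
}

#' Bin markers by a covariate and summarise reliability
#'
#' Markers are sorted by the covariate (stable; ties by position), sliced
#' into consecutive bins of `bin_size` (the last bin may be smaller), and
#' each bin reports the mean covariate and the mean reliability, i.e. the
#' mean of r-squared over the bin's markers.
#'
#' @param values per-marker accuracy r (will be squared for reliability).
#' @param covariate aligned per-marker covariate (distance, MAF, ...).
#' @param bin_size markers per bin (default 1000).
#' @param positions optional tie-break key (marker positions).
#' @return data.frame with `bin_index`, `covariate_mean`,
#'   `reliability_mean`, `n_markers`.
#' @export
bin_by_covariate <- function(values, covariate, bin_size = 1000L,
                             positions = seq_along(values)) {
  stopifnot(length(values) == length(covariate))
  if (length(values) == 0L)
    return(data.frame(bin_index = integer(0), covariate_mean = numeric(0),
                      reliability_mean = numeric(0), n_markers = integer(0)))
  ord <- order(covariate, positions)
  v <- values[ord]
  cv <- covariate[ord]
  bin <- (seq_along(v) - 1L) %/% as.integer(bin_size) + 1L
  data.frame(
    bin_index = unique(bin),
    covariate_mean = as.numeric(tapply(cv, bin, mean)),
    reliability_mean = as.numeric(tapply(v^2, bin, mean)),
    n_markers = as.integer(table(bin))
  )
}
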