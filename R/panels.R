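#' Panel definition
#'
#' An ordered subset of a marker map playing the role of a SNP array tier
#' (e.g. a 50K-like or HD-like chip nested inside the sequence marker set).
#'
#' @param name panel label, e.g. `"seq"`, `"hd"`, `"lo"`.
#' @param marker_indices strictly increasing 1-based indices into the map.
#' @param map the [marker_map()] the indices refer to.
#' @param ascertainment optional record of the selection rule
#'   (`maf_min`, `target_count`).
#' @return A `panel_definition`.
#' @export
panel_definition <- function(name, marker_indices, map,
                             ascertainment = NULL) {
  marker_indices <- as.integer(marker_indices)
  if (length(marker_indices) > 0L) {
    if (any(diff(marker_indices) <= 0L))
      stop("panel marker indices must be strictly increasing")
    if (min(marker_indices) < 1L || max(marker_indices) > nrow(map))
      stop("panel marker indices out of range for the map")
  }
  structure(list(name = as.character(name),
                 marker_indices = marker_indices,
                 positions_bp = map$pos_bp[marker_indices],
                 chrom = unique(as.character(map$chrom)),
                 ascertainment = ascertainment),
            class = "panel_definition")
}

#' @export
print.panel_definition <- function(x, ...) {
  cat("panel", shQuote(x$name), "with", length(x$marker_indices),
      "markers\n")
  invisible(x)
}

#' Build an ascertained marker panel
#'
#' Emulates SNP-array ascertainment: markers are non-random, biased toward
#' high minor allele frequency, and approximately evenly spaced. The
#' chromosome is walked in `target_count` equal-width windows and the
#' highest-MAF eligible marker (MAF >= `maf_min`) in each window is picked;
#' empty windows are then backfilled by repeatedly splitting the largest
#' remaining inter-marker gap with its highest-MAF eligible marker.
#'
#' @param map a [marker_map()].
#' @param genos a [genotype_matrix()] used to compute MAF.
#' @param maf_min minimum MAF for a marker to be eligible.
#' @param target_count number of markers to select.
#' @param name panel label.
#' @param within optional parent `panel_definition`: restrict candidates to
#'   the parent's markers, guaranteeing nestedness.
#' @return A [panel_definition()] with exactly `target_count` markers.
#' @export
build_panel <- function(map, genos, maf_min, target_count, name = "panel",
                        within = NULL) {
  stopifnot(inherits(map, "marker_map"))
  target_count <- as.integer(target_count)
  fr <- maf(genos)
  eligible <- which(fr >= maf_min)
  if (!is.null(within)) {
    stopifnot(inherits(within, "panel_definition"))
    eligible <- intersect(eligible, within$marker_indices)
  }
  if (length(eligible) < target_count)
    stop("only ", length(eligible), " markers have MAF >= ", maf_min,
         " but ", target_count, " were requested (short by ",
         target_count - length(eligible), ")")
  pos <- map$pos_bp
  lo <- min(pos[eligible])
  hi <- max(pos[eligible])
  width <- (hi - lo + 1) / target_count
  win <- pmin(floor((pos[eligible] - lo) / width) + 1L, target_count)
  chosen <- integer(0)
  for (w in split(eligible, win)) {
    chosen <- c(chosen, w[which.max(fr[w])])  # ties: first (lowest position)
  }
  # backfill empty windows from the largest remaining gaps
  while (length(chosen) < target_count) {
    sel <- sort(chosen)
    bounds <- c(lo - 1L, pos[sel], hi + 1L)
    rem <- setdiff(eligible, chosen)
    gap_of <- findInterval(pos[rem], bounds)  # gap index per remaining marker
    gap_len <- diff(bounds)
    open <- sort(unique(gap_of))
    g <- open[which.max(gap_len[open])]
    cand <- rem[gap_of == g]
    chosen <- c(chosen, cand[which.max(fr[cand])])
  }
  panel_definition(name, sort(chosen), map,
                   ascertainment = list(maf_min = maf_min,
                                        target_count = target_count))
}

#' Mask genotypes down to a panel
#'
#' Genotypes at panel markers are kept unchanged; every other marker is set
#' to missing. Dimensions and the marker map are preserved, mirroring how
#' sequence genotypes of validation individuals are reduced to an array.
#'
#' @param genos a [genotype_matrix()].
#' @param panel a [panel_definition()] over the same map.
#' @return A [genotype_matrix()] with non-panel markers missing.
#' @export
mask_to_panel <- function(genos, panel) {
  stopifnot(inherits(genos, "genotype_matrix"),
            inherits(panel, "panel_definition"))
  L <- ncol(genos$genotypes)
  if (length(panel$marker_indices) > 0L && max(panel$marker_indices) > L)
    stop("panel indices exceed genotype matrix markers")
  g <- genos$genotypes
  drop <- setdiff(seq_len(L), panel$marker_indices)
  g[, drop] <- NA_integer_
  genotype_matrix(g, genos$marker_map, ids = genos$individual_ids,
                  hap_index = genos$hap_index)
}

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a count relative to a total, reported to 2 decimals
#'
#' The rounding rule is half-up (so 2.325 reports as 2.33), matching how
#' panel sizes are conventionally reported relative to the sequence marker
#' count.
#'
#' @param count marker count in the subset.
#' @param total marker count in the reference tier.
#' @return percentage rounded half-up to 2 decimals.
#' @export
overlap_percentage <- function(count, total) {
  if (any(total <= 0)) stop("total must be positive")
  round_half_up(100 * count / total, 2)
}

#' Overlap bookkeeping between marker panels
#'
#' Pairwise intersection counts between panels sharing one marker map, and
#' the percentage of each panel relative to the sequence tier (taken as the
#' largest panel unless one is named `"seq"`).
#'
#' @param panels a named list of [panel_definition()]s on the same map.
#' @return list with `sizes`, `pairwise` (count matrix) and `pct_of_seq`
#'   (2-decimal percentages relative to the sequence tier).
#' @export
panel_overlap_report <- function(panels) {
  stopifnot(is.list(panels), length(panels) >= 1L)
  nm <- vapply(panels, function(p) p$name, character(1))
  names(panels) <- nm
  chroms <- unique(unlist(lapply(panels, function(p) p$chrom)))
  if (length(chroms) > 1L)
    stop("panels reference different chromosomes: ",
         paste(chroms, collapse = ", "))
  sizes <- vapply(panels, function(p) length(p$marker_indices), integer(1))
  k <- length(panels)
  pw <- matrix(0L, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) for (j in seq_len(k))
    pw[i, j] <- length(intersect(panels[[i]]$marker_indices,
                                 panels[[j]]$marker_indices))
  seq_name <- if ("seq" %in% nm) "seq" else nm[which.max(sizes)]
  total <- sizes[[seq_name]]
  pct <- overlap_percentage(sizes, total)
  list(sizes = sizes, pairwise = pw, seq_panel = seq_name,
       pct_of_seq = pct)
}
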