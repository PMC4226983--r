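#' Parameters for per-SNP reliability prediction
#'
#' @param Ne effective population size used in the LD-decay term. The
#'   default 1000 reflects that LD at the very short distances relevant to
#'   imputation is governed by historical rather than current effective
#'   size; pass the simulated population size when predicting on simulated
#'   data.
#' @param dmaf_variant which parse of the MAF-difference bound to use:
#'   `"ratio_linear"` gives `(1 - 2*dmaf) / (1 + 2*dmaf)` (reaches 0 at
#'   dmaf = 0.5) and `"ratio_squared"` gives `1 - 4*dmaf^2 / (dmaf + 1)`.
#' @return A `reliability_params` list.
#' @export
reliability_params <- function(Ne = 1000,
                               dmaf_variant = c("ratio_linear",
                                                "ratio_squared")) {
  if (!(Ne > 0)) stop("Ne must be positive")
  structure(list(Ne = as.double(Ne),
                 dmaf_variant = match.arg(dmaf_variant)),
            class = "reliability_params")
}

#' LD decay with genetic distance
#'
#' Expected r-squared between two loci at genetic distance `c` Morgan in a
#' population of effective size `Ne`: `1 / (4 * Ne * c + 1)`. Equals 1 at
#' zero distance and decreases in both arguments.
#'
#' @param Ne effective population size (> 0).
#' @param c genetic distance in Morgan (>= 0), vectorised.
#' @return expected r-squared in (0, 1].
#' @export
r2_dist <- function(Ne, c) {
  if (!(all(Ne > 0))) stop("Ne must be positive")
  bad <- !is.na(c) & c < 0
  if (any(bad)) stop("genetic distance must be nonnegative")
  1 / (4 * Ne * c + 1)
}

#' Upper limit of LD from a difference in minor allele frequency
#'
#' Two loci that differ in MAF cannot be in complete LD; this bound
#' decreases from 1 (equal MAFs) as the absolute MAF difference grows. The
#' source formula typesets ambiguously, so both parses are provided:
#' `ratio_linear` = `(1 - 2*dmaf) / (1 + 2*dmaf)` (the default; reaches 0
#' at the maximal difference 0.5) and `ratio_squared` =
#' `1 - 4*dmaf^2 / (dmaf + 1)`.
#'
#' @param dmaf absolute MAF difference in \[0, 0.5\], vectorised.
#' @param variant `"ratio_linear"` or `"ratio_squared"`.
#' @return bound on r-squared in \[0, 1\].
#' @export
r2_dmaf <- function(dmaf, variant = c("ratio_linear", "ratio_squared")) {
  variant <- match.arg(variant)
  bad <- !is.na(dmaf) & (dmaf < 0 | dmaf > 0.5)
  if (any(bad)) stop("dmaf must lie in [0, 0.5]")
  switch(variant,
    ratio_linear = (1 - 2 * dmaf) / (1 + 2 * dmaf),
    ratio_squared = 1 - 4 * dmaf^2 / (dmaf + 1)
  )
}

#' Exact maximal r-squared between two biallelic loci
#'
#' The largest squared correlation attainable between two binary variables
#' with given minor allele frequencies, maximised over all joint
#' distributions with those margins. With minor frequencies p and q the
#' disequilibrium D is bounded by `min(p*(1-q), q*(1-p))` in coupling phase
#' and `min(p*q, (1-p)*(1-q))` in repulsion phase, and
#' `r2 = D^2 / (p*(1-p)*q*(1-q))`; the maximum over the two phases is
#' returned. Symmetric in its arguments.
#'
#' @param maf_a,maf_b minor allele frequencies in (0, 0.5\], vectorised.
#' @return maximal r-squared in (0, 1].
#' @export
max_r2_exact <- function(maf_a, maf_b) {
  if (any(maf_a <= 0) || any(maf_b <= 0))
    stop("a monomorphic locus (MAF 0) has no defined correlation")
  if (any(maf_a > 0.5) || any(maf_b > 0.5))
    stop("minor allele frequencies cannot exceed 0.5")
  p <- maf_a
  q <- maf_b
  d_coup <- pmin(p * (1 - q), q * (1 - p))
  d_rep <- pmin(p * q, (1 - p) * (1 - q))
  pmax(d_coup^2, d_rep^2) / (p * (1 - p) * q * (1 - q))
}

#' Construct a Michaelis-Menten reliability curve
#'
#' `mm_fit` objects hold the asymptote `Vmax` and half-saturation point
#' `Km` of the empirical reliability-vs-MAF curve
#' `r2 = Vmax * MAF / (Km + MAF)`; use this constructor to evaluate the
#' curve at externally given parameter values (see [mm_value()]), or
#' obtain a fitted object from [fit_michaelis_menten()].
#'
#' @param Vmax upper limit of the reliability curve.
#' @param Km MAF at which the curve reaches `Vmax / 2`.
#' @param se_Vmax,se_Km optional standard errors.
#' @param n_bins number of bins behind a fit (0 for a constructed curve).
#' @return An `mm_fit` list.
#' @export
mm_fit <- function(Vmax, Km, se_Vmax = NA_real_, se_Km = NA_real_,
                   n_bins = 0L) {
  if (!(Vmax > 0)) stop("Vmax must be positive")
  if (!(Km > 0)) stop("Km must be positive")
  if (Vmax > 1.2)
    warning("Vmax = ", format(Vmax), " exceeds the plausible range (0, 1.2]")
  if (Km >= 0.5)
    warning("Km = ", format(Km), " is at or beyond the maximal MAF 0.5")
  structure(list(Vmax = as.double(Vmax), Km = as.double(Km),
                 se_Vmax = as.double(se_Vmax), se_Km = as.double(se_Km),
                 n_bins = as.integer(n_bins)),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten reliability curve: Vmax = %.4g (SE %.2g), Km = %.4g (SE %.2g), %d bins\n",
              x$Vmax, x$se_Vmax, x$Km, x$se_Km, x$n_bins))
  invisible(x)
}

#' Fit a Michaelis-Menten curve to binned reliabilities
#'
#' Nonlinear least squares of `reliability = Vmax * maf / (Km + maf)` on
#' bin summaries (mean MAF, mean r-squared per bin), as produced by
#' [bin_by_covariate()] over MAF. Starting values are `Vmax` = maximum
#' observed reliability and `Km` = the bin MAF nearest half that value.
#'
#' @param bins data.frame with columns `covariate_mean` (MAF) and
#'   `reliability_mean`, or two plain vectors via `maf`/`reliability`.
#' @param tol convergence tolerance on the parameters (default 1e-10).
#' @return An [mm_fit()] with estimates and asymptotic standard errors.
#' @export
fit_michaelis_menten <- function(bins, tol = 1e-10) {
  x <- bins$covariate_mean
  y <- bins$reliability_mean
  if (length(x) < 3L) stop("need at least 3 bins spanning the MAF range")
  if (stats::var(y) == 0)
    stop("reliability is flat across bins; Michaelis-Menten fit is degenerate")
  v0 <- max(y)
  k0 <- x[which.min(abs(y - v0 / 2))]
  if (k0 <= 0) k0 <- max(min(x[x > 0], na.rm = TRUE), 1e-4)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ Vmax * x / (Km + x),
                      start = list(Vmax = v0, Km = k0),
                      control = minpack.lm::nls.lm.control(
                        ftol = tol, ptol = tol, maxiter = 500)),
    error = function(e) stop("Michaelis-Menten fit failed to converge: ",
                             conditionMessage(e))
  )
  est <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) c(NA_real_, NA_real_))
  mm_fit(est[["Vmax"]], est[["Km"]], se[[1L]], se[[2L]],
         n_bins = length(x))
}

#' Evaluate a Michaelis-Menten reliability curve
#'
#' `Vmax * maf / (Km + maf)`; by construction the value at `maf = Km` is
#' exactly `Vmax / 2`. Values are returned unrounded; round only at
#' reporting time.
#'
#' @param fit an [mm_fit()].
#' @param maf minor allele frequency in \[0, 0.5\], vectorised.
#' @return predicted reliability.
#' @export
mm_value <- function(fit, maf) {
  stopifnot(inherits(fit, "mm_fit"))
  if (any(maf < 0 | maf > 0.5)) stop("maf must lie in [0, 0.5]")
  fit$Vmax * maf / (fit$Km + maf)
}

#' Best copying neighbor among the nearest panel SNPs
#'
#' The nearest panel SNP is not necessarily the one in highest LD with an
#' imputed SNP, so `r2_dist * r2_dmaf` is evaluated for the nearest
#' candidates and the neighbor with the highest product is selected. Ties
#' go to the smaller genetic distance, then the lower position.
#'
#' @param c_morgan genetic distances of candidate neighbors (Morgan).
#' @param dmaf absolute MAF differences of the candidates.
#' @param params a [reliability_params()].
#' @param positions optional candidate positions for the final tie-break.
#' @return list with `index` (chosen candidate), `product`
#'   (`r2_dist * r2_dmaf`), `r2_dist` and `r2_dmaf` of the chosen neighbor.
#' @export
select_best_neighbor <- function(c_morgan, dmaf, params = reliability_params(),
                                 positions = seq_along(c_morgan)) {
  ok <- which(!is.na(c_morgan) & !is.na(dmaf))
  if (length(ok) == 0L) stop("no panel SNP neighbors available")
  rd <- r2_dist(params$Ne, c_morgan[ok])
  rm_ <- r2_dmaf(dmaf[ok], params$dmaf_variant)
  prod <- rd * rm_
  best <- ok[order(-prod, c_morgan[ok], positions[ok])][1L]
  sel <- match(best, ok)
  list(index = best, product = prod[sel], r2_dist = rd[sel],
       r2_dmaf = rm_[sel])
}

#' Predict per-SNP imputation reliability
#'
#' Multiplies the three components: the best-of-neighbors LD product
#' `r2_dist * r2_dmaf` (see [select_best_neighbor()]) and the
#' Michaelis-Menten term at the marker's own MAF:
#' `r2_total = r2_dist * r2_dmaf * r2_maf`.
#'
#' @param marker_stats a [compute_marker_stats()] result.
#' @param fit an [mm_fit()].
#' @param params a [reliability_params()].
#' @return data.frame with one row per non-panel marker: `marker`,
#'   `pos_bp`, `maf`, `chosen_neighbor`, `chosen_neighbor_pos`, `c_morgan`,
#'   `dmaf`, `r2_dist`, `r2_dmaf`, `r2_maf`, `r2_total`.
#' @export
predict_reliability <- function(marker_stats, fit,
                                params = reliability_params()) {
  stopifnot(inherits(marker_stats, "marker_stats"), inherits(fit, "mm_fit"))
  st <- marker_stats$stats
  M <- nrow(st)
  cm <- marker_stats$neighbor_morgan
  dm <- marker_stats$neighbor_dmaf
  np <- marker_stats$neighbor_pos
  rd_all <- r2_dist(params$Ne, cm)
  rm_all <- r2_dmaf(dm, params$dmaf_variant)
  prod_all <- rd_all * rm_all
  chosen <- integer(M)
  for (j in seq_len(M)) {
    p <- prod_all[j, ]
    ok <- which(!is.na(p))
    chosen[j] <- ok[order(-p[ok], cm[j, ok], np[j, ok])][1L]
  }
  pick <- cbind(seq_len(M), chosen)
  r2d <- rd_all[pick]
  r2m <- rm_all[pick]
  r2f <- mm_value(fit, st$maf)
  data.frame(
    marker = st$marker,
    pos_bp = st$pos_bp,
    maf = st$maf,
    chosen_neighbor = chosen,
    chosen_neighbor_pos = np[pick],
    c_morgan = cm[pick],
    dmaf = dm[pick],
    r2_dist = r2d,
    r2_dmaf = r2m,
    r2_maf = r2f,
    r2_total = r2d * r2m * r2f
  )
}
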