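#' Parameters of the haplotype-copying imputation model
#'
#' @param recombination_scale positive scalar controlling the template
#'   switch rate per Morgan (an effective-size-like quantity; the switch
#'   probability over genetic distance d is `1 - exp(-scale * d)`).
#' @param error_rate per-allele probability that an observed allele
#'   mismatches the copied template; must lie in (0, 0.5).
#' @return An `hmm_params` list.
#' @export
hmm_params <- function(recombination_scale = 100, error_rate = 1e-3) {
  if (!(recombination_scale > 0)) stop("recombination_scale must be > 0")
  if (!(error_rate > 0 && error_rate < 0.5))
    stop("error_rate must lie in (0, 0.5)")
  structure(list(recombination_scale = as.double(recombination_scale),
                 error_rate = as.double(error_rate)),
            class = "hmm_params")
}

#' Impute genotypes with a diploid Li-Stephens copying model
#'
#' Each target individual is modelled as an ordered pair of reference
#' haplotypes; the pair switches templates along the chromosome at a rate
#' set by genetic distance and `recombination_scale`, and typed genotypes
#' are observed through a symmetric per-allele error channel. The
#' forward-backward algorithm yields posterior P(AA), P(AB), P(BB) at every
#' marker, from which the B-allele dosage `P(AB) + 2 P(BB)` is derived.
#'
#' Typed markers are re-estimated by the model internally but reported as
#' observed: their dosage equals the observed genotype and their posterior
#' is the corresponding point mass.
#'
#' @param reference a [haplotype_set()] covering every marker.
#' @param targets a [genotype_matrix()] typed only at panel markers
#'   (missing elsewhere), on the same marker map.
#' @param params an [hmm_params()].
#' @param error_by_marker optional per-marker allele error rates overriding
#'   `params$error_rate`: a vector of length L shared by all individuals,
#'   or an N x L matrix with one row per individual, for observations of
#'   mixed provenance (e.g. hard calls from an earlier imputation step).
#' @return A [dosage_matrix()] for all target individuals and markers.
#' @export
impute_ls_hmm <- function(reference, targets, params = hmm_params(),
                          error_by_marker = NULL) {
  stopifnot(inherits(reference, "haplotype_set"),
            inherits(targets, "genotype_matrix"),
            inherits(params, "hmm_params"))
  if (!same_map(reference$marker_map, targets$marker_map))
    stop("reference and target marker maps differ")
  H <- nrow(reference$alleles)
  if (H < 2L) stop("need at least 2 reference haplotypes")
  L <- ncol(reference$alleles)
  N <- nrow(targets$genotypes)
  err <- if (is.null(error_by_marker)) {
    matrix(params$error_rate, N, L)
  } else if (is.matrix(error_by_marker)) {
    stopifnot(nrow(error_by_marker) == N, ncol(error_by_marker) == L)
    error_by_marker
  } else {
    matrix(rep_len(as.double(error_by_marker), L), N, L, byrow = TRUE)
  }
  if (any(err <= 0 | err >= 0.5))
    stop("per-marker error rates must lie in (0, 0.5)")
  dmorgan <- diff(reference$marker_map$pos_morgan)
  probs <- array(NA_real_, dim = c(N, L, 3L))
  for (i in seq_len(N)) {
    gt <- targets$genotypes[i, ]
    if (all(is.na(gt)))
      stop("individual ", targets$individual_ids[i],
           " has no typed markers")
    post <- .ls_diploid_fb(reference$alleles, as.integer(gt), dmorgan,
                           params$recombination_scale, err[i, ])
    typed <- which(!is.na(gt))
    post[, typed] <- 0
    post[cbind(gt[typed] + 1L, typed)] <- 1
    probs[i, , 1L] <- post[1L, ]
    probs[i, , 2L] <- post[2L, ]
    probs[i, , 3L] <- post[3L, ]
  }
  dosage_matrix(probs, targets$marker_map, ids = targets$individual_ids)
}

#' Most likely genotypes from posterior probabilities
#'
#' Per cell argmax of (P(AA), P(AB), P(BB)); ties are broken toward the
#' heterozygote, then toward AA.
#'
#' @param dosages a [dosage_matrix()].
#' @return A [genotype_matrix()] of hard calls.
#' @export
hard_call <- function(dosages) {
  stopifnot(inherits(dosages, "dosage_matrix"))
  p0 <- dosages$genotype_probs[, , 1L]
  p1 <- dosages$genotype_probs[, , 2L]
  p2 <- dosages$genotype_probs[, , 3L]
  g <- ifelse(p1 >= p0 & p1 >= p2, 1L, ifelse(p0 >= p2, 0L, 2L))
  genotype_matrix(matrix(g, nrow = nrow(dosages$dosages)),
                  dosages$marker_map, ids = dosages$individual_ids)
}

#' Two-step (stepwise) imputation
#'
#' Step 1 imputes the low-density targets up to the intermediate panel
#' against a reference typed at that panel, then hard-calls the result
#' (most likely genotypes are passed between steps, not dosages). Step 2
#' imputes the hard-called intermediate genotypes up to the full sequence
#' marker set against a second, disjoint reference.
#'
#' Step-2 anchors are not all equally trustworthy: original low-density
#' genotypes are direct observations, while the remaining intermediate
#' markers are hard calls whose miscall rate the step-1 posteriors
#' themselves estimate. The step-2 emission error is therefore set per
#' marker: `params$error_rate` at the original panel markers, and at the
#' imputed anchors an allele error derived from the mean posterior
#' probability of the called genotype (`1 - sqrt(P(call correct))`,
#' floored at `params$error_rate` and capped at 0.45).
#'
#' In the returned overall dosages, markers of the intermediate panel keep
#' their step-1 posteriors (they are imputed products of step 1, not of
#' step 2), original panel markers stay observed, and all remaining
#' markers carry the step-2 posteriors.
#'
#' @param targets a [genotype_matrix()] typed only at the low-density panel.
#' @param step1_reference a [haplotype_set()] used at the intermediate
#'   (hd) panel markers.
#' @param step2_reference a [haplotype_set()] covering all markers.
#' @param lo_panel,hd_panel [panel_definition()]s with `lo` nested in `hd`.
#' @param params an [hmm_params()].
#' @return list with `final` (a [dosage_matrix()] over all markers,
#'   combining the step outputs as above) and `step1` (the retained
#'   step-1 [dosage_matrix()] over hd markers).
#' @export
impute_stepwise <- function(targets, step1_reference, step2_reference,
                            lo_panel, hd_panel, params = hmm_params()) {
  stopifnot(inherits(lo_panel, "panel_definition"),
            inherits(hd_panel, "panel_definition"))
  if (!all(lo_panel$marker_indices %in% hd_panel$marker_indices))
    stop("panel nesting violated: lo panel is not a subset of the hd panel")
  hd_idx <- hd_panel$marker_indices
  hd_map <- subset_map(targets$marker_map, hd_idx)

  ref1 <- step1_reference
  if (ncol(ref1$alleles) == length(hd_idx)) {
    # already restricted to hd markers
    if (!same_map(ref1$marker_map, hd_map))
      stop("step-1 reference map does not match the hd panel markers")
  } else {
    ref1 <- haplotype_set(ref1$alleles[, hd_idx, drop = FALSE], hd_map,
                          ids = ref1$haplotype_ids)
  }
  tg1 <- genotype_matrix(targets$genotypes[, hd_idx, drop = FALSE], hd_map,
                         ids = targets$individual_ids)
  step1 <- impute_ls_hmm(ref1, tg1, params)
  hc <- hard_call(step1)

  # per-individual, per-marker confidence of the step-1 hard calls
  # -> step-2 anchor error (allele error from P(call correct) ~ (1-e)^2)
  p_call <- pmax(step1$genotype_probs[, , 1L], step1$genotype_probs[, , 2L],
                 step1$genotype_probs[, , 3L])
  p_call <- matrix(p_call, nrow = nrow(step1$dosages))
  e_anchor <- pmin(pmax(1 - sqrt(p_call), params$error_rate), 0.49)

  N <- nrow(targets$genotypes)
  L <- ncol(targets$genotypes)
  g2 <- matrix(NA_integer_, N, L)
  g2[, hd_idx] <- hc$genotypes
  err2 <- matrix(params$error_rate, N, L)
  err2[, hd_idx] <- e_anchor
  err2[, lo_panel$marker_indices] <- params$error_rate
  tg2 <- genotype_matrix(g2, targets$marker_map,
                         ids = targets$individual_ids)
  step2 <- impute_ls_hmm(step2_reference, tg2, params,
                         error_by_marker = err2)

  # overall output: step-1 posteriors at intermediate-only markers,
  # observations at the original panel, step-2 posteriors elsewhere
  probs <- step2$genotype_probs
  probs[, hd_idx, ] <- step1$genotype_probs
  lo_in_hd <- match(lo_panel$marker_indices, hd_idx)
  obs <- targets$genotypes[, lo_panel$marker_indices, drop = FALSE]
  oh <- array(step1$genotype_probs[, lo_in_hd, ],
              c(nrow(obs), ncol(obs), 3L))
  for (k in 1:3) {
    pl <- oh[, , k]
    sel <- !is.na(obs)
    pl[sel] <- as.numeric(obs[sel] == k - 1L)
    oh[, , k] <- pl
  }
  probs[, lo_panel$marker_indices, ] <- oh
  final <- dosage_matrix(probs, targets$marker_map,
                         ids = targets$individual_ids)
  list(final = final, step1 = step1)
}
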