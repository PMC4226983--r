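# Shared simulation fixtures, memoised so several test files can reuse the
# same populations without re-simulating.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# small population for unit-scale checks
small_sim <- function(seed = 42) {
  memo(paste0("small", seed), {
    cfg <- simulation_config(n_sites = 600, n_sample_individuals = 24,
                             seed = seed)
    haps <- simulate_population(cfg)
    truth <- sample_diploids(haps, 24, seed + 1)
    list(cfg = cfg, haps = haps, truth = truth)
  })
}

# default-parameter population (the study conditions of the generator)
default_sim <- function(seed) {
  memo(paste0("default", seed), simulate_population(simulation_config(seed = seed)))
}

# binned LD decay of a haplotype population, estimated on common variants
ld_decay_bins <- function(haps, maf_min = 0.2, breaks = seq(0, 0.02, 0.0025)) {
  f <- maf(haps)
  keep <- which(f >= maf_min)
  C <- suppressWarnings(cor(haps$alleles[, keep]))^2
  pm <- haps$marker_map$pos_morgan[keep]
  D <- abs(outer(pm, pm, "-"))
  ut <- upper.tri(D)
  d <- D[ut]
  r2 <- C[ut]
  b <- cut(d, breaks)
  ok <- !is.na(b) & !is.na(r2)
  data.frame(c_mean = as.numeric(tapply(d[ok], b[ok], mean)),
             r2_mean = as.numeric(tapply(r2[ok], b[ok], mean)))
}

# full cross-validation study at the package's reference problem size:
# 60 individuals, 2000 candidate sites, hd = 200, lo = 20 markers
directional_results <- function(seed) {
  memo(paste0("dir", seed), {
    cfg <- simulation_config(n_sites = 2000, n_sample_individuals = 60,
                             seed = seed)
    haps <- simulate_population(cfg)
    truth <- sample_diploids(haps, 60, seed + 50)
    map <- truth$marker_map
    hd <- build_panel(map, truth, 0.1, 200, "hd")
    lo <- build_panel(map, truth, 0.1, 20, "lo", within = hd)
    asn <- assign_groups(truth$individual_ids, 5, seed + 70)
    params <- hmm_params()
    all_m <- seq_len(nrow(map))
    ev <- function(sc, panel, hd_panel = NULL) {
      plan <- scenario_plan(asn, sc)
      res <- run_scenario(truth, haps, plan, panel, params,
                          hd_panel = hd_panel)
      excl <- if (sc == "TWO_STEP") lo$marker_indices else
        panel$marker_indices
      evaluate_scenario(truth, res$dosages, asn, setdiff(all_m, excl),
                        sc, panel$name)
    }
    evals <- list(S80_hd = ev("S80", hd), S60_hd = ev("S60", hd),
                  S40_hd = ev("S40", hd), S40_lo = ev("S40", lo),
                  TWO_STEP = ev("TWO_STEP", lo, hd_panel = hd))
    list(cfg = cfg, haps = haps, truth = truth, hd = hd, lo = lo,
         asn = asn, evals = evals,
         mean_snp = vapply(evals, function(e) mean(e$per_snp$r), numeric(1)),
         mean_ind = vapply(evals, function(e)
           mean(e$per_individual$raw, na.rm = TRUE), numeric(1)))
  })
}

# exact genotype matrix with prescribed per-column B-allele counts
geno_with_counts <- function(n_ind, alt_counts) {
  g <- vapply(alt_counts, function(k) {
    col <- integer(n_ind)
    full <- k %/% 2
    if (full > 0) col[seq_len(full)] <- 2L
    if (k %% 2 == 1) col[full + 1L] <- 1L
    col
  }, integer(n_ind))
  g
}
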