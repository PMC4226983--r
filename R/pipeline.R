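#' Configuration of a full pipeline run
#'
#' Bundles the simulation settings, panel sizes, scenario list, imputation
#' parameters and reliability-model settings under one master seed. The
#' master seed deterministically derives per-stage seeds (stage k uses
#' `(master %% 2e7) * 100 + k`), so individual stages can be re-run in
#' isolation.
#'
#' @param sim named list of [simulation_config()] arguments (without
#'   `seed`).
#' @param hd_size,lo_size marker counts of the intermediate and low-density
#'   panels.
#' @param panel_maf_min MAF ascertainment threshold for both panels.
#' @param scenarios character vector drawn from
#'   `c("S80", "S60", "S40", "TWO_STEP")`.
#' @param hmm named list of [hmm_params()] arguments.
#' @param reliability named list of [reliability_params()] arguments; an
#'   `Ne` of `NULL` uses the simulated population size.
#' @param bin_size markers per bin for the reliability analysis.
#' @param out_dir output directory.
#' @param master_seed integer master seed.
#' @return A `run_config` list, serialisable to YAML with exact round-trip.
#' @export
run_config <- function(sim = list(), hd_size = 200L, lo_size = 20L,
                       panel_maf_min = 0.1,
                       scenarios = c("S80", "S60", "S40", "TWO_STEP"),
                       hmm = list(), reliability = list(),
                       bin_size = 100L, out_dir = "seqimp_run",
                       master_seed = 1L) {
  bad <- setdiff(scenarios, c("S80", "S60", "S40", "TWO_STEP"))
  if (length(bad)) stop("unknown scenario(s): ", paste(bad, collapse = ", "))
  structure(list(sim = sim, hd_size = as.integer(hd_size),
                 lo_size = as.integer(lo_size),
                 panel_maf_min = as.double(panel_maf_min),
                 scenarios = as.character(scenarios), hmm = hmm,
                 reliability = reliability, bin_size = as.integer(bin_size),
                 out_dir = as.character(out_dir),
                 master_seed = as.integer(master_seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param file path of the YAML config file.
#' @export
write_run_config <- function(config, file) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), file, precision = 15L)
  invisible(file)
}

#' @rdname run_config
#' @export
read_run_config <- function(file) {
  y <- yaml::read_yaml(file)
  do.call(run_config, y)
}

derive_seed <- function(master, stage) {
  (as.integer(master) %% 20000000L) * 100L + as.integer(stage)
}

#' Impute one cross-validation scenario
#'
#' Rotates over the five folds of a [scenario_plan()]: in each fold the
#' validation individuals are masked down to the panel and imputed back to
#' sequence density against the fold's reference individuals (whose
#' haplotypes are taken from the simulated truth). For `TWO_STEP`, `panel`
#' is the low-density panel and imputation goes through `hd_panel` with the
#' two disjoint reference sets.
#'
#' @param truth full [genotype_matrix()] with haplotype back-references.
#' @param haps the [haplotype_set()] population the individuals came from.
#' @param plan a [scenario_plan()].
#' @param panel the typed [panel_definition()] of the validation
#'   individuals.
#' @param params an [hmm_params()].
#' @param hd_panel intermediate panel, required for `TWO_STEP`.
#' @return list with `dosages` (a [dosage_matrix()]; every individual's row
#'   comes from the fold where it was validated) and, for `TWO_STEP`,
#'   `step1` dosages over the hd markers.
#' @export
run_scenario <- function(truth, haps, plan, panel, params = hmm_params(),
                         hd_panel = NULL) {
  stopifnot(inherits(plan, "scenario_plan"))
  asn <- plan$assignment
  N <- nrow(truth$genotypes)
  L <- ncol(truth$genotypes)
  probs <- array(NA_real_, c(N, L, 3L))
  two_step <- plan$scenario == "TWO_STEP"
  if (two_step) {
    if (is.null(hd_panel)) stop("TWO_STEP requires hd_panel")
    step1_probs <- array(NA_real_, c(N, length(hd_panel$marker_indices), 3L))
  }
  masked <- mask_to_panel(truth, panel)
  for (f in plan$folds) {
    val <- group_members(asn, f$validation_group)
    tg <- genotype_matrix(masked$genotypes[val, , drop = FALSE],
                          truth$marker_map,
                          ids = truth$individual_ids[val])
    if (two_step) {
      ref1 <- individual_haplotypes(haps, truth,
                                    group_members(asn,
                                                  f$step1_reference_groups))
      ref2 <- individual_haplotypes(haps, truth,
                                    group_members(asn,
                                                  f$step2_reference_groups))
      res <- impute_stepwise(tg, ref1, ref2, panel, hd_panel, params)
      probs[val, , ] <- res$final$genotype_probs
      step1_probs[val, , ] <- res$step1$genotype_probs
    } else {
      ref <- individual_haplotypes(haps, truth,
                                   group_members(asn, f$reference_groups))
      dos <- impute_ls_hmm(ref, tg, params)
      probs[val, , ] <- dos$genotype_probs
    }
  }
  out <- list(dosages = dosage_matrix(probs, truth$marker_map,
                                      ids = truth$individual_ids))
  if (two_step)
    out$step1 <- dosage_matrix(step1_probs,
                               subset_map(truth$marker_map,
                                          hd_panel$marker_indices),
                               ids = truth$individual_ids)
  out
}

#' Accuracy of an imputed scenario
#'
#' Applies the fixed-marker filter within validation groups, then computes
#' per-SNP accuracy (pooled over all validation individuals) and
#' per-individual accuracy in raw, centered and standardized modes
#' (centering statistics from the individual's own fold).
#'
#' @param truth full observed [genotype_matrix()].
#' @param dosages imputed [dosage_matrix()] aligned with `truth`.
#' @param assignment the [assign_groups()] partition.
#' @param markers marker indices to evaluate (typically the imputed,
#'   non-panel markers).
#' @param scenario,panel labels carried into the result.
#' @return An `accuracy_result`: list with `per_snp` (data.frame `marker`,
#'   `r`), `per_individual` (data.frame `individual_id`, `group`, `raw`,
#'   `centered`, `standardized`), `n_markers_evaluated`,
#'   `n_markers_removed`, `scenario`, `panel`.
#' @export
evaluate_scenario <- function(truth, dosages, assignment, markers,
                              scenario = "", panel = "") {
  obs <- truth$genotypes[, markers, drop = FALSE]
  dos <- dosages$dosages[, markers, drop = FALSE]
  groups <- split(seq_along(assignment$group_of), assignment$group_of)
  keep <- filter_informative(obs, dos, groups)
  ok <- as.matrix(obs[, keep, drop = FALSE])
  od <- as.matrix(dos[, keep, drop = FALSE])
  r <- accuracy_per_snp(ok, od)
  per_ind <- do.call(rbind, lapply(names(groups), function(gname) {
    g <- groups[[gname]]
    data.frame(
      individual_id = truth$individual_ids[g],
      group = as.integer(gname),
      raw = accuracy_per_individual(ok[g, , drop = FALSE],
                                    od[g, , drop = FALSE], "raw"),
      centered = accuracy_per_individual(ok[g, , drop = FALSE],
                                         od[g, , drop = FALSE], "centered"),
      standardized = accuracy_per_individual(ok[g, , drop = FALSE],
                                             od[g, , drop = FALSE],
                                             "standardized")
    )
  }))
  structure(list(per_snp = data.frame(marker = markers[keep], r = r),
                 per_individual = per_ind,
                 n_markers_evaluated = sum(keep),
                 n_markers_removed = sum(!keep),
                 scenario = scenario, panel = panel),
            class = "accuracy_result")
}

summary_row <- function(x, scenario, panel) {
  data.frame(scenario = scenario, panel = panel,
             mean = mean(x, na.rm = TRUE), sd = stats::sd(x, na.rm = TRUE),
             min = min(x, na.rm = TRUE), max = max(x, na.rm = TRUE),
             n = sum(!is.na(x)))
}

#' Run the full simulation-imputation-evaluation pipeline
#'
#' Executes simulate -> sample -> panels -> plan -> impute (all configured
#' scenarios, including two-step) -> evaluate -> Michaelis-Menten fit ->
#' reliability prediction, writing VCF and TSV artifacts plus summary
#' tables (per-SNP and per-individual accuracy by scenario and panel, with
#' two-step broken into step 1 / step 2 / overall) and a run log to
#' `out_dir`. All randomness derives from `config$master_seed`; re-running
#' with the same config reproduces the outputs byte for byte.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (defaults to `config$out_dir`).
#' @return invisibly, a list with the in-memory results: `summary_per_snp`,
#'   `summary_per_individual`, `mm_fits`, `panels`, `accuracy` (per
#'   scenario/panel `accuracy_result`s), `predictions`.
#' @export
run_pipeline <- function(config, out_dir = config$out_dir) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- c(sprintf("seqimp %s pipeline run",
                   as.character(utils::packageVersion("seqimp"))),
           sprintf("master_seed: %d", config$master_seed))

  sim_cfg <- stage("simulate", do.call(simulation_config,
    c(config$sim, list(seed = derive_seed(config$master_seed, 1L)))))
  haps <- stage("simulate", simulate_population(sim_cfg))
  truth <- stage("sample", sample_diploids(haps, sim_cfg$n_sample_individuals,
                                           derive_seed(config$master_seed,
                                                       2L)))
  map <- truth$marker_map
  log <- c(log, sprintf("simulated %d haplotypes x %d sites; sampled %d individuals",
                        nrow(haps$alleles), ncol(haps$alleles),
                        nrow(truth$genotypes)))

  panels <- stage("panels", {
    seq_p <- panel_definition("seq", seq_len(nrow(map)), map)
    hd <- build_panel(map, truth, config$panel_maf_min, config$hd_size, "hd")
    lo <- build_panel(map, truth, config$panel_maf_min, config$lo_size, "lo",
                      within = hd)
    list(seq = seq_p, hd = hd, lo = lo)
  })
  ovl <- panel_overlap_report(panels)
  log <- c(log, sprintf("panel %s: %d markers (%.2f%% of seq)",
                        names(ovl$sizes), ovl$sizes, ovl$pct_of_seq))

  write_vcf(truth, file.path(out_dir, "truth.vcf"))
  write_results_tsv(as.data.frame(map), file.path(out_dir, "marker_map.tsv"))
  write_panel_tsv(panels$hd, file.path(out_dir, "panel_hd.tsv"))
  write_panel_tsv(panels$lo, file.path(out_dir, "panel_lo.tsv"))

  asn <- stage("plan", assign_groups(truth$individual_ids, 5L,
                                     derive_seed(config$master_seed, 3L)))
  params <- do.call(hmm_params, config$hmm)

  snp_rows <- list()
  ind_rows <- list()
  acc <- list()
  hd_results <- list()  # per-SNP accuracy from the hd panel, per scenario
  all_m <- seq_len(nrow(map))

  for (sc in config$scenarios) {
    plan <- scenario_plan(asn, sc)
    write_plan_tsv(plan, file.path(out_dir, sprintf("plan_%s.tsv", sc)))
    if (sc == "TWO_STEP") {
      res <- stage(sc, run_scenario(truth, haps, plan, panels$lo, params,
                                    hd_panel = panels$hd))
      hd_i <- panels$hd$marker_indices
      lo_i <- panels$lo$marker_indices
      sub_truth <- genotype_matrix(truth$genotypes[, hd_i, drop = FALSE],
                                   subset_map(map, hd_i),
                                   ids = truth$individual_ids)
      e1 <- evaluate_scenario(sub_truth, res$step1, asn,
                              which(!hd_i %in% lo_i), sc, "step1")
      e2 <- evaluate_scenario(truth, res$dosages, asn,
                              setdiff(all_m, hd_i), sc, "step2")
      eo <- evaluate_scenario(truth, res$dosages, asn,
                              setdiff(all_m, lo_i), sc, "overall")
      for (e in list(e1, e2, eo)) {
        snp_rows[[length(snp_rows) + 1L]] <- summary_row(e$per_snp$r, sc,
                                                         e$panel)
        ind_rows[[length(ind_rows) + 1L]] <-
          summary_row(e$per_individual$raw, sc, e$panel)
        acc[[paste(sc, e$panel, sep = "_")]] <- e
      }
      write_vcf(res$dosages, file.path(out_dir,
                                       sprintf("imputed_%s.vcf", sc)))
    } else {
      for (pn in c("hd", "lo")) {
        res <- stage(sc, run_scenario(truth, haps, plan, panels[[pn]],
                                      params))
        e <- evaluate_scenario(truth, res$dosages, asn,
                               setdiff(all_m, panels[[pn]]$marker_indices),
                               sc, pn)
        snp_rows[[length(snp_rows) + 1L]] <- summary_row(e$per_snp$r, sc, pn)
        ind_rows[[length(ind_rows) + 1L]] <-
          summary_row(e$per_individual$raw, sc, pn)
        acc[[paste(sc, pn, sep = "_")]] <- e
        if (pn == "hd") hd_results[[sc]] <- e
        write_vcf(res$dosages,
                  file.path(out_dir, sprintf("imputed_%s_%s.vcf", sc, pn)))
        write_results_tsv(e$per_snp,
                          file.path(out_dir,
                                    sprintf("per_snp_%s_%s.tsv", sc, pn)))
        write_results_tsv(e$per_individual,
                          file.path(out_dir,
                                    sprintf("per_individual_%s_%s.tsv",
                                            sc, pn)))
      }
    }
  }

  summary_per_snp <- do.call(rbind, snp_rows)
  summary_per_individual <- do.call(rbind, ind_rows)
  write_results_tsv(summary_per_snp,
                    file.path(out_dir, "summary_per_snp.tsv"))
  write_results_tsv(summary_per_individual,
                    file.path(out_dir, "summary_per_individual.tsv"))

  # reliability analysis on the hd-panel scenarios
  rel_args <- config$reliability
  if (is.null(rel_args$Ne)) rel_args$Ne <- sim_cfg$population_size_diploid
  rparams <- do.call(reliability_params, rel_args)
  mstats <- stage("reliability",
                  compute_marker_stats(map, panels$hd, truth))
  mm_rows <- list()
  predictions <- list()
  for (sc in names(hd_results)) {
    e <- hd_results[[sc]]
    sel <- match(e$per_snp$marker, mstats$stats$marker)
    kept <- !is.na(sel)
    bins <- bin_by_covariate(e$per_snp$r[kept],
                             mstats$stats$maf[sel[kept]],
                             config$bin_size,
                             positions = mstats$stats$pos_bp[sel[kept]])
    fit <- stage("fit-mm", fit_michaelis_menten(bins))
    mm_rows[[sc]] <- data.frame(scenario = sc, Vmax = fit$Vmax, Km = fit$Km,
                                se_Vmax = fit$se_Vmax, se_Km = fit$se_Km,
                                n_bins = fit$n_bins)
    pred <- predict_reliability(mstats, fit, rparams)
    obs_r <- rep(NA_real_, nrow(pred))
    obs_r[sel[kept]] <- e$per_snp$r[kept]
    pred$observed_r2 <- obs_r^2
    predictions[[sc]] <- pred
    write_results_tsv(pred, file.path(out_dir,
                                      sprintf("reliability_%s.tsv", sc)))
  }
  mm_fits <- do.call(rbind, mm_rows)
  if (!is.null(mm_fits))
    write_results_tsv(mm_fits, file.path(out_dir, "mm_fits.tsv"))

  log <- c(log, sprintf("R %s.%s", R.version$major, R.version$minor),
           sprintf("scenarios: %s", paste(config$scenarios, collapse = ", ")))
  writeLines(log, file.path(out_dir, "run_log.txt"))
  write_run_config(config, file.path(out_dir, "config.yaml"))

  invisible(list(summary_per_snp = summary_per_snp,
                 summary_per_individual = summary_per_individual,
                 mm_fits = mm_fits, panels = panels, accuracy = acc,
                 predictions = predictions, truth = truth, haps = haps,
                 assignment = asn))
}
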