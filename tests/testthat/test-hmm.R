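test_that("parameter validation rejects degenerate settings", {
  expect_error(hmm_params(error_rate = 0), "error_rate")
  expect_error(hmm_params(error_rate = 0.5), "error_rate")
  expect_error(hmm_params(recombination_scale = 0), "recombination_scale")
})

test_that("forward-backward matches the dense-transition oracle", {
  cases <- expand.grid(H = 2:4, L = c(3L, 5L, 6L))
  for (k in seq_len(nrow(cases))) {
    inst <- rand_hmm_instance(cases$H[k], cases$L[k], seed = 100 + k)
    got <- pkg_fb(inst)
    want <- ls_fb_dense(inst$ref, inst$gt, inst$dmorgan, inst$rho, inst$err)
    expect_lt(max(abs(got - want)), 1e-8)
  }
})

test_that("dense oracle agrees with exhaustive path enumeration", {
  for (k in 1:4) {
    inst <- rand_hmm_instance(H = 3, L = 4, seed = 200 + k)
    dense <- ls_fb_dense(inst$ref, inst$gt, inst$dmorgan, inst$rho, inst$err)
    enum <- ls_enum(inst$ref, inst$gt, inst$dmorgan, inst$rho, inst$err)
    expect_lt(max(abs(dense - enum)), 1e-10)
  }
})

test_that("posteriors are normalised and dosages bounded", {
  sim <- small_sim()
  panel <- build_panel(sim$truth$marker_map, sim$truth, 0.1, 60)
  ref <- individual_haplotypes(sim$haps, sim$truth, 1:8)
  tg <- mask_to_panel(sim$truth, panel)
  tg <- genotype_matrix(tg$genotypes[9:12, ], sim$truth$marker_map,
                        ids = sim$truth$individual_ids[9:12])
  d <- impute_ls_hmm(ref, tg)
  tot <- d$genotype_probs[, , 1] + d$genotype_probs[, , 2] +
    d$genotype_probs[, , 3]
  expect_lt(max(abs(tot - 1)), 1e-9)
  expect_true(all(d$dosages >= 0 & d$dosages <= 2))
  expect_lt(max(abs(d$dosages -
                      (d$genotype_probs[, , 2] +
                         2 * d$genotype_probs[, , 3]))), 1e-12)
})

test_that("a densely typed copy of a reference diploid is recovered", {
  sim <- small_sim()
  ref <- individual_haplotypes(sim$haps, sim$truth, 1:6)
  true_geno <- sim$truth$genotypes[3, ]  # individual 3 is in the reference
  typed <- true_geno
  untyped <- seq(5, length(typed), by = 5)
  typed[untyped] <- NA
  tg <- genotype_matrix(matrix(typed, 1), sim$truth$marker_map)
  d <- impute_ls_hmm(ref, tg, hmm_params(error_rate = 1e-6))
  expect_lt(max(abs(d$dosages[1, ] - true_geno)), 0.01)
})

test_that("with two reference haplotypes the implied pair genotype is returned", {
  map <- marker_map("1", as.integer(seq(1000, 20000, by = 1000)))
  withr::with_seed(31, {
    h1 <- sample(0:1, 20, replace = TRUE)
    h2 <- sample(0:1, 20, replace = TRUE)
  })
  ref <- haplotype_set(rbind(h1, h2), map)
  gt <- h1 + h2
  gt[seq(2, 20, by = 2)] <- NA
  d <- impute_ls_hmm(ref, genotype_matrix(matrix(gt, 1), map),
                     hmm_params(error_rate = 1e-6))
  expect_lt(max(abs(d$dosages[1, ] - (h1 + h2))), 0.01)
})

test_that("hard calls take the modal genotype with het-then-AA ties", {
  map <- marker_map("1", c(10L, 20L, 30L, 40L))
  probs <- array(0, c(1, 4, 3))
  probs[1, 1, ] <- c(0.2, 0.5, 0.3)
  probs[1, 2, ] <- c(0.5, 0.5, 0.0)
  probs[1, 3, ] <- c(1, 0, 0)
  probs[1, 4, ] <- c(0.4, 0.2, 0.4)
  hc <- hard_call(dosage_matrix(probs, map))
  expect_equal(as.vector(hc$genotypes), c(1L, 1L, 0L, 0L))
})

test_that("imputation contracts reject inconsistent inputs", {
  sim <- small_sim()
  ref <- individual_haplotypes(sim$haps, sim$truth, 1:4)
  other_map <- marker_map("1", sim$truth$marker_map$pos_bp + 1L)
  tg_bad <- genotype_matrix(sim$truth$genotypes[1:2, ], other_map)
  expect_error(impute_ls_hmm(ref, tg_bad), "maps differ")

  tg_empty <- genotype_matrix(
    matrix(NA_integer_, 1, nrow(sim$truth$marker_map)),
    sim$truth$marker_map, ids = "lonely")
  expect_error(impute_ls_hmm(ref, tg_empty), "no typed markers")

  one_hap <- haplotype_set(sim$haps$alleles[1, , drop = FALSE],
                           sim$haps$marker_map)
  tg <- mask_to_panel(sim$truth, build_panel(sim$truth$marker_map,
                                             sim$truth, 0.1, 30))
  expect_error(impute_ls_hmm(one_hap, tg), "at least 2")
})

test_that("two-step with identical panels collapses to single-step", {
  sim <- small_sim()
  map <- sim$truth$marker_map
  hd <- build_panel(map, sim$truth, 0.1, 40, "hd")
  ref1 <- individual_haplotypes(sim$haps, sim$truth, 1:6)
  ref2 <- individual_haplotypes(sim$haps, sim$truth, 7:12)
  tg <- mask_to_panel(sim$truth, hd)
  tg <- genotype_matrix(tg$genotypes[13:16, ], map,
                        ids = sim$truth$individual_ids[13:16])
  res <- impute_stepwise(tg, ref1, ref2, hd, hd)
  direct <- impute_ls_hmm(ref2, tg)
  expect_equal(res$final$genotype_probs, direct$genotype_probs,
               tolerance = 1e-12)
})

test_that("two-step refuses panels that do not nest", {
  sim <- small_sim()
  map <- sim$truth$marker_map
  hd <- build_panel(map, sim$truth, 0.1, 40, "hd")
  lo <- panel_definition("lo", setdiff(1:20, hd$marker_indices)[1:5], map)
  ref <- individual_haplotypes(sim$haps, sim$truth, 1:6)
  tg <- mask_to_panel(sim$truth, lo)
  expect_error(impute_stepwise(tg, ref, ref, lo, hd), "nesting")
})

test_that("enlarging the reference set does not hurt accuracy", {
  for (seed in c(42, 43, 44)) {
    sim <- small_sim(seed)
    map <- sim$truth$marker_map
    panel <- build_panel(map, sim$truth, 0.1, 50)
    targets <- 21:24
    tg <- mask_to_panel(sim$truth, panel)
    tg <- genotype_matrix(tg$genotypes[targets, ], map,
                          ids = sim$truth$individual_ids[targets])
    acc <- function(ref_ind) {
      ref <- individual_haplotypes(sim$haps, sim$truth, ref_ind)
      d <- impute_ls_hmm(ref, tg)
      ev <- setdiff(seq_len(nrow(map)), panel$marker_indices)
      obs <- sim$truth$genotypes[targets, ev]
      keep <- filter_informative(obs, d$dosages[, ev], list(1:4))
      mean(accuracy_per_snp(obs[, keep], d$dosages[, ev][, keep]))
    }
    expect_gte(acc(1:20), acc(1:10) - 0.02)
  }
})
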