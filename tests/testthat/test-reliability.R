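test_that("LD decay term follows 1/(4*Ne*c + 1)", {
  expect_equal(r2_dist(100, 0), 1)
  expect_equal(r2_dist(100, 0.0025), 0.5)
  expect_equal(r2_dist(1000, 1e-4), 1 / 1.4)
  cs <- seq(0, 0.05, length.out = 50)
  expect_true(all(diff(r2_dist(500, cs)) < 0))
  expect_error(r2_dist(100, -1e-4), "nonnegative")
  expect_error(r2_dist(0, 0.1), "positive")
})

test_that("MAF-difference bound is 1 at equal MAFs and decreases", {
  expect_equal(r2_dmaf(0, "ratio_linear"), 1)
  expect_equal(r2_dmaf(0, "ratio_squared"), 1)
  expect_equal(r2_dmaf(0.5, "ratio_linear"), 0)
  expect_equal(r2_dmaf(0.1, "ratio_linear"), 0.8 / 1.2)
  d <- seq(0, 0.5, length.out = 60)
  expect_true(all(diff(r2_dmaf(d, "ratio_linear")) < 0))
  expect_true(all(diff(r2_dmaf(d, "ratio_squared")) < 0))
  expect_error(r2_dmaf(0.6), "0, 0.5")
  expect_error(r2_dmaf(-0.1), "0, 0.5")
})

test_that("exact maximal r2 matches brute-force maximisation", {
  expect_equal(max_r2_exact(0.3, 0.3), 1)
  expect_equal(round(max_r2_exact(0.45, 0.05), 2), 0.06)
  withr::with_seed(17, {
    p <- runif(200, 0.005, 0.5)
    q <- runif(200, 0.005, 0.5)
  })
  closed <- max_r2_exact(p, q)
  brute <- mapply(max_r2_grid, p, q)
  expect_lt(max(abs(closed - brute)), 1e-6)
  expect_equal(max_r2_exact(p, q), max_r2_exact(q, p))
  expect_error(max_r2_exact(0, 0.2), "MAF 0")
  expect_error(max_r2_exact(0.2, 0.7), "exceed")
})

test_that("maximal r2 bounds every observed pairwise r2 in simulated data", {
  sim <- small_sim()
  f <- maf(sim$haps)
  keep <- which(f >= 0.02)[1:80]
  X <- sim$haps$alleles[, keep]
  r2 <- suppressWarnings(cor(X))^2
  bound <- outer(f[keep], f[keep], max_r2_exact)
  ut <- upper.tri(r2)
  ok <- !is.na(r2[ut])
  expect_true(all(r2[ut][ok] <= bound[ut][ok] + 1e-9))
})

test_that("Michaelis-Menten fitting recovers noiseless parameters exactly", {
  mafs <- seq(0.01, 0.5, length.out = 50)
  bins <- data.frame(covariate_mean = mafs,
                     reliability_mean = 0.95 * mafs / (0.036 + mafs))
  fit <- fit_michaelis_menten(bins)
  expect_equal(fit$Vmax, 0.95, tolerance = 1e-6)
  expect_equal(fit$Km, 0.036, tolerance = 1e-6)
  # deflection-point identity
  expect_equal(mm_value(fit, fit$Km), fit$Vmax / 2, tolerance = 1e-9)

  expect_error(fit_michaelis_menten(bins[1:2, ]), "at least 3")
  flat <- data.frame(covariate_mean = mafs, reliability_mean = 0.5)
  expect_error(fit_michaelis_menten(flat), "flat")
})

test_that("reliability curve endpoints match reported scenario fits", {
  expect_equal(round(mm_value(mm_fit(1.01, 0.073), 0.5), 3), 0.881)
  expect_equal(round(mm_value(mm_fit(0.98, 0.049), 0.5), 3), 0.893)
  expect_equal(round(mm_value(mm_fit(0.95, 0.036), 0.5), 3), 0.886)
  expect_equal(mm_value(mm_fit(1.01, 0.073), 0), 0)
  expect_error(mm_value(mm_fit(1, 0.05), 0.6), "0, 0.5")
})

test_that("best neighbor maximises the distance-dMAF product", {
  params <- reliability_params(Ne = 1000, dmaf_variant = "ratio_linear")
  # near-but-mismatched versus farther-but-matched
  sel <- select_best_neighbor(c(1e-4, 5e-4), c(0.4, 0.0), params)
  expect_equal(sel$index, 2L)
  expect_equal(sel$product, 1 / 3, tolerance = 1e-9)
  expect_equal(sel$r2_dist * sel$r2_dmaf, sel$product)

  one <- select_best_neighbor(2e-4, 0.1, params)
  expect_equal(one$index, 1L)

  tie <- select_best_neighbor(rep(1e-4, 5), rep(0.2, 5), params)
  expect_equal(tie$index, 1L)
  expect_error(select_best_neighbor(NA_real_, NA_real_, params),
               "no panel SNP")
})

test_that("predicted reliability is the product of its components", {
  sim <- small_sim()
  map <- sim$truth$marker_map
  panel <- build_panel(map, sim$truth, 0.1, 40)
  st <- compute_marker_stats(map, panel, sim$truth)
  # drop monomorphic markers (MAF 0 has no defined reliability target)
  poly <- st$stats$maf > 0
  st$stats <- st$stats[poly, ]
  st$neighbor_pos <- st$neighbor_pos[poly, , drop = FALSE]
  st$neighbor_morgan <- st$neighbor_morgan[poly, , drop = FALSE]
  st$neighbor_dmaf <- st$neighbor_dmaf[poly, , drop = FALSE]
  fit <- mm_fit(0.95, 0.05)
  pred <- predict_reliability(st, fit, reliability_params(Ne = 100))
  expect_lt(max(abs(pred$r2_total -
                      pred$r2_dist * pred$r2_dmaf * pred$r2_maf)), 1e-12)
  comp <- as.matrix(pred[, c("r2_dist", "r2_dmaf", "r2_maf", "r2_total")])
  expect_true(all(comp >= 0 & comp <= 1))
  expect_true(all(pred$r2_total <= pred$r2_dist + 1e-15))
  expect_true(all(pred$r2_total <= pred$r2_dmaf + 1e-15))
  expect_true(all(pred$r2_total <= pred$r2_maf + 1e-15))
})

test_that("predicted and observed binned reliabilities are rank-correlated", {
  d <- directional_results(101)
  e <- d$evals$S40_hd
  st <- compute_marker_stats(d$truth$marker_map, d$hd, d$truth)
  sel <- match(e$per_snp$marker, st$stats$marker)
  kept <- !is.na(sel)
  bins <- bin_by_covariate(e$per_snp$r[kept], st$stats$maf[sel[kept]], 100,
                           positions = st$stats$pos_bp[sel[kept]])
  fit <- fit_michaelis_menten(bins)
  pred <- predict_reliability(st, fit,
                              reliability_params(Ne = 100))
  pb <- bin_by_covariate(e$per_snp$r[kept], pred$r2_total[sel[kept]], 100,
                         positions = pred$pos_bp[sel[kept]])
  expect_gt(cor(pb$covariate_mean, pb$reliability_mean,
                method = "spearman"), 0.8)
})
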