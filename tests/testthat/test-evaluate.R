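test_that("markers fixed in any validation group are removed", {
  # 6 individuals, two groups of 3; 4 markers
  obs <- rbind(c(0L, 0L, 1L, 2L),
               c(0L, 1L, 2L, 1L),
               c(0L, 2L, 0L, 0L),
               c(1L, 0L, 1L, 2L),
               c(2L, 1L, 2L, 1L),
               c(0L, 2L, 0L, 0L))
  dos <- withr::with_seed(3, matrix(runif(24, 0, 2), 6, 4))
  groups <- list(1:3, 4:6)
  keep <- filter_informative(obs, dos, groups)
  # marker 1 observed constant (0,0,0) in group 1 only -> removed anyway
  expect_equal(keep, c(FALSE, TRUE, TRUE, TRUE))

  # constant dosage in one group also removes
  dos2 <- dos
  dos2[4:6, 2] <- 1.37
  expect_equal(filter_informative(obs, dos2, groups),
               c(FALSE, FALSE, TRUE, TRUE))

  expect_error(filter_informative(obs, dos, list(1:3, integer(0))),
               "empty validation group")
})

test_that("per-SNP accuracy is the pooled observed-dosage correlation", {
  expect_equal(accuracy_per_snp(cbind(c(0, 1, 2, 1)), cbind(c(0, 1, 2, 1))),
               1)
  expect_equal(accuracy_per_snp(cbind(c(0, 2, 0, 2)), cbind(c(2, 0, 2, 0))),
               -1)
  expect_equal(accuracy_per_snp(cbind(c(0, 0, 1, 2)), cbind(c(0, 1, 1, 2))),
               0.8528, tolerance = 1e-4)
  # hand oracle on a random matrix
  withr::with_seed(5, {
    o <- matrix(sample(0:2, 40, replace = TRUE), 8)
    d <- matrix(runif(40, 0, 2), 8)
  })
  expect_equal(accuracy_per_snp(o, d),
               vapply(1:5, function(j) cor(o[, j], d[, j]), numeric(1)))
  expect_error(accuracy_per_snp(cbind(c(1, 1, 1)), cbind(c(0, 1, 2))),
               "filter_informative")
})

test_that("random dosages give near-zero mean accuracy", {
  withr::with_seed(8, {
    o <- matrix(sample(0:2, 50 * 1000, replace = TRUE), 50)
    d <- matrix(runif(50 * 1000, 0, 2), 50)
  })
  keep <- filter_informative(o, d, list(1:50))
  expect_lt(abs(mean(accuracy_per_snp(o[, keep], d[, keep]))), 0.05)
})

test_that("per-individual accuracy supports raw, centered and standardized modes", {
  # perfect imputation: 1 in every mode (no marker may be fixed for
  # the standardized mode to be defined)
  op <- rbind(c(2, 1, 0, 1),
              c(1, 2, 1, 0))
  for (mode in c("raw", "centered", "standardized"))
    expect_equal(accuracy_per_individual(op, op, mode), c(1, 1))

  o <- rbind(c(2, 1, 0, 1),
             c(2, 2, 0, 0))

  # frequency-aligned errors: raw exceeds centered (the allele-frequency
  # contribution inflates the raw correlation)
  d <- rbind(c(1.7, 1.6, 0.2, 0.3),
             c(1.9, 1.8, 0.1, 0.2))
  raw <- accuracy_per_individual(o, d, "raw")
  cen <- accuracy_per_individual(o, d, "centered")
  m <- colMeans(o)
  expect_equal(raw[1], cor(o[1, ], d[1, ]))
  expect_equal(cen[1], cor(o[1, ] - m, d[1, ] - m))
  expect_gt(raw[1], cen[1])

  # centering by a constant changes nothing
  o2 <- rbind(c(0, 2, 0, 2), c(2, 0, 2, 0))  # all marker means equal 1
  d2 <- rbind(c(0.2, 1.8, 0.4, 1.9), c(1.7, 0.3, 1.5, 0.1))
  expect_equal(accuracy_per_individual(o2, d2, "raw"),
               accuracy_per_individual(o2, d2, "centered"))
})

test_that("marker stats find nearest panel SNPs with the stated tie-break", {
  map <- marker_map("1", c(100L, 400L, 1000L))
  g <- genotype_matrix(geno_with_counts(10, c(8, 5, 4)), map)
  p <- panel_definition("p", c(1L, 3L), map)
  st <- compute_marker_stats(map, p, g)
  expect_equal(st$stats$marker, 2L)
  expect_equal(st$stats$nearest_panel_pos, 100)
  expect_equal(st$stats$distance_bp, 300)
  expect_equal(st$stats$dmaf_nearest, abs(0.25 - 0.4))
  # only two panel SNPs -> three NA neighbor slots
  expect_equal(sum(is.na(st$neighbor_pos[1, ])), 3L)

  # exact tie in distance -> lower position wins
  map2 <- marker_map("1", c(100L, 400L, 700L))
  g2 <- genotype_matrix(geno_with_counts(10, c(8, 5, 8)), map2)
  p2 <- panel_definition("p", c(1L, 3L), map2)
  st2 <- compute_marker_stats(map2, p2, g2)
  expect_equal(st2$stats$nearest_panel_pos, 100)
})

test_that("binning slices sorted markers into equal groups", {
  withr::with_seed(13, {
    r <- runif(2500, -1, 1)
    cv <- runif(2500)
  })
  b <- bin_by_covariate(r, cv, 1000)
  expect_equal(b$n_markers, c(1000L, 1000L, 500L))
  expect_true(all(diff(b$covariate_mean) >= 0))

  const <- bin_by_covariate(r, rep(0.3, 2500), 1000)
  expect_equal(const$covariate_mean, rep(0.3, 3))

  # r2 increasing in MAF -> nondecreasing bin means
  mafs <- seq(0.01, 0.5, length.out = 3000)
  r2 <- sqrt(0.9 * mafs / (0.05 + mafs))
  bm <- bin_by_covariate(r2, mafs, 1000)
  expect_true(all(diff(bm$reliability_mean) >= 0))

  expect_equal(nrow(bin_by_covariate(numeric(0), numeric(0))), 0L)
})

test_that("per-individual beats per-SNP accuracy on simulated imputation", {
  d <- directional_results(101)
  expect_gt(d$mean_ind[["S40_lo"]], d$mean_snp[["S40_lo"]])
  expect_gt(d$mean_ind[["S80_hd"]], d$mean_snp[["S80_hd"]])
})
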