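map100 <- function(n = 10, spacing = 100L) marker_map("1", spacing * seq_len(n))

test_that("ascertainment keeps the eligible high-MAF markers", {
  map <- map100(10)
  # MAFs .4 .01 .4 .4 .01 .4 .4 .01 .4 .4 with 50 individuals
  g <- genotype_matrix(geno_with_counts(50, round(
    c(.4, .01, .4, .4, .01, .4, .4, .01, .4, .4) * 100)), map)
  p <- build_panel(map, g, maf_min = 0.05, target_count = 7)
  expect_equal(p$marker_indices, c(1L, 3L, 4L, 6L, 7L, 9L, 10L))

  ident <- build_panel(map, g, maf_min = 0, target_count = 10)
  expect_equal(ident$marker_indices, 1:10)

  expect_error(build_panel(map, g, maf_min = 0.05, target_count = 8),
               "short by 1")
})

test_that("panels are evenly spaced with MAF above the threshold", {
  n <- 1000
  map <- withr::with_seed(21, marker_map("1", sort(sample.int(1e6, n))))
  fr <- withr::with_seed(22, runif(n, 0, 0.5))
  g <- genotype_matrix(geno_with_counts(100, round(fr * 200)), map)
  p <- build_panel(map, g, maf_min = 0.1, target_count = 100)
  expect_length(p$marker_indices, 100)
  expect_true(all(maf(g)[p$marker_indices] >= 0.1))
  gaps <- diff(p$positions_bp)
  expect_lt(max(gaps), 3 * mean(gaps))
})

test_that("nested construction yields a subset panel", {
  sim <- small_sim()
  hd <- build_panel(sim$truth$marker_map, sim$truth, 0.1, 60, "hd")
  lo <- build_panel(sim$truth$marker_map, sim$truth, 0.1, 12, "lo",
                    within = hd)
  expect_true(all(lo$marker_indices %in% hd$marker_indices))
})

test_that("masking blanks exactly the non-panel markers", {
  map <- map100(3)
  g <- genotype_matrix(matrix(c(1L, 2L, 0L), 1), map)
  p <- panel_definition("p", c(1L, 3L), map)
  m <- mask_to_panel(g, p)
  expect_equal(as.vector(m$genotypes), c(1L, NA, 0L))

  ident <- panel_definition("all", 1:3, map)
  expect_equal(mask_to_panel(g, ident)$genotypes, g$genotypes)

  none <- panel_definition("none", integer(0), map)
  expect_true(all(is.na(mask_to_panel(g, none)$genotypes)))
})

test_that("masking never alters retained genotypes", {
  sim <- small_sim()
  p <- build_panel(sim$truth$marker_map, sim$truth, 0.1, 40)
  m <- mask_to_panel(sim$truth, p)
  expect_identical(m$genotypes[, p$marker_indices],
                   sim$truth$genotypes[, p$marker_indices])
  expect_true(all(is.na(m$genotypes[, -p$marker_indices])))
})

test_that("overlap percentages reproduce array-versus-sequence bookkeeping", {
  expect_equal(overlap_percentage(40492, 1737471), 2.33)
  expect_equal(overlap_percentage(3132, 1737471), 0.18)

  map <- map100(20)
  a <- panel_definition("seq", 1:20, map)
  b <- panel_definition("b", c(2L, 5L, 9L), map)
  rep_ <- panel_overlap_report(list(a, b))
  expect_equal(rep_$pairwise["seq", "b"], 3L)
  expect_equal(unname(rep_$pct_of_seq["b"]), 15)
  expect_equal(unname(rep_$pct_of_seq["seq"]), 100)

  same <- panel_overlap_report(list(b, b))
  expect_equal(same$pairwise[1, 2], 3L)
  expect_equal(unname(same$pct_of_seq[1]), 100)

  map2 <- marker_map("2", c(10L, 20L))
  c2 <- panel_definition("c", 1:2, map2)
  expect_error(panel_overlap_report(list(a, c2)), "different chromosomes")
})
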