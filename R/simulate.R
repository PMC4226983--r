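#' Configuration for the Wright-Fisher haplotype simulator
#'
#' The simulator stands in for real sequence data: a single chromosome in a
#' closed random-mating population whose size controls the extent of
#' linkage disequilibrium (expected pairwise r2 approximately
#' `1/(4*Ne*c + 1)` at genetic distance `c` Morgan).
#'
#' Mutation acts on a fixed lattice of `n_sites` candidate polymorphic
#' positions drawn uniformly along the chromosome (at most one mutation
#' event per site per generation, symmetric 0 <-> 1). The per-site rate is
#' `mutation_rate * chromosome_length_bp / n_sites`, so `mutation_rate`
#' keeps its per-base-pair meaning while the simulation stays tractable.
#'
#' @param population_size_diploid number of diploid individuals (>= 2);
#'   this is the effective size governing LD decay.
#' @param n_generations generations of discrete Wright-Fisher reproduction.
#' @param chromosome_length_bp chromosome length in base pairs.
#' @param mutation_rate per-base per-generation mutation probability.
#' @param recombination_rate_per_bp Morgan per base pair; the default 1e-8
#'   encodes the 1 Mb = 1 cM convention.
#' @param n_sample_individuals default sample size for [sample_diploids()].
#' @param n_sites number of candidate polymorphic positions tracked.
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(population_size_diploid = 100L,
                              n_generations = 1000L,
                              chromosome_length_bp = 1e7,
                              mutation_rate = 1.2e-7,
                              recombination_rate_per_bp = 1e-8,
                              n_sample_individuals = 60L,
                              n_sites = 10000L,
                              seed = 1L) {
  cfg <- list(
    population_size_diploid = as.integer(population_size_diploid),
    n_generations = as.integer(n_generations),
    chromosome_length_bp = as.double(chromosome_length_bp),
    mutation_rate = as.double(mutation_rate),
    recombination_rate_per_bp = as.double(recombination_rate_per_bp),
    n_sample_individuals = as.integer(n_sample_individuals),
    n_sites = as.integer(n_sites),
    seed = as.integer(seed)
  )
  if (cfg$population_size_diploid < 2L)
    stop("population_size_diploid must be at least 2")
  if (cfg$n_sample_individuals > cfg$population_size_diploid)
    stop("n_sample_individuals cannot exceed population_size_diploid")
  if (cfg$chromosome_length_bp <= 0) stop("chromosome length must be positive")
  if (cfg$mutation_rate < 0 || cfg$recombination_rate_per_bp < 0)
    stop("rates must be nonnegative")
  if (cfg$n_generations < 0L) stop("n_generations must be nonnegative")
  if (cfg$n_sites < 1L || cfg$n_sites > cfg$chromosome_length_bp)
    stop("n_sites must be between 1 and chromosome_length_bp")
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate a haplotype population by forward Wright-Fisher reproduction
#'
#' Founders carry allele 0 everywhere; variation builds up by symmetric
#' mutation and is reshuffled by recombination (per-transmission crossover
#' count Poisson with mean equal to the map length in Morgan, breakpoints
#' uniform on the genetic map). Monomorphic sites are retained; downstream
#' filters remove them where required.
#'
#' @param config a [simulation_config()].
#' @return A [haplotype_set()] with `2 * population_size_diploid`
#'   haplotypes. With `n_generations = 0` the founder matrix is returned
#'   with a warning, since it carries no LD structure.
#' @export
simulate_population <- function(config) {
  if (!inherits(config, "simulation_config"))
    stop("config must be a simulation_config")
  withr::with_seed(config$seed, {
    L <- config$n_sites
    pos <- sort(sample.int(config$chromosome_length_bp, L, replace = FALSE))
    map <- marker_map("1", pos,
                      morgan_per_bp = config$recombination_rate_per_bp)
    nh <- 2L * config$population_size_diploid
    haps <- matrix(0L, nh, L)
    if (config$n_generations == 0L) {
      warning("n_generations = 0: returning founder haplotypes ",
              "(no LD structure)")
      return(haplotype_set(haps, map))
    }
    map_len <- config$chromosome_length_bp * config$recombination_rate_per_bp
    mu_site <- config$mutation_rate * config$chromosome_length_bp / L
    pos_m <- map$pos_morgan
    N <- config$population_size_diploid
    for (g in seq_len(config$n_generations)) {
      parent <- sample.int(N, nh, replace = TRUE)
      first <- sample.int(2L, nh, replace = TRUE)
      nco <- stats::rpois(nh, map_len)
      child <- haps[2L * (parent - 1L) + first, , drop = FALSE]
      for (j in which(nco > 0L)) {
        bp <- sort(stats::runif(nco[j], min(pos_m), max(pos_m)))
        seg <- findInterval(pos_m, bp)
        odd <- seg %% 2L == 1L
        if (any(odd)) {
          other <- haps[2L * (parent[j] - 1L) + (3L - first[j]), ]
          child[j, odd] <- other[odd]
        }
      }
      nmut <- stats::rpois(1L, nh * L * mu_site)
      if (nmut > 0L) {
        site <- sample.int(L, nmut, replace = TRUE)
        hap <- sample.int(nh, nmut, replace = TRUE)
        keep <- !duplicated(site)  # at most one event per site per generation
        idx <- cbind(hap[keep], site[keep])
        child[idx] <- 1L - child[idx]
      }
      haps <- child
    }
    haplotype_set(haps, map)
  })
}

#' Sample diploid individuals from a haplotype population
#'
#' Draws `2n` haplotypes without replacement and pairs them consecutively;
#' the genotype at every site is the sum of the pair's alleles. The returned
#' object records which haplotype rows formed each individual so that
#' truth-based evaluations can recover reference haplotypes.
#'
#' @param haps a [haplotype_set()].
#' @param n number of diploid individuals to form (`2n` haplotypes needed).
#' @param seed integer seed.
#' @return A [genotype_matrix()] with `hap_index` back-references.
#' @export
sample_diploids <- function(haps, n, seed = 1L) {
  stopifnot(inherits(haps, "haplotype_set"))
  H <- nrow(haps$alleles)
  n <- as.integer(n)
  if (2L * n > H)
    stop("cannot form ", n, " diploids from ", H, " haplotypes")
  rows <- withr::with_seed(as.integer(seed),
                           sample.int(H, 2L * n, replace = FALSE))
  i1 <- rows[seq(1L, 2L * n, by = 2L)]
  i2 <- rows[seq(2L, 2L * n, by = 2L)]
  geno <- haps$alleles[i1, , drop = FALSE] + haps$alleles[i2, , drop = FALSE]
  genotype_matrix(geno, haps$marker_map,
                  ids = sprintf("ind%03d", seq_len(n)),
                  hap_index = cbind(i1, i2))
}

#' Haplotypes of sampled individuals
#'
#' Extracts the source haplotypes of a subset of individuals from the
#' population they were sampled from, e.g. to form an imputation reference.
#'
#' @param haps the [haplotype_set()] the individuals were drawn from.
#' @param genos a [genotype_matrix()] carrying `hap_index` back-references.
#' @param individuals indices of individuals in `genos`.
#' @return A [haplotype_set()] with two haplotypes per individual.
#' @export
individual_haplotypes <- function(haps, genos, individuals) {
  stopifnot(inherits(haps, "haplotype_set"), inherits(genos, "genotype_matrix"))
  if (is.null(genos$hap_index))
    stop("genotype matrix carries no haplotype back-references")
  idx <- as.vector(t(genos$hap_index[individuals, , drop = FALSE]))
  haplotype_set(haps$alleles[idx, , drop = FALSE], haps$marker_map,
                ids = haps$haplotype_ids[idx])
}
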