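---
title: "Evaluating imputation to sequence density and predicting per-SNP reliability"
author: "seqimp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating imputation to sequence density and predicting per-SNP reliability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqimp)
```

## The problem

Whole-genome sequencing a handful of key individuals and imputing everyone
else up from SNP-array genotypes is the standard route to sequence-level
genotypes in livestock. Whether that route is worth taking hinges on two
questions this package is built to study on controlled, simulated data:

1. **How accurate is the imputation**, as a function of the reference set
   size, the density of the typed panel, and whether imputation is staged
   through an intermediate panel?
2. **Can the per-SNP reliability be predicted in advance**, from quantities
   known without the true genotypes: distance to the nearest typed SNP,
   allele-frequency mismatch, the SNP's own minor allele frequency (MAF),
   and the number of reference individuals?

Accuracy is throughout the Pearson correlation $r$ between observed
genotypes (0/1/2 counts of the B allele) and imputed B-allele dosages
$0\,P(AA) + 1\,P(AB) + 2\,P(BB) \in [0,2]$; reliability is $r^2$.
Correlation is used rather than percent-correct because it does not reward
trivially "imputing" the major allele at rare variants.

## The synthetic population

Real sequence panels of this kind are access-restricted, so the package
generates its own study population with the statistical features the
analysis depends on:

* a single chromosome (default 10 Mb at the 1 Mb = 1 cM map convention,
  i.e. `morgan_per_bp = 1e-8`);
* a closed random-mating diploid population of effective size `Ne`
  (default 100, the order of magnitude of intensively selected cattle
  breeds), evolved by discrete Wright–Fisher reproduction: each
  transmitted haplotype is a parental mosaic with a Poisson(map length)
  number of crossovers at uniform genetic positions;
* symmetric $0 \leftrightarrow 1$ mutation on a fixed lattice of
  `n_sites` candidate positions drawn uniformly once per seed. The
  configured rate is per base pair; the per-site rate is
  `mutation_rate * chromosome_length_bp / n_sites`. Defaults
  (`mutation_rate = 1.2e-7`, `n_sites = 10000`, 1000 generations) give
  $\geq 2000$ segregating sites per run with per-site
  $\theta \approx 0.05$, so essentially every segregating site has a
  single mutational origin — the infinite-sites regime real sequence data
  occupies. A markedly higher per-site rate visibly erodes short-range LD
  through recurrent mutation and was avoided for that reason.

A forward simulator was chosen over a coalescent because the analysis
needs only one property to be right: linkage disequilibrium that decays
with genetic distance like $E[r^2] \approx 1/(4 N_e c + 1)$. The test
suite verifies this against that closed form, binned by distance and
averaged over five seeds, estimating $r^2$ on common variants
(MAF $\geq 0.2$) as is standard for LD-decay work — rare-variant pairs
have frequency-bounded $r^2$ (see the mismatch bound below) and drag
binned means below the drift expectation.

What the generator deliberately does **not** model: demography
(bottlenecks, migration, time-varying $N_e$ — a constant size is used even
though real populations fit short-range LD with historical, larger sizes),
multiple chromosomes, genotyping or sequencing error, and relatedness
structure beyond what random mating produces. Passing tests therefore
demonstrate correctness of the machinery under idealised LD, not
performance on any particular breed. Founders are monomorphic (allele 0
everywhere): requesting zero generations returns that founder matrix with
a warning, since it carries no LD and no variation.

## Panels and cross-validation

SNP arrays are not random marker subsets: they favour common, evenly
spaced variants. `build_panel()` emulates that ascertainment with a
windowed greedy rule — walk the chromosome in `target_count` equal
windows, take the highest-MAF marker with MAF $\geq$ `maf_min` in each,
and backfill empty windows from the largest remaining gaps. The rule
itself is this package's invention; what matters downstream is only that
panels are high-MAF and near-uniform. Nested tiers (low-density inside
intermediate inside sequence) are built by restricting a panel to its
parent's markers.

Validation follows a five-fold rotation: individuals are randomly split
into five near-equal groups, each validated once with its sequence
genotypes masked down to a panel. Scenarios differ in the reference set:
S80 uses the other four groups, S60 the three cyclically following
groups, S40 the two following groups (group 5 wraps to group 1). The
two-step design imputes low-density $\to$ intermediate against the two
following groups, hard-calls, then intermediate $\to$ sequence against the
two *preceding* groups, so the two references are disjoint. One random
partition per seed is reused across scenarios, enabling paired
comparisons on identical folds.

## The imputation engine

The engine is a diploid Li–Stephens haplotype-copying hidden Markov
model, not a re-implementation of any released imputation program. The
hidden state is an ordered pair of reference haplotypes; each chromosome
independently switches template across an interval of genetic length $d$
with probability $1 - e^{-\rho d}$ (uniform choice among all $H$
templates on a switch), and a typed genotype is observed through a
symmetric per-allele error channel. Forward–backward over the $H^2$ pair
states — $O(H^2)$ per marker via row/column sums, implemented in C++ —
yields posterior genotype probabilities, hence dosages. Typed markers are
reported as observed. Correctness is pinned by two independent oracles in
the test suite: a dense $H^2 \times H^2$ transition-matrix
forward–backward in plain R, and exhaustive enumeration of all
template-pair paths on tiny instances.

Defaults: `recombination_scale` $\rho = 100$ per Morgan (the simulated
population size; copying breakpoints track ancestral recombination) and
`error_rate` $10^{-3}$. There is no principled mapping from these to any
Beagle-style default, and none is claimed; both are plain arguments.

Two-step imputation passes most-likely genotypes (hard calls) between
stages, never dosages. Two design points deserve emphasis:

* **Anchor noise is estimated, not assumed.** Step-2 anchors at
  intermediate-only markers are imputed hard calls, not array reads. Their
  error rate is taken from the step-1 posteriors themselves, per
  individual and per marker: allele error $1 - \sqrt{P(\text{call
  correct})}$, floored at `error_rate`, capped at 0.49. Treating noisy
  anchors as near-certain observations (a constant $10^{-3}$) measurably
  degrades step 2, because step-1 errors come in locally correlated runs
  that then confidently mislead the copying model.
* **The overall output mixes step outputs.** Intermediate-only markers
  keep their step-1 posteriors, original panel markers stay observed, and
  only the remaining markers carry step-2 posteriors — mirroring how
  step-level and overall accuracies are conventionally reported
  (step 1 at hd-minus-lo markers, step 2 at sequence-minus-hd, overall at
  sequence-minus-lo).

Even so, the two-step advantage over direct low-density imputation is
*small* under an exactly inferred copying model — the historical gains of
staging were largely a property of haplotype-cluster imputation software
struggling with sparse panels. At this package's reference problem size
the paired two-step-versus-direct margin is a few thousandths to a
hundredth in mean $r$ and can flip sign at some seeds; the test suite
checks the direction at its three study seeds.

## Metrics and filtering

A correlation needs variation on both sides, so markers whose observed
genotypes *or* dosages are constant within **any** validation group are
removed before anything else; with five groups of ~12 this removes most
rare variants, which biases mean accuracy upward — a property inherent to
the metric, shared with the study design this package emulates, and worth
remembering when reading absolute numbers.

Per-SNP accuracy pools all validation individuals of a scenario (each is
validated in exactly one fold), because a per-fold correlation followed by
averaging would never give each SNP its full sample; per-fold values are
available by subsetting. Per-individual accuracy is computed across that
individual's evaluated markers in three modes: `raw`; `centered`
(subtract the per-marker mean observed genotype of the individual's fold
before correlating — removes the allele-frequency contribution that
inflates raw per-individual values); and `standardized` (additionally
divide by the per-marker observed standard deviation). Raw exceeds
centered exceeds standardized on typical data, and per-individual means
exceed per-SNP means — both directions are asserted in the tests.

Only imputed (non-panel) markers enter accuracy summaries; typed markers
would contribute exact 1s and, at simulation panel densities (10% of
markers rather than a real array's 2%), visibly inflate means.

## The reliability model

Three multiplicative components predict per-SNP reliability:

$$r^2_{total} = r^2_{dist} \times r^2_{dMAF} \times r^2_{MAF}$$

* $r^2_{dist} = 1/(4 N_e c + 1)$: drift–recombination LD decay at genetic
  distance $c$ (Morgan) to the chosen panel SNP. For predictions on real
  cattle-like data the appropriate $N_e$ is the historical one (~1000)
  because imputation-relevant distances are short; on simulated data the
  pipeline uses the simulated size. Both are plain parameters.
* $r^2_{dMAF}$: the upper bound on LD implied by a MAF mismatch
  $dMAF$. The source formula for this bound typesets ambiguously, so both
  parses ship as variants: `ratio_linear`
  $(1-2\,dMAF)/(1+2\,dMAF)$ — the default, reaching 0 at the maximal
  mismatch 0.5 — and `ratio_squared` $1 - 4\,dMAF^2/(dMAF+1)$. Reports
  must state the variant; the package never silently mixes them. The
  *exact* frequency bound is also provided (`max_r2_exact()`): maximising
  $D^2 / (p(1-p)q(1-q))$ over admissible disequilibrium in coupling and
  repulsion phase; e.g. MAFs 0.45 and 0.05 cap squared correlation at
  0.064 — reported to two decimals as 0.06, and notably a bound on $r^2$,
  not on $r$.
* $r^2_{MAF} = V_{max}\,\mathrm{MAF}/(K_m + \mathrm{MAF})$: an empirical
  Michaelis–Menten curve for the joint effect of the SNP's own MAF and
  reference size, fitted by nonlinear least squares (Levenberg–Marquardt,
  parameter tolerance $10^{-10}$, starts $V_{max} = \max$ observed
  reliability, $K_m =$ MAF nearest half of it) on *binned* means — bins of
  `bin_size` SNPs sorted by MAF (stable sort, ties by position; the last
  bin may be short). Binned fitting matches how such curves are
  conventionally estimated; raw per-SNP fitting is available by passing
  unbinned data. $K_m$ falls as the reference grows: rare alleles need
  more reference copies to be imputable.

Because the nearest panel SNP need not be the best-correlated one, the
product $r^2_{dist} \times r^2_{dMAF}$ is evaluated for the five nearest
panel SNPs and the best is kept (ties: smaller distance, then lower
position; chromosome ends simply have fewer candidates when the panel is
smaller than five).

## Numerical and tie-break conventions

* Forward and backward passes are rescaled per marker; posteriors are
  normalised per site (asserted to $10^{-9}$) and dosages tied to the
  probability triple to $10^{-12}$.
* Hard-call ties go to the heterozygote, then AA.
* Nearest-SNP distance ties go to the lower position.
* Percentages are rounded half-up to 2 decimals; accuracy-like values are
  reported to 3 decimals, rounded only at reporting time.
* Every stochastic step takes an explicit seed; the pipeline derives
  per-stage seeds from a master seed (`(master mod 2e7) * 100 + stage`),
  and rerunning a configuration reproduces every output byte for byte.

## Problem sizes

The reference study size used throughout the test suite is 60 diploid
individuals from an $N_e = 100$ population, 2000 candidate sites
(~1100 segregating), an intermediate panel of 200 and a low-density panel
of 20 markers, five-fold validation, three seeds — the scale at which all
scenario comparisons (S40/S60/S80, panel density, two-step versus direct,
per-individual versus per-SNP) are asserted. LD-decay calibration runs the
full default generator (10 000 candidate sites) over five seeds.
Michaelis–Menten recovery is checked by refitting 20 noisy replicates
(Gaussian noise, sd 0.02) of a known curve and requiring mean estimates
within 5%.

## Known limitations

* The copying model is exact but the reliability model is deliberately
  marginal: one panel SNP at a time, no haplotype context. Binned
  predictions rank observed reliabilities well (rank correlation > 0.8 in
  the tests) but are upward-biased at low $r^2_{total}$.
* The fixed-marker filter ties evaluated marker sets to the scenario, so
  means across scenarios compare slightly different marker sets —
  identical to the situation in real evaluations of this design.
* $V_{max}$ may legitimately exceed 1 slightly (it is an asymptote
  estimated from noisy bins, not a probability); the constructor warns
  outside $(0, 1.2]$.
* The simulator's unrelated, randomly mating population makes imputation
  *harder* than pedigreed livestock practice at equal reference size;
  absolute accuracies here underestimate what close relatives deliver.

## A minimal run

```{r, eval = FALSE}
cfg <- run_config(
  sim = list(n_sites = 2000L, n_sample_individuals = 60L),
  hd_size = 200L, lo_size = 20L, bin_size = 100L,
  out_dir = "demo_run", master_seed = 7L
)
res <- run_pipeline(cfg)
res$summary_per_snp   # scenario x panel accuracy table
res$mm_fits           # per-scenario Michaelis-Menten parameters
```

The same pipeline is scriptable from a shell through the thin CLI at
`inst/cli/seqimp` (subcommands `simulate`, `mask`, `plan`, `impute`,
`evaluate`, `fit-mm`, `predict`, `run-all`).
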