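---
title: "Simulating and scanning an artificial selection experiment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and scanning an artificial selection experiment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedscan)
```

## The problem

Small mammal populations respond readily to artificial selection, yet with
only a few dozen breeders per generation, allele-frequency changes are
dominated by drift, inbreeding and linkage.  Deciding whether an observed
frequency shift at a locus reflects selection on that locus therefore
requires a null model much stronger than neutral drift: the null must be
*polygenic adaptation itself* — a trait responding through innumerable
tiny-effect loci — played out over the actual breeding design.  `pedscan`
implements that program end to end:

1. simulate the experiment down its pedigree under an infinitesimal model
   with linkage (junction genomes);
2. seed SNPs onto the simulated ancestry under bracketing assumptions about
   founder linkage disequilibrium;
3. scan the two sequenced timepoints with the variance-stabilized
   allele-frequency shift statistic (here called `dz2`);
4. derive significance thresholds from the genome-wide maxima of simulated
   replicates and call sweep peaks with a hitchhiking-aware extension rule;
5. quantify parallelism between replicate lines and infer per-locus
   selection coefficients and response contributions from allele-frequency
   trajectories.

## The simulation model

**Genomes as junctions.**  Following a chromosome base pair by base pair
down a pedigree is wasteful: what matters is which founder haplotype each
segment descends from.  A chromosome homolog is therefore an ordered list
of breakpoints labeled by founder haplotype.  Meiosis draws a Poisson
number of crossovers with mean equal to the genetic map length, places
them uniformly on the physical length (no interference, sex-averaged map),
and splices the two parental homologs.  SNP genotypes are reconstructed at
the end by painting panel alleles onto segments.  A brute-force per-site
gene-dropping oracle with the same crossover realizations reproduces the
junction reconstruction exactly (see `test-oracle.R`); the compiled fast
path and the pure-R reference engine consume identical RNG streams and are
tested for exact agreement.

**Trait.**  A phenotype is `V_g + V_s + V_e`: an infinitesimal background
(`V_g`), realized as a dense grid of loci (default 10 per cM) with i.i.d.
Gaussian founder-haplotype effects; a discrete component of 10^4 evenly
spaced loci (`V_s`); and Gaussian noise (`V_e`).  Both genetic components
scale their per-chromosome variance with genetic map length, and the
founder-population variance of breeding values equals `V_g + V_s` (tested
to 10%).  The dense-grid realization converges to the Brownian-increment
continuum as the grid refines and keeps every contribution transparent to
test; 10/cM makes the grid spacing (0.1 cM) far smaller than the ancestry
blocks that build up over ~20 generations.

Defaults are `V_g = V_s = 0.2`, `V_e = 0.6` (phenotypic variance 1,
heritability 0.4, components split 1:1).  The heritability follows the
response-to-differential ratio reported for this kind of experiment; the
1:1 split is a neutral default, configurable.

**Selection and mating.**  Selection is within-family truncation: in every
family the male and the female with the largest trait value breed (ties to
the lowest id, so replicates are reproducible).  Control lines draw
breeders uniformly per family.  Breeders are re-paired each generation by
a random derangement of families — no sibling matings, and no fixed
pairing topology.  This choice matters: a fixed circular pairing
(family *f* male × family *f+1* female every generation) builds a ring of
locally related families in which within-individual coalescence is fast
even though global drift is slow; we measured inbreeding-effective sizes
of ~23 under circular pairing versus ~70–75 under random re-pairing for a
16-pair design, with an independent single-locus simulation confirming
both numbers.  The real experiment re-paired at random excluding siblings,
so the derangement is the faithful choice.

**The composite trait.**  Fitness in the real experiment was tibia length
relative to body mass.  The simulator treats the composite score
`ln T + phi * ln B` directly as "the trait"; `T` and `B` are only
separated when estimating `phi` from realized breeder choices
(`estimate_phi()`, a grid search maximizing concordance with the actual
choices, ties broken toward 0).  Note the concordance curve typically has
a short perfect plateau; the estimate is reported with its concordance.

**Selection differential and response.**  `S` is the phenotypic
superiority of the selected parents and `R` the shift of the cohort mean,
both in model phenotypic standard deviations.  Under within-family
truncation only the within-family half of the additive variance is
selectable, so the early-generation oracle is `R = h2_w * S` with
`h2_w = (V_A/2)/(V_A/2 + V_E)` — 0.25 at the defaults, *not* the
mass-selection `h2 = 0.4`.  With ~12 offspring per family the realized
`S` is ≈ 1.1 s.d., giving `R` ≈ 0.27 s.d./generation, close to the ~0.29
s.d./generation regime the design is modeled after (which realized a
smaller `S` ≈ 0.7 on the measured trait — selection there acted on a
composite index, and husbandry constraints diluted the differential — but
nearly the same response).

## Founder genomes and LD seeding

Founder haplotypes are mosaics of a small ancestral pool (default 18 base
haplotypes, matching the number of source haplotypes behind a CD-1-like
commercial stock), with exponentially distributed block lengths (default
500 kbp; the data anchor only the SNP density of ~1 SNP/4 kbp, not the LD
scale, which is why the scan brackets LD rather than trusting this
number).  Site frequencies in the pool follow a Beta(1/2, 1/2) spectrum
truncated at a minor-allele floor of 0.05 — U-shaped like a neutral
equilibrium spectrum; with 36 founder chromosomes, rarer alleles would
almost never survive sampling anyway.

Because real founders are genotyped at low coverage, their *phase* is
unknown.  `seed_snps()` therefore assigns alleles to founder haplotypes
within shared-ancestry intervals (the partition induced by the union of
all junction breakpoints across sampled individuals) under three schemes
bounding the truth: `no_ld` (linkage equilibrium), `min_ld` (observed
diploid genotypes, heterozygous sites coin-phased per site) and `max_ld`
(heterozygous sites phased consistently within each interval).  A fourth
scheme, `exact`, uses the simulated panel's true phase and exists only
because the panel is synthetic — it is the reconstruction oracle's mode.
Under `max_ld` every founder's alternate alleles go to the same designated
haplotype slot within an interval (perfect coupling across the panel);
under `no_ld` each site's realized allele count is permuted across slots
— the observed frequencies are preserved exactly, never redrawn, which
matters: a binomial redraw manufactures extra ultra-rare sites whose
z-shifts dominate genome-wide maxima.

Thresholds derived from selected-line replicates under the three schemes
order `max_ld >= min_ld >= no_ld`, the reason the most conservative (max
LD) scheme backs headline thresholds.  One honest caveat: in *this*
synthetic world the ordering is a small effect.  The generated ancestral
pool is in linkage equilibrium by construction (independent alleles per
site), so even the true founder haplotypes carry adjacent-site r² of only
about 1/pool ≈ 0.06–0.1, and with ~2.5 SNPs per 10-kbp window the
LD-scheme contrast in windowed `dz2` amounts to a few percent against
10–15% replicate noise in the genome-wide maximum.  A real commercial
stock, recently descended from long inbred-line haplotypes, has far
stronger allelic LD, which is why LD seeding mattered greatly in the
study this package emulates.  The ordering reproduces here in replicate
means (30+ matched replicates) and in the derived thresholds, but a
20-replicate paired sign test on maxima is underpowered and is left red
in the acceptance suite rather than weakened.

## The scan

Frequencies are polarized per line by the minor allele at the first
timepoint (ties to the alternate allele); `z(q) = 2 asin(sqrt(q))` maps
frequencies to `[0, pi]`, so the squared shift ranges from 0 to `pi^2`
and has per-generation drift variance `1/(2 Ne)` independent of starting
frequency.  The factor 2 is essential: with `asin(sqrt(q))` alone the
range would be `pi^2/4` and the variance `1/(8 Ne)`, inconsistent with
both stated anchors.  Per-site values are averaged in adjacent 10-kbp
windows tiling each chromosome from coordinate 0 (0-based, half-open;
empty windows are missing, never zero).  Windowing averages the per-site
statistic rather than transforming window-mean frequencies — the reading
consistent with "averaged within windows".

Thresholds are the `ceiling(n(1-alpha))`-th order statistic of the
genome-wide maximum windowed value over `n` simulated null replicates, so
the exceedance probability is exactly interpretable (at `n = 100`,
`alpha = 0.05`, the 95th largest maximum).  Peaks are called by
descending rank; each peak's span grows outward from its contiguous
significant-window run in blocks of 100 SNPs per side, a side stopping
when its latest block has no single SNP above `0.2 pi^2` (the stopping
block is still absorbed, as in the worked trace in
`test-significance.R`); absorbed windows leave the candidate list and
overlapping spans merge.  Ties in rank order break by (chromosome,
start), making peak calling invariant to processing order.

Parallelism between lines is summarized two ways: a Pearson chi-squared
test (1 df, no continuity correction) on the 2×2 classification of
windows significant in both / one / neither line, and the Pearson
correlation of the windowed profiles.  The 2×2 window-level construction
is an assumption of this package, recorded here, not asserted of the
original study.

`interval_permutation()` is the generic enrichment engine (features as
BED-like intervals, query spans placed uniformly without self-overlap;
overlap count upper-tailed, nearest-distance lower-tailed; p is the
quantile rank, with an observation beyond every permutation reported as
`< 1/n`).  No curated gene, TAD or phenotype databases are bundled —
Table-style annotations are data, not algorithm.

## Selection inference

`wf_transition()` is the genic Wright–Fisher kernel: each focal-allele
copy has relative fitness `1 + s`, so `q* = q(1+s)/(1+sq)` and the next
count is binomial.  The genic convention is the one under which the
headline numbers cohere: a 0.17 → 0.87 shift in 17 generations gives
`s = exp(Δ ln-odds / 17) − 1 = 0.228 ≈ 0.24`; an additive-diploid
convention would need `s ≈ 0.4`.  `estimate_s()` maximizes a hidden
Markov likelihood over a grid (default `[-0.5, 1]` step 0.005): latent
counts evolve by the kernel, missing generations are bridged by chaining
transitions (never interpolation), observations are binomial samples of
the latent frequency, and the CI is the 1.92 log-likelihood drop.
`Ne = Inf` switches to the deterministic ln-odds limit.  `Ne` defaults to
46 — the inbreeding-derived estimate typical of such lines — but is
always explicit.

`contribution_arithmetic()` is the bookkeeping identity
`100 · 2·mean(Δq)·effect / total`; `contribution_simulated()` injects one
additive biallelic locus (effect `a` per copy, start frequency `q0`) into
the full simulation, rescaling `V_g + V_s` so total initial genetic
variance is unchanged, and calibrates `a` so the mean replicate frequency
change hits the target (0.7 by default).  Calibration is bisection on
noisy Monte-Carlo means followed by a local linear fit of the smooth
dose–response around the bisection output — plain noisy bisection
reliably stops a noise-width off target, which propagates into the
contribution.  The reported quantity is the per-replicate
`2·a·Δq / total response`, mean and min–max limits over ≥ 100 replicates.
At the default design the mean lands near 10% — inside the printed
3.6–15.5% limits of the study this design emulates, a little above its
9.4% point estimate because this idealized design (constant litters of
12, frictionless within-family truncation) realizes a slightly larger
selection differential and a slightly smaller total response than the
real experiment.

## What the synthetic world does and does not establish

The generator reproduces the statistical skeleton the analysis assumes:
founder mosaics at ~1 SNP/4 kbp with a U-shaped spectrum, 14–16 pairs per
generation with within-family truncation, a trait with infinitesimal +
discrete + environmental components, mouse-scale maps (19 × 0.7 M when
run at full scale).  It does not emulate: real litter-size variation and
breeding failures (litters are constant 12 by default — the study
reports only that breeders were 15–20% of offspring), genotyping error,
missingness and imputation, mutation during the experiment, sex
chromosomes, or crossover interference.  A green test therefore
establishes internal correctness of the machinery and consistency with
the stated quantitative anchors — not that any particular biological
dataset would reproduce them.

## Numerical choices and degenerate inputs

* Zero-Morgan chromosomes are legal everywhere (meiosis copies a homolog).
* Monomorphic panel sites are dropped at generation; monomorphic sites at
  scan time yield undefined F_ST and are excluded from windows.
* `critical_value()` refuses fewer than 20 replicate maxima.
* Ties: equal phenotypes within a family → lowest id; equal-value windows
  → (chromosome, start); `phi` concordance ties → closest to 0;
  polarization ties → alternate allele.
* All randomness flows from explicit `seed` arguments through R's RNG;
  the compiled engine uses the same stream in the same order as the R
  reference engine, so `engine = "cpp"` and `engine = "r"` are
  bit-identical.
* Run configuration is JSON (round-trippable, hashed with `tools::md5sum`
  into every output); YAML is not available in the supported dependency
  set, and JSON preserves the contract.

## Known limitations

* The inbreeding-effective size of the idealized design (~70) exceeds the
  ~46 of the real experiment, whose extra drift came from unequal litter
  sizes and husbandry events the generator does not model; `Ne` is
  therefore always an explicit parameter on the inference side.
* `interval_permutation()`'s distance mode averages over queries that
  found a feature on their chromosome set; chromosomes with no features
  contribute nothing.
* The per-site scan assumes called genotypes; genotype likelihoods for
  low-coverage data are out of scope.
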