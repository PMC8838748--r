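---
title: "Methods: pooled time-series analysis of clonal evolve-and-resequence experiments"
author: "poolER"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled time-series analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolER)
```

# The setting

`poolER` analyzes pooled population sequencing (pool-seq) time series from
replicated experimental evolution of clonal organisms. The reference
design it emulates is a Chlorovirus PBCV-1 population coevolving with its
algal host *Chlorella variabilis* in chemostats: a ~330 kb double-stranded
DNA genome, six independent replicates split over two demographic regimes
(roughly constant population size versus strong periodic fluctuations),
five sequencing time points per replicate over ~75 viral generations
(experiment days 12–64), and ~1000× mean pooled coverage. PBCV-1 blocks
superinfection of a host cell, so recombination between virions is
negligible and the population evolves clonally: selection on any locus
drags the whole genome along, and no genuine polymorphism should sit at a
constant frequency while directional selection acts.

Two consequences shape the whole pipeline:

1. **Frequencies, not genotypes.** Each library is a population pool;
   per-site ref/alt read counts estimate allele frequencies. An estimate
   is only trusted at ≥ `min_depth` (default 10×) total reads, and an
   untrusted estimate is *missing*, never zero — "no data" and "allele
   absent" are deliberately distinct states in the data model.
2. **Constancy is pathology.** Under clonal directional selection a
   variant whose frequency never moves, or one that is polymorphic in
   every library of a sequencing batch, is almost certainly a mapping or
   reference artifact rather than biology. The artifact filters are built
   directly on these two signatures.

# Data model

A `variant_table` holds biallelic SNP sites × pooled libraries of
ref/alt counts. Two different base changes at one position are two
distinct sites throughout (they are independent mutation events in
different replicates); multi-allelic caller records are decomposed
accordingly, with reads supporting non-focal alternatives assigned to the
reference count so each site's frequency refers to that base change
alone. Coordinates are 1-based inclusive everywhere. ORFs are
strand-aware, possibly multi-segment intervals; for the PBCV-1 naming
convention a trailing `R`/`L` in a gene name encodes rightward/leftward
transcription, used as a strand fallback when no explicit strand is given.

# Artifact filtering

`apply_filter_cascade()` computes four per-site flags *independently* (so
per-criterion removal counts are reportable; the retained set is the same
as for sequential application):

* **low_qual** — caller quality below `min_qual` (default 20).
* **excess_missing** — more than `floor(max_missing_fraction × n_samples)`
  missing frequency estimates (default 10%; with 35 libraries that is
  "more than 3").
* **constant_binomial** — per replicate, the pooled alternative
  proportion p̂ = Σalt/Σdepth is computed over the replicate's time
  points (ancestor libraries are excluded: frequency change "over time"
  is a within-replicate notion); each time point's count is then given a
  two-sided exact binomial p-value under Binomial(depth, p̂). All of a
  site's p-values, pooled over replicates and time points, form one
  Benjamini–Hochberg family; the site is removed iff no adjusted value
  falls below `fdr_alpha` (default 0.05). The per-locus family makes each
  verdict independent of which other sites happened to be called.
  The two-sided convention is *minimum likelihood* — the p-value sums
  the probabilities of all outcomes no more probable than the observed
  one (with the customary `1 + 1e-7` slack) — matching the default exact
  binomial test of mainstream statistical software. One consequence worth
  knowing: a site observed at a single informative time point can never
  reject constancy (its only observation defines p̂), so it is removed.
* **ubiquitous_polymorphic** — for each sequencing batch with at least
  two non-missing estimates, the site is flagged when *every* non-missing
  frequency lies in `(af_lower, af_upper]` (default (0.01, 0.99]).
  Requiring two observations is deliberate: a single library cannot
  establish "polymorphic across every population". The rule is evaluated
  per batch because batch-specific library chemistry produces
  batch-specific artifacts; running all libraries as one batch is
  available by giving them one `batch_id`.

The false-positive behavior of the constancy filter is a property, not an
assumption: on simulated constant-frequency sites with binomial read noise
at 1000×, the fraction escaping removal is well under the nominal 0.05
(the test is conservative because p̂ is estimated from the same counts,
and because BH operates on discrete exact p-values). The test suite and
the acceptance script measure it on 1000 simulated sites.

# Population statistics

**Diversity.** Expected heterozygosity per library is
π = Σ 2p(1−p) / `L_eff` over sites with a frequency estimate. `L_eff`
(default 3×10⁵) is the number of reliably evaluated genomic sites; it
normalizes π so that libraries with different numbers of called variants
are comparable. A fixed derived allele (p = 1) counts as a polymorphic
site (frequency > 0) but contributes nothing to π.

**Effective selection coefficient.** `selection_coefficient()` returns
s_eff = ln(f_end/f_start)/Δg — the average extra per-generation log
growth of the allele's frequency relative to a lineage whose frequency
stays constant. It is a *normalized measure of frequency change*, exact
for the Malthusian selection coefficient only while both frequencies are
far from 1; near fixation it understates s (the log-odds variant, which
does not saturate, is available via `form = "logit"`). Frequencies below
`f_floor = 0.002` — the variant caller's detection threshold — are
floored, giving alleles absent at the first time point a finite, floored
estimate rather than ±∞. Day spans convert to generations at
`gen_per_day = 75/52` by default (seventy-five generations over the
52-day window), configurable.

**Repeatability.** The number of replicate endpoints (each replicate's
last sequenced time point) where the site segregates at frequency > 0.
`class_comparison()` contrasts synonymous versus non-synonymous SNPs:
repeatability by a Mann–Whitney test, mean s_eff by a Welch t test.
Intergenic and start/stop-codon changes are excluded from these contrasts
because predictions about their average fitness effects are less clear.
The Mann–Whitney implementation enumerates all label arrangements exactly
when n+m ≤ 12 (mid-ranks for ties; the two-sided p counts arrangements
whose U deviates from its null mean at least as much as observed) and
otherwise uses the tie-corrected normal approximation. "t-test" means
Welch (unequal variances, Satterthwaite df) throughout: on the shipped
endpoint diversity summaries the Welch form gives P ≈ 0.13 where a
pooled-variance test would give ≈ 0.10, and the Welch convention is the
one the headline value reproduces. The treatment contrast on endpoint
polymorphic-site *counts* is the Wald z test of the group coefficient of
a two-group Poisson log-linear model: β = ln(mean_b/mean_a), SE =
√(1/Σa + 1/Σb) — identical to `glm(..., family = poisson)` because the
group totals are sufficient.

# Effect classification and the mutational null

`classify_variants()` is a codon-level reimplementation of variant-effect
annotation for a compact intron-free genome, using the standard genetic
code (the PBCV-1 reference annotation uses translation table 1). For
each ORF covering a position the position is mapped through the ORF's
segments to a coding coordinate (reverse-complemented on the minus
strand), the codon is mutated, and the amino acids compared. Precedence
within a codon: stop_gained and stop_lost are recognized first, then any
codon-1 change destroying the ATG is start_lost (so ATG→TAG at codon 1
reports stop_gained — a deterministic, documented choice), then
synonymous/nonsynonymous by amino-acid identity. Overlapping ORFs are
resolved by severity (start/stop changes > nonsynonymous > synonymous)
with ties broken by the lowest ORF start, so every SNP gets exactly one
class. ORFs whose length is not a multiple of 3 are excluded from codon
classification (with a warning) but still count in the enrichment scan.
Upstream-ATG creation ("start gained") is not modeled — there is no UTR
model for this genome.

The null spectrum enumerates **all** 3 × genome_length possible SNPs and
classifies each, giving the effect distribution expected under a uniform
per-position mutation probability. `spectrum_test()` compares empirical
versus null counts with Pearson's X² and a Monte-Carlo p-value
(fixed-margin table resampling, add-one estimator
`(1 + #{X²_sim ≥ X²_obs})/(n_mc + 1)`, seeded); the add-one estimator is
the standard unbiased-conservative choice for resampling tests, and the
Monte-Carlo route is used because the empirical total (tens of SNPs) is
far too small for the asymptotic X² distribution. Because reporting
granularity of start/stop changes varies between analyses, spectra can be
exported both with the three fine start/stop classes and with them lumped
(`lump_start_stop()`).

# ORF enrichment scan

For each ORF the 2×2 table
`[[m_orf, L_orf − m_orf], [m_total − m_orf, L_G − L_orf − (m_total − m_orf)]]`
contrasts variable versus invariant sites inside versus outside the ORF.
`p_raw` is the one-sided enrichment tail P(X ≥ m_orf) of the
hypergeometric distribution — identical to one-sided Fisher — because the
scan's question is "more variation than gene length predicts", not
"different". Holm correction runs over the family of *all* ORFs tested
(812 for the PBCV-1 annotation); both raw and corrected values are
emitted. The genome-length denominator is the full reference length
(330,611 bp), not the smaller reliably-evaluated count used for π: the
contingency table is about genomic positions, not about evaluable
coverage. A site inside overlapping ORFs counts for each of them.
`m_total` defaults to the number of distinct input positions; for the
shipped PBCV-1 summaries that is 68 — the 67 sites inside the eighteen
variant-carrying ORFs plus the single intergenic site — and with that
configuration the scan reproduces the published Holm-corrected values
(0.52 for *A078R*, 0.005 for *A140/145R*) and finds exactly the three
hotspot genes. `neighbor_counts()` reports, per focal SNP, how many SNPs
(including itself) lie within 500 bp, the clustering summary behind
hotspot visualization.

# The Wright–Fisher generator

`simulate_wf()` implements genotype-class Wright–Fisher dynamics without
recombination: the population starts isogenic; a genotype class carrying
mutations with selection coefficients s₁…s_k has fitness `exp(Σ sᵢ)`;
next-generation class counts are multinomial at the generation's
population size with probabilities ∝ count × fitness; mutations arrive as
Poisson(N·µ·L) per generation, each at a uniformly drawn unused site on a
parent class drawn by frequency. Site frequencies derive from class
composition. Everything is reproducible from one seed.

Parameterization choices, with reasons:

* **Fitness is log-additive (`exp(Σs)`), i.e. Malthusian.** The package's
  estimator s_eff is a per-generation log frequency ratio; with w = eˢ
  the deterministic-limit trajectory is *exactly* the logistic
  f_g = f₀e^{sg}/(1−f₀+f₀e^{sg}), the closed form the test suite checks
  to 10⁻¹⁰, and s_eff recovers s without parameterization bias in the
  exponential phase. With w = 1+s both statements hold only to O(s²).
* **Desk-scale population size.** The defaults use N = 10⁵ (crashing to
  N×10⁻³ in the strong-demography regime) rather than the experimental
  census ~10¹⁰: at 10¹⁰ the frequency dynamics of selected alleles are
  deterministic to far below sequencing noise, so simulating them
  stochastically adds nothing but cost; a deterministic-limit mode
  (`deterministic = TRUE`) covers the infinite-N case exactly.
* **Demography as stylized crashes.** Strong demography is modeled as a
  crash to `N_min` every `bottleneck_period` (default 15) generations
  with instant regrowth — a stylization of predator–prey population-size
  fluctuations, which are not themselves modeled. The generator
  demonstrably reproduces the expected direction of the demographic
  effect (bottlenecked replicates end less diverse than constant-size
  ones under identical seeds; a sign-test property in the suite).
* **Mutation:** one new site per mutation event, no back mutation —
  double hits per site are negligible while µ × generations ≪ 1.
* **Sequencing:** per (site, library), depth ~ Poisson(`depth_mean`,
  default 1000) and alt reads ~ Binomial(depth, f(1−e) + (1−f)e) with
  symmetric error e = 10⁻³. Caller behavior is *not* modeled: simulated
  sites get a fixed high QUAL, and no detection threshold is applied to
  the simulated counts. A consequence visible in examples: at 1000× a
  truly absent allele still draws ~1 error read, so naive "frequency > 0"
  presence calls on raw simulated counts overcount; the real pipeline's
  caller imposes a ~0.2% detection floor that the generator leaves to the
  analysis side (`f_floor`).

`standard_scenario()` freezes the benchmark used for filter
operating-characteristics: 20 sweep sites distributed over six founding
beneficial haplotypes (one per replicate, s = 0.1 per site, f₀ = 10⁻³,
each site carried in two replicates — co-segregating sites on one
haplotype are exactly what clonal hitchhiking produces), plus 20
constant-frequency artifacts (one latent frequency per replicate, counts
binomial around it) and 20 batch-wide artifacts (one mid-band latent
frequency per sequencing batch). With no recombination and strong
selection the sweeps move fast and far, the artifacts by construction do
not, and the cascade separates them essentially perfectly.

**Selection-coefficient recovery** is validated in the exponential phase:
one site with true s = 0.10 injected at f₀ = 0.01, sampled at
generations 0 and 30, N = 10⁵, 1000×. The window matters: s_eff is a log
*frequency* ratio, so once the allele approaches fixation the measure
saturates (the deterministic value over 0→30 generations is 0.094, over
0→75 it would be far lower although the allele is still the same s = 0.10
allele); requiring a detectable starting frequency at 1000× while staying
exponential selects a window like 30 generations. The suite checks the
median estimate over 50 seeded runs against ±20% of the truth.

# Shipped summary tables

`inst/extdata` contains two small TSVs transcribed from the published
PBCV-1 coevolution experiment's printed summaries: the eighteen
variant-carrying ORFs (coordinates on NC_000852.5, lengths, per-ORF
variable-site counts) and the six per-replicate endpoint summaries
(polymorphic-site counts and nucleotide diversities by treatment). They
drive `pbcv1_annotation()` / `pbcv1_snp_positions()` (the enrichment-scan
configuration: 812 ORFs — the eighteen real ones plus inert zero-count
fillers whose coordinates cannot matter because m_orf = 0 forces p = 1 —
330,611 bp, 68 genome-wide sites) and the treatment-comparison
reproductions. Note one bookkeeping subtlety: the per-ORF counts sum to
67 unique SNPs *inside ORFs*, and the single intergenic site brings the
genome-wide distinct-position total to 68, which is the `m_total` under
which the published Fisher/Holm values reproduce.

# Problem sizes and runtime

The default test suite runs in about a minute on one CPU: the exhaustive
oracle comparisons use toy genomes of a few hundred bp (every possible
SNP against a whole-CDS-translation oracle), the fixation-probability
check uses 4000 Wright–Fisher runs at N = 100, the false-positive-rate
check uses 1000 simulated constant sites at 1000×, and the cascade
benchmark uses five seeds of the standard scenario. The full-genome-scale
smoke test (330,611 bp, 812 ORFs) exercises only generation and
validation, not exhaustive classification. These sizes are the package's
chosen trade-off between statistical resolution and a test suite that
runs everywhere quickly; all of them are parameters, not limits.

# Known limitations

* The generator models neither coevolutionary host dynamics, infection
  kinetics, burst-size offspring variance, nor read-level artifacts; its
  artifact variants are *statistical* stand-ins (constant latent
  frequency; batch-shared latent frequency) for the mapping pathologies
  the filters target. Passing the filter ROC on simulated data therefore
  shows the filters implement their definitions, not that the definitions
  capture every real artifact.
* The effect classifier covers point mutations in annotated CDS only: no
  splice sites, UTRs, frameshifts, or upstream-start creation.
* s_eff is a descriptive, floored, saturating measure — not a likelihood
  estimator of s; no confidence intervals are attached.
* The constancy filter's power depends on coverage and the number of
  time points; at a single informative time point it removes the site by
  construction.
* With three replicates per treatment, the treatment comparisons have
  little power; they are reproductions of the published summary
  statistics, not new inference.
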