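# poolER

Pooled time-series genomics for evolve-and-resequence (E&R) experiments
with clonal organisms.

`poolER` analyzes pooled whole-population sequencing (pool-seq) time series
of the kind produced by replicated experimental-evolution studies: several
independent populations, each sequenced at a handful of time points at high
coverage, with per-site alternative/reference read counts standing in for
allele frequencies. The package was built around a replicated Chlorovirus
PBCV-1 / *Chlorella variabilis* chemostat coevolution design (a ~330 kb
clonal dsDNA virus, six replicates under two demographic regimes, ~75
generations at ~1000× pooled coverage), but every stage is generic.

It is aimed at researchers running E&R studies on viruses or other clonal
microbes who need to (1) separate genuine de-novo variants from
pooled-sequencing artifacts, (2) quantify selection and repeatability of
genomic change, and (3) ask which genes collect more variation than gene
length alone predicts.

## What it computes

**Artifact filtering** (`apply_filter_cascade()`). Three bespoke
post-calling filters remove spurious pooled variant calls:

* *Missing data*: a site is removed when more than
  `floor(0.10 × n_samples)` libraries lack a frequency estimate (an
  estimate requires ≥ 10× coverage).
* *Binomial constancy*: in a clonal population under directional
  selection, no genuine polymorphism should hold a constant frequency. Per
  replicate, the pooled proportion p̂ = Σalt/Σdepth is estimated and each
  time point's alternative count is tested against Binomial(depth, p̂)
  (two-sided exact test, minimum-likelihood convention). The site's tests
  are Benjamini–Hochberg adjusted; a site with no adjusted p < 0.05
  anywhere shows no evidence of frequency change and is removed as an
  artifact.
* *Batch-wide polymorphism*: a site whose frequency estimate lies in
  (0.01, 0.99] in **every** library of a sequencing batch is removed —
  genuine variants are not polymorphic everywhere; duplications and
  complex regions are.

**Population statistics** (`diversity()`, `selection_coefficient()`,
`repeatability()`, `class_comparison()`):

* expected heterozygosity π = Σ 2p(1−p) / L_eff, with L_eff = 3×10⁵
  reliably evaluated sites by default;
* the effective selection coefficient s_eff = ln(f_end/f_start)/Δg — the
  per-generation log frequency ratio, i.e. the extra growth of a lineage
  relative to one whose frequency stays constant (frequencies below the
  detection floor 0.002 are floored);
* repeatability = the number of replicate endpoints where a SNP
  segregates at frequency > 0;
* treatment comparisons: Welch t on endpoint diversity, Wald test of a
  two-group Poisson log-linear model on endpoint polymorphic-site counts,
  Mann–Whitney / Welch comparisons of repeatability and s_eff between
  synonymous and non-synonymous SNPs.

**Effect classification** (`classify_variants()`, `null_spectrum()`,
`spectrum_test()`). A codon-level classifier (standard genetic code,
strand-aware, multi-segment ORFs) labels each SNP intergenic / synonymous /
nonsynonymous / start_lost / stop_gained / stop_lost; the exhaustive null
spectrum classifies **all** `3 × genome_length` possible SNPs, and a
Monte-Carlo Pearson chi-squared test compares the observed spectrum against
that mutational null.

**ORF enrichment** (`orf_scan()`, `neighbor_counts()`). Per ORF, a
one-sided Fisher's exact test (hypergeometric tail) on the 2×2 table of
variable vs invariant sites inside vs outside the ORF, Holm-corrected over
all ORFs tested.

**Synthetic data with ground truth** (`simulate_experiment()`,
`standard_scenario()`). A clonal (recombination-free) genotype-class
Wright–Fisher simulator with constant or periodically crashing population
size, Poisson mutation supply, founding haplotypes, Poisson-depth binomial
pool-seq noise, and injected constant-frequency / batch-wide artifact
variants — so every pipeline stage can be tested against known truth.

## Worked example

Simulate the standard benchmark scenario (six replicates, five time points
at 1000×; 20 selective sweeps riding founding haplotypes plus 20
constant-frequency and 20 batch-wide artifacts), filter it, and summarize:

```r
library(poolER)

sim  <- standard_scenario(seed = 42)
sim$table
#> variant_table: 60 site(s) x 35 sample(s), min_depth = 10
#>   missing allele-frequency estimates: 0.0%

casc <- apply_filter_cascade(sim$table, filter_config())
n_sites(casc$table)
#> [1] 20        # the 20 true sweeps; all 40 artifacts removed

diversity(casc$table, L_eff = 3e5)[endpoint_samples(casc$table$samples), ]
#>    sample_id n_polymorphic           pi
#> 5     R1_d64            16 1.274046e-07
#> 10    R2_d64            16 1.670075e-07
#> 15    R3_d64            15 1.942484e-07
#> ...
```

`n_polymorphic` counts sites with endpoint frequency > 0 and `pi` is the
per-site expected heterozygosity; at 1000× coverage a handful of
sequencing-error reads can make a site "present" at ~10⁻³ frequency, which
is why counts exceed the sweeps truly carried by each replicate.

Scan the shipped PBCV-1 summary annotation (18 ORFs with observed
variation among 812 total, 330,611 bp, 68 genome-wide variable sites) for
variation hotspots:

```r
scan <- orf_scan(pbcv1_snp_positions(), pbcv1_annotation())
subset(scan, significant)[, c("orf", "length", "m_orf", "p_holm")]
#>          orf length m_orf       p_holm
#> 8  A122/123R   4032    14 8.505701e-11
#> 9  A140/145R   3384     7 5.325057e-03
#> 17     A540L   3771    20 5.232682e-20
```

Three genes — *A122/123R* (minor capsid glycoprotein Vp260), *A140/145R*
(host-recognition spike protein Vp130) and *A540L* (conserved
virion-associated protein) — carry far more variable sites than their
length predicts under a uniform mutation probability.

A thin command-line wrapper over the same functions ships at
`inst/cli/pooler` (subcommands `simulate`, `filter`, `stats`, `effects`,
`enrich`).

## Vignette

`vignettes/pooled-timeseries-methods.Rmd` documents the statistical model
behind each stage, the tunable parameters and their defaults, what the
Wright–Fisher generator does and does not emulate, and the numerical
conventions (exact-test definitions, FDR/FWER families, floors and
tie-breaks).
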