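---
title: "Inter-sex F_ST from pooled read counts: model, filters and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inter-sex F_ST from pooled read counts: model, filters and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexfst)
```

## The problem

Homomorphic sex chromosomes leave no cytological signature. In *Aedes*-like
systems a dominant male-determining locus (M) sits on an ordinary-looking
autosome; recombination suppression around it lets an X-like and a Y-like
haplotype diverge. Because every male is heterozygous (Mm) for the divergent
region while females are homozygous, two population-genetic signals mark the
proto-Y: allele frequencies at divergent sites differ between male and
female samples of the same population (high inter-sex F_ST), and male
expected heterozygosity is locally elevated. With pooled sequencing, allele
frequencies are estimated from read counts rather than genotypes, which
makes the analysis cheap but adds sampling layers that the filtering and
calibration below address.

## Estimator

For SNP $s$, the variant-allele frequency of group $k$ is the read-count
ratio $\hat p_{k,s} = c_{k,s}/C_{k,s}$ (variant-base coverage over total
A/C/G/T coverage; indel reads are excluded throughout). With
$\alpha_{k,s} = 2\hat p_{k,s}(1-\hat p_{k,s})$ and pool sizes $n_i, n_j$:

$$
b_s = \frac{n_i\alpha_{i,s} + n_j\alpha_{j,s}}{n_i+n_j-1},\qquad
a_s = \frac{4n_i(\hat p_{i,s}-\hat p_s)^2 + 4n_j(\hat p_{j,s}-\hat p_s)^2 - b_s}
           {2\,(2n_in_j/(n_i+n_j))},
$$

where $\hat p_s$ is the coverage-weighted combined frequency (exactly the
pooled-count ratio, not the unweighted mean of $\hat p_i,\hat p_j$). Then
$F_{ST}(s)=a_s/(a_s+b_s)$ and, over the $m$ SNPs of a gene,
$F_{ST}(g)=\sum a_s / \sum(a_s+b_s)$ — a ratio of sums, so high-variance
sites weigh more and a gene is not dominated by near-degenerate SNPs. The
same $\alpha$ is reported as per-sex Hardy–Weinberg expected heterozygosity;
its gene-wise aggregate is the arithmetic mean over the gene's retained SNPs
(the aggregation could equally be a median; the mean keeps the regional
t-test on its natural scale).

Structural facts used as test invariants: $b_s \ge 0$ always;
$a_s + b_s \ge 0$ whenever $n_i, n_j \ge 1$ (the harmonic-mean denominator
makes the $b_s$ coefficient positive); $F_{ST}(s) \le 1$ with equality
exactly when $b_s = 0 < a_s$. The fully sex-linked case — females fixed,
males heterozygous, $n_i=n_j=12$, equal coverage — evaluates in closed form
to $b_s = 6/23$, $a_s = 11/46$, $F_{ST} = 11/23 \approx 0.478261$, and
$a_s \to 1/4$, $F_{ST}\to 1/2$ as $n\to\infty$. Negative $a_s$ (hence
negative F_ST) is legal for similar frequencies and is reported unclamped;
clamping would bias gene sums.

```{r worked}
comp <- site_components(p_i = 1, p_j = 0.5, cov_i = 100, cov_j = 100,
                        n_i = 12, n_j = 12)
c(a = comp$a, b = comp$b, fst = site_fst(comp$a, comp$b))
```

### Choice of $n$

$n_i, n_j$ are the numbers of individuals behind the combined counts. With
12 mosquitoes per pool and two summed biological replicates per sex (distinct
individuals), 24 individuals contribute per group, so the default is
$n_i=n_j=24$; it is configurable, and the calibration runs below use 12 (one
pool's worth) when comparing against the 0.478 closed form, which is defined
at that size. The choice shifts the small-sample correction ($b_s/2n$ inside
$a_s$) and is second-order at these depths.

## Filtering

Raw readcount tables (one row per site; A/C/G/T/indel counts per replicate
library, header-discovered columns) pass through, in order:

1. **Coverage**: every replicate of both sexes needs total nucleotide
   coverage ≥ `min_coverage` (default 15, boundary inclusive).
2. **Replicate concordance**: at least one sex must show ≥ 1 read of a
   shared non-reference base in each of its replicate libraries. Demanding
   this of *both* sexes would delete every site fixed in one sex — precisely
   the fully sex-linked signal — so the one-group rule is the only coherent
   composition; a `concordance = "coverage"` switch implements the looser
   coverage-only reading.
3. **Pooling**: replicate counts are summed per sex (summation preserves
   count semantics for a count-ratio estimator; averaging would not).
4. **Monomorphic removal**: sites with 100% of both sexes' coverage on one
   identical base (equal to the reference or not) carry no signal and are
   dropped. Otherwise the designated variant is the non-reference base with
   the highest summed coverage, ties broken A < C < G < T, so multi-allelic
   sites collapse deterministically to ref-vs-major-variant for the
   estimator while full counts are retained in outputs.

The chain is idempotent, and the per-category bookkeeping (input =
low-coverage + discordant + monomorphic + retained) is always written.
Base-quality control is assumed upstream in the readcount producer; PCR
duplicates are deliberately not modeled.

## Inference layer

* `classify_high_fst`: gene flagged iff defined $F_{ST}(g) \ge 0.100$
  (inclusive). The threshold is a parameter; 0.100 is the conventional
  cut-off for this analysis.
* `male_hexp_test`: one-sided test of higher mean gene-wise male H_exp in a
  region (genes selected by midpoint). Default Welch unpaired; a
  paired-by-gene variant exists because male/female values come from the
  same genes — the paired test is sharper for shift alternatives but leans
  on the pairing being exchangeable under the null.
* `chromosome_enrichment` / `category_overrepresentation`: one-sided exact
  hypergeometric tails (identical to one-sided Fisher tests), computed via
  `phyper` and verified in the test suite against brute-force tail
  enumeration on every 2×2 table with margins ≤ 30. Raw p-values by default
  (mirroring how such scans are usually reported); Benjamini–Hochberg is an
  option.
* `between_population_fst`: the same estimator re-targeted at
  (population X, sex k) vs (population Y, sex k) after merging tables on
  shared sites, for female-vs-female / male-vs-male scans.
* `fit_beta`: method-of-moments beta shapes for the gene F_ST distribution,
  with a Kolmogorov–Smirnov distance reported as a *diagnostic only* — gene
  values share sites and are dependent, so the KS p-value is not a
  calibrated test.
* Regions default to whole chromosome 1 and its central third; the central
  third stands in for the M-proximal region when no coordinates are known,
  and any interval can be supplied.

## The generator

`sim_config()` / `scenario_presets()` emulate pooled exome sequencing of
12-mosquito male and female pools, two replicate libraries per sex, on three
chromosomes of 60 non-overlapping 2-kb genes with 5 SNPs each (900 sites —
sized so a full pipeline run takes well under a second and a 100-run
calibration stays in the minutes). Sampling layers, per replicate and site:

1. finite-pool resampling: $2\times\text{pool\_size}$ allele copies drawn
   binomially from the sex's true frequency (independent individuals per
   biological replicate) — skipping this would understate variance at
   $n=12$;
2. depth $\sim$ NegBin(mean 180, size 10) — overdispersed coverage with
   Table-like mean depth (261 for the high-diversity preset; the
   calibration runs use 150);
3. variant reads binomial at the pool frequency, then symmetric miscalls at
   rate $10^{-3}$ (Q30-filtered data) redistributed uniformly over the
   other three bases.

Background sites share one population frequency between the sexes, drawn
from Beta(0.2, 1.8): right-skewed, giving mean site H_exp ≈ 0.1 with median
≈ 0.02, the shape seen in exome-wide pool-seq heterozygosity summaries.
Inside the configured divergent region (central third of chromosome 1 by
default), each SNP becomes X–Y divergent with probability $d = 0.5$ — a
proto-Y is young, so only a fraction of region sites is assumed fixed
between haplotypes; divergent sites default to a fixed difference
($p_X = 0$, $p_Y = 1$, hence true female frequency 0 and male frequency
0.5), with partial divergence available via `x_freq`/`y_freq`. Presets:
`aaa_like` (clustered region, suppressed recombination), `senaae_like`
(region spanning 90% of chromosome 1, doubled background diversity, depth
261) and `null` ($d = 0$). One root seed drives deterministic child seeds
per stage; identical seeds give byte-identical tables.

What the generator does **not** emulate: linkage disequilibrium beyond the
region block structure, exome-capture bias, mapping artefacts, indel reads,
and unequal DNA contributions per individual. Passing calibration therefore
shows the estimator, filters and tests behave correctly under the stated
sampling model — not that real libraries are free of alignment- or
capture-induced artefacts.

## Calibration results computed by the suite

The acceptance tests and `scripts/acceptance.R` recompute, per run of 100
seeds (clustered preset at depth 150, $n = 12$): region sensitivity of the
0.100 flag (observed ≈ 96%; the miss rate is dominated by the
$(1-d)^{5}$ ≈ 3% of region genes that draw no divergent SNP), mean site
F_ST at truly sex-linked sites (≈ 0.48, against the 0.478 closed form), and
the male-H_exp excess test (rejects in essentially all runs in-region;
under the null preset the flag rate is ≈ 1% and rejections are rare — the
unpaired test is conservative there because male and female gene values are
positively correlated through shared sites). The chromosome-wide preset
spreads flagged genes over > 80% of chromosome 1 while the clustered preset
concentrates > 90% of its flags inside the configured region, reproducing
the qualitative contrast between the two architectures.

## Numerical conventions and degenerate inputs

* F_ST is undefined (NA, not an error) when $a_s + b_s \le 10^{-12}$;
  such sites still contribute their (0, 0) components to gene sums.
* Undefined gene F_ST is never flagged and is counted separately.
* Output tables print floats at 6 significant digits, rows ordered by
  chromosome then position/start; writing is deterministic and
  round-trippable by the package's readers.
* Coordinates are 1-based closed internally (the readcount convention);
  BED input is converted on parse, and interval membership is
  endpoint-inclusive.
* Fewer than 2 usable genes in a region yields an NA-p test result with a
  warning rather than an error, so batch scans keep running.

## Limitations

Single-replicate designs are not supported by the concordance filter (by
construction it needs ≥ 2 libraries per sex). The estimator is biallelic in
form; multi-allelic sites are collapsed rather than decomposed. No
multiple-testing correction is applied by default. The t-test operates on
gene-wise values that are not strictly independent along a chromosome;
regional p-values should be read as strength-of-signal summaries, which is
how the calibration treats them.
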