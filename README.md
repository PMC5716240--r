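# sexfst

Detecting sex-linked genomic differentiation from pooled sequencing read
counts.

In species with homomorphic sex chromosomes — such as *Aedes aegypti*, where
maleness is decided by a dominant M locus on chromosome 1 — the X and Y are
cytologically identical and cannot be found by karyotype. What betrays a
proto-Y is population genetics: when males are heterozygous (Mm) for a region
of suppressed recombination, allele frequencies at sites inside that region
differ systematically between male and female pools, and male expected
heterozygosity is elevated. `sexfst` implements the full analysis for
pool-seq data: per-SNP and gene-wise inter-sex F\_ST from read-count tables,
per-sex expected heterozygosity, the SNP filtering rules appropriate for
replicated pooled libraries, sex-linkage classification and regional tests,
and a synthetic pool-seq generator with configurable proto-Y architecture for
calibration. It is aimed at population genomicists working with pooled
(rather than individually genotyped) sequencing of sexed samples.

## The statistic

For SNP site *s* and groups *i*, *j* (females and males), with
variant-allele frequencies estimated as read-count ratios
(p̂ = variant coverage / total nucleotide coverage) and *n_i*, *n_j*
individuals per pool:

    alpha_k = 2 p̂_k (1 − p̂_k)                                  k ∈ {i, j}
    b_s  = (n_i alpha_i + n_j alpha_j) / (n_i + n_j − 1)
    a_s  = [4 n_i (p̂_i − p̂_s)² + 4 n_j (p̂_j − p̂_s)² − b_s]
           / (2 (2 n_i n_j / (n_i + n_j)))
    F_ST(s) = a_s / (a_s + b_s)

where p̂_s is the coverage-weighted combined frequency. For a gene *g* with
*m* SNPs the aggregate is the **ratio of sums**, not the mean of per-site
ratios:

    F_ST(g) = Σ a_s / Σ (a_s + b_s)

`alpha` doubles as the Hardy–Weinberg expected heterozygosity H\_exp
reported per sex. Genes with F\_ST(g) ≥ 0.100 are classified as
sex-associated; male H\_exp excess over a region is tested with a one-sided
t-test, chromosome enrichment of flagged genes with one-sided Fisher's exact
tests, and functional-category over-representation with exact hypergeometric
upper tails.

## Worked example

The `analysis/` scripts are numbered drivers over the package. Starting from
a simulated clustered proto-Y dataset (180 genes on 3 chromosomes, 900 SNPs,
male/female pools of 12 in 2 replicates):

```r
library(sexfst)
cfg    <- scenario_presets("aaa_like", seed = 42)
sim    <- run_simulate(cfg, "scratch/sim/aaa_like")
counts <- parse_readcounts(sim$paths$readcounts,
                           list(female = c("F1", "F2"), male = c("M1", "M2")))
st <- run_sites(counts)                      # filter + per-SNP F_ST
gn <- run_genes(st$sites, sim$genome$genes)  # gene-wise ratio of sums
tst <- run_tests(gn)                         # classification + tests
```

which prints, via `analysis/02_site_gene_fst.R` and
`analysis/03_sexlink_tests.R`:

```
== aaa_like ==
  input                     900
  no_concordant_variant     480
  retained                  420
  genes with >= 1 SNP       171
  flagged genes (F_ST >= 0.100): 19 of 171
  chr1 enrichment: 19/59 flagged, one-sided p = 1.8e-10
  central-third male H_exp 0.409, male>female t-test p = 3.29e-13
```

480 low-frequency background sites fail replicate concordance (a shared
non-reference read in both libraries of at least one sex); of the retained
420 SNPs, the genes exceeding the 0.100 cut-off sit almost exclusively in
the simulated divergent region of chromosome 1, chromosome 1 is strongly
enriched for flagged genes, and the region shows the male heterozygosity
excess expected from Mm heterozygosity. A fully sex-linked site (females
fixed, males heterozygous, pools of 12) has the analytic value
F\_ST = 0.478261, which site estimates track closely at realistic depth.
`analysis/04_calibration.R` quantifies recovery over 25 seeded replicates
(97% region sensitivity, 0.8% null flag rate).

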