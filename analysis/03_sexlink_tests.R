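#!/usr/bin/env Rscript
# Sex-linkage inference on the gene-wise tables: high-F_ST classification at
# the 0.100 cut-off, regional male-heterozygosity-excess t-tests, per-
# chromosome Fisher enrichment, beta-distribution diagnostics, the
# cross-architecture gene intersection, and a female-vs-female
# between-population F_ST comparison.
#
# Requires analysis/01 and 02. Reports land under results/<preset>/ and
# results/compare/.

library(sexfst)

pools <- list(female = c("F1", "F2"), male = c("M1", "M2"))
cfg <- default_run_config()
genes_tbl <- list()

for (preset in c("aaa_like", "senaae_like", "null")) {
  gn <- read_result_table(file.path("results", preset, "genes.tsv"))
  attr(gn, "groups") <- c("female", "male")
  tst <- run_tests(gn, config = cfg, out_dir = file.path("results", preset))
  genes_tbl[[preset]] <- tst$flagged

  cat(sprintf("\n== %s ==\n", preset))
  cat(sprintf("  flagged genes (F_ST >= %.3f): %d of %d\n",
              cfg$threshold, sum(tst$flagged$high_fst), nrow(gn)))
  enr1 <- tst$enrichment[tst$enrichment$chrom == "chr1", ]
  cat(sprintf("  chr1 enrichment: %d/%d flagged, one-sided p = %.3g\n",
              enr1$n_flagged, enr1$n_genes, enr1$p_value))
  rt <- tst$region_tests
  ct <- rt[rt$region == "chr1-central-third" & rt$group == "male", ]
  cat(sprintf("  central-third male H_exp %.3f, male>female t-test p = %.3g\n",
              ct$mean, ct$t_p_male_gt_female))
  cat(sprintf("  gene F_ST beta fit: alpha = %.3f, beta = %.3f (KS D = %.3f)\n",
              tst$beta_fit$alpha, tst$beta_fit$beta, tst$beta_fit$ks_stat))
}

# intersection of the two proto-Y architectures (shared region, different
# random genomes is NOT the case here: both use the same annotation grid, so
# shared flags concentrate in the overlap of the two divergent regions)
dir.create("results/compare", showWarnings = FALSE)
cmp <- run_compare(genes_tbl$aaa_like, genes_tbl$senaae_like, config = cfg,
                   annotation = genes_tbl$aaa_like,
                   out = "results/compare/common_genes.tsv")
cat(sprintf("\ncommon flagged genes: %d (%s)\n", length(cmp$common),
            paste(sprintf("%s: %d", cmp$by_chrom$chrom, cmp$by_chrom$n_common),
                  collapse = ", ")))

# female-vs-female comparison across the two architectures: background
# frequencies differ between the datasets, so differentiation is genome-wide
# rather than region-specific
counts_a <- parse_readcounts("scratch/sim/aaa_like/readcounts.tsv", pools)
counts_s <- parse_readcounts("scratch/sim/senaae_like/readcounts.tsv", pools)
genes_bed <- parse_gene_intervals("scratch/sim/aaa_like/genes.bed", "bed")
ff <- between_population_fst(counts_a, counts_s, pools, pools, "female",
                             genes = genes_bed, labels = c("aaa", "sen"))
write_gene_table(ff$genes, "results/compare/female_vs_female_genes.tsv",
                 params = list(comparison = "aaa-female vs senaae-female"))
cat(sprintf("female-vs-female: %d shared sites, mean gene F_ST %.4f, %d genes >= 0.100\n",
            nrow(ff$sites), mean(ff$genes$fst, na.rm = TRUE),
            sum(ff$genes$fst >= 0.1, na.rm = TRUE)))
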