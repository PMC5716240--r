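#!/usr/bin/env Rscript
# Generate the three study datasets: a clustered proto-Y architecture
# ("aaa_like": divergent sites confined to the central third of chromosome 1),
# a chromosome-wide one ("senaae_like": divergence across 90% of chromosome 1
# with higher background diversity and depth), and a null with no sex-linked
# sites. Each dataset is pooled exome-style readcounts for male and female
# pools of 12 mosquitoes, two replicate libraries per sex.
#
# Raw tables land under scratch/sim/<preset>/ (large, regenerable); a compact
# description of each dataset goes to results/sim_overview.tsv.

library(sexfst)

seed <- 42L
dir.create("results", showWarnings = FALSE)

overview <- do.call(rbind, lapply(c("aaa_like", "senaae_like", "null"), function(preset) {
  cfg <- scenario_presets(preset, seed = seed)
  sim <- run_simulate(cfg, file.path("scratch", "sim", preset))
  truth <- sim$truth
  cat(sprintf(
    "%-12s %d genes, %d SNP sites, %d sex-linked (%.1f%% of region SNPs), depth mean %g\n",
    preset, nrow(sim$genome$genes), nrow(truth), sum(truth$sexlinked),
    100 * mean(truth$sexlinked[truth$chrom == cfg$sexlink_region$chrom &
                               truth$pos >= cfg$sexlink_region$start &
                               truth$pos <= cfg$sexlink_region$end]),
    cfg$depth_mean))
  data.frame(preset = preset, seed = seed,
             n_genes = nrow(sim$genome$genes), n_snps = nrow(truth),
             n_sexlinked = sum(truth$sexlinked),
             region = cfg$sexlink_region$label,
             region_start = cfg$sexlink_region$start,
             region_end = cfg$sexlink_region$end,
             depth_mean = cfg$depth_mean,
             stringsAsFactors = FALSE)
}))

write_filter_summary(overview, "results/sim_overview.tsv",
                     params = list(stage = "simulate", seed = seed))
cat("\nDatasets under scratch/sim/, overview in results/sim_overview.tsv\n")
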