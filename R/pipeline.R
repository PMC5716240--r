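# Pipeline composition: run configuration, stage drivers and the simulation
# recovery harness used for calibration.

#' Default run configuration
#'
#' Parameter defaults follow the analysis conventions: per-replicate minimum
#' coverage 15, high-F_ST threshold 0.100, pools of 12 mosquitoes in 2
#' replicates per sex (so 24 individuals per group enter the estimator).
#'
#' @return Named list of defaults.
#' @export
default_run_config <- function() {
  list(
    min_coverage = 15,
    threshold = 0.100,
    concordance = "variant",
    monomorphic_drop = TRUE,
    n_i = 24,
    n_j = 24,
    test_mode = "unpaired",
    seed = 1L
  )
}

#' Load a run configuration
#'
#' Layering: package defaults < YAML config file < explicit overrides. Unknown
#' keys are rejected so typos fail loudly.
#'
#' @param path Optional YAML file path.
#' @param overrides Named list of final overrides.
#' @return Resolved configuration list.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  layer <- function(base, extra, origin) {
    unknown <- setdiff(names(extra), c(names(base), "pools", "regions"))
    if (length(unknown)) {
      stop("validation error: unknown configuration key '", unknown[1L],
           "' (", origin, ")", call. = FALSE)
    }
    utils::modifyList(base, extra)
  }
  if (!is.null(path)) {
    if (!file.exists(path)) {
      stop("usage error: config file not found: ", path, call. = FALSE)
    }
    cfg <- layer(cfg, yaml::read_yaml(path), path)
  }
  layer(cfg, overrides, "overrides")
}

#' Site-level stage: filter and compute per-SNP statistics
#'
#' @param counts Readcount data.frame or a path to a readcount TSV.
#' @param pools Pool layout; defaults to the one attached to `counts`
#'   (required when `counts` is a path... supply it for files without one).
#' @param config Resolved configuration (see [load_run_config()]).
#' @param out Optional path: writes the site table (and a filter summary next
#'   to it).
#' @return A list with `sites` ([site_stats()] output) and `filter_summary`.
#' @export
run_sites <- function(counts, pools = NULL, config = default_run_config(),
                      out = NULL) {
  if (is.character(counts)) {
    if (!file.exists(counts)) {
      stop("usage error: readcount file not found: ", counts, call. = FALSE)
    }
    counts <- parse_readcounts(counts, pools %||% stop(
      "configuration error: 'pools' is required when reading from a path",
      call. = FALSE))
  }
  if (is.null(pools)) pools <- attr(counts, "pools")
  filt <- filter_sites(counts, pools,
                       min_coverage = config$min_coverage,
                       concordance = config$concordance,
                       monomorphic_drop = config$monomorphic_drop)
  sites <- site_stats(filt$pooled, n_i = config$n_i, n_j = config$n_j)
  if (!is.null(out)) {
    params <- config[c("min_coverage", "concordance", "monomorphic_drop",
                       "n_i", "n_j")]
    write_site_table(sites, out, params)
    write_filter_summary(filt$summary,
                         sub("(\\.tsv)?$", ".filter_summary.tsv", out, perl = TRUE)[1],
                         params)
  }
  list(sites = sites, filter_summary = filt$summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gene-level stage
#'
#' @param sites `SiteStats` from [run_sites()] / [site_stats()].
#' @param genes Gene intervals (data.frame or BED/GFF3 path).
#' @param config Resolved configuration.
#' @param out Optional output TSV path.
#' @return `GeneStats` data.frame.
#' @export
run_genes <- function(sites, genes, config = default_run_config(), out = NULL) {
  if (is.character(genes)) genes <- parse_gene_intervals(genes)
  gstats <- gene_stats(sites, genes)
  if (!is.null(out)) {
    write_gene_table(gstats, out, config[c("n_i", "n_j")])
  }
  gstats
}

#' Default analysis regions for chromosome 1
#'
#' Whole chromosome 1 plus its central third (the default stand-in for the
#' M-locus-proximal region), with the chromosome length taken from the
#' annotation span unless given.
#'
#' @param genes Gene interval data.frame.
#' @param chrom Chromosome of interest (default `"chr1"`).
#' @param chrom_length Optional known chromosome length.
#' @return Data.frame of [region_spec()] rows.
#' @export
default_regions <- function(genes, chrom = "chr1", chrom_length = NULL) {
  L <- chrom_length %||% max(genes$end[genes$chrom == chrom])
  rbind(
    region_spec(chrom, 1, L, paste0(chrom, "-whole")),
    region_spec(chrom, floor(L / 3) + 1, floor(2 * L / 3),
                paste0(chrom, "-central-third"))
  )
}

#' Test stage: classification, regional and enrichment reports
#'
#' @param genes `GeneStats` data.frame.
#' @param config Resolved configuration.
#' @param regions Regions for the heterozygosity tests (default
#'   [default_regions()]).
#' @param male,female Group names.
#' @param out_dir Optional directory for the TSV reports.
#' @return A list: `flagged` (genes with `high_fst`), `region_tests`,
#'   `enrichment`, `beta_fit`.
#' @export
run_tests <- function(genes, config = default_run_config(), regions = NULL,
                      male = "male", female = "female", out_dir = NULL) {
  flagged <- classify_high_fst(genes, config$threshold)
  if (is.null(regions)) regions <- default_regions(genes)
  region_tests <- region_hexp_summary(flagged, regions, mode = config$test_mode,
                                      male = male, female = female)
  enrichment <- chromosome_enrichment(flagged)
  beta_fit <- fit_beta(flagged$fst)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    params <- config[c("threshold", "test_mode")]
    write_gene_table(flagged, file.path(out_dir, "genes_flagged.tsv"), params)
    write_tsv_with_header(region_tests, file.path(out_dir, "region_tests.tsv"), params)
    write_tsv_with_header(enrichment, file.path(out_dir, "chrom_enrichment.tsv"), params)
    bf <- data.frame(alpha = beta_fit$alpha, beta = beta_fit$beta,
                     n = beta_fit$n, mean = beta_fit$mean, var = beta_fit$var,
                     ks_stat = beta_fit$ks_stat, ks_p = beta_fit$ks_p)
    write_tsv_with_header(bf, file.path(out_dir, "beta_fit.tsv"), params)
  }
  list(flagged = flagged, region_tests = region_tests,
       enrichment = enrichment, beta_fit = beta_fit)
}

#' Compare stage: cross-population intersection
#'
#' @param genes_a,genes_b `GeneStats` from the two populations.
#' @param config Resolved configuration (threshold).
#' @param annotation Optional gene intervals for the per-chromosome tally.
#' @param out Optional output TSV path for the common-gene list.
#' @return [intersect_populations()] result plus the flagged id sets.
#' @export
run_compare <- function(genes_a, genes_b, config = default_run_config(),
                        annotation = NULL, out = NULL) {
  fa <- classify_high_fst(genes_a, config$threshold)
  fb <- classify_high_fst(genes_b, config$threshold)
  ids_a <- fa$gene_id[fa$high_fst]
  ids_b <- fb$gene_id[fb$high_fst]
  res <- intersect_populations(ids_a, ids_b, annotation %||% genes_a)
  if (!is.null(out)) {
    common <- data.frame(gene_id = res$common, stringsAsFactors = FALSE)
    write_tsv_with_header(common, out, list(threshold = config$threshold),
                          signif_digits = NULL)
  }
  c(res, list(flagged_a = ids_a, flagged_b = ids_b))
}

#' Simulate one scenario and run the full pipeline on it
#'
#' Convenience harness for calibration and validation: generates a dataset,
#' applies the filter chain and both statistic stages, and summarizes recovery
#' of the simulated proto-Y architecture against the generator's ground truth.
#'
#' @param config A [sim_config()] / [scenario_presets()] result.
#' @param n_i,n_j Individuals per group for the estimator (default
#'   `2 * pool_size`: two summed biological replicates per sex).
#' @param threshold High-F_ST gene cut-off.
#' @param min_coverage Per-replicate coverage minimum.
#' @param test_mode t-test mode for the regional tests.
#' @return A list: `truth`, `sites`, `genes` (with `high_fst`),
#'   `filter_summary`, and `metrics` — a one-row data.frame with
#'   `sensitivity` (flagged fraction of genes whose midpoint lies in the
#'   sex-linked region), `fpr_outside` (flagged fraction outside it),
#'   `flag_rate` (overall), `mean_fst_sexlinked` (mean site F_ST at
#'   truth-flagged sites), `hexp_p_region` (one-sided male-excess p in the
#'   region), `frac_flagged_in_region`, `span_flagged_chr1` (fraction of
#'   chromosome 1 spanned by flagged-gene midpoints), `n_genes`, `n_sites`.
#' @export
run_scenario <- function(config, n_i = 2 * config$pool_size,
                         n_j = 2 * config$pool_size,
                         threshold = 0.100, min_coverage = 15,
                         test_mode = "unpaired") {
  genome <- simulate_genome(config)
  truth <- simulate_frequencies(config, genome)
  counts <- simulate_readcounts(config, truth)
  filt <- filter_sites(counts, attr(counts, "pools"),
                       min_coverage = min_coverage)
  sites <- site_stats(filt$pooled, n_i = n_i, n_j = n_j)
  genes <- gene_stats(sites, genome$genes)
  genes <- classify_high_fst(genes, threshold)

  region <- config$sexlink_region
  ann <- genome$genes
  ann_mid <- (ann$start + ann$end) / 2
  in_region_ann <- ann$chrom == region$chrom &
    ann_mid >= region$start & ann_mid <= region$end
  flag_of <- genes$high_fst[match(ann$gene_id, genes$gene_id)]
  flag_of[is.na(flag_of)] <- FALSE           # genes with no retained SNP: unflagged

  key_sites <- paste(sites$chrom, sites$pos)
  key_truth <- paste(truth$chrom, truth$pos)
  sl <- truth$sexlinked[match(key_sites, key_truth)]
  mean_fst_sl <- if (any(sl, na.rm = TRUE)) {
    mean(sites$fst[which(sl)], na.rm = TRUE)
  } else NA_real_

  ht <- suppressWarnings(male_hexp_test(genes, region, mode = test_mode))

  flagged_genes <- genes[genes$high_fst, , drop = FALSE]
  fl_chr1 <- flagged_genes[flagged_genes$chrom == region$chrom, , drop = FALSE]
  span <- if (nrow(fl_chr1) >= 2) {
    (max(fl_chr1$midpoint) - min(fl_chr1$midpoint)) / config$chrom_length
  } else 0
  in_region_fl <- genes_in_region(flagged_genes, region)

  metrics <- data.frame(
    sensitivity = if (any(in_region_ann)) mean(flag_of[in_region_ann]) else NA_real_,
    fpr_outside = if (any(!in_region_ann)) mean(flag_of[!in_region_ann]) else NA_real_,
    flag_rate = mean(genes$high_fst),
    mean_fst_sexlinked = mean_fst_sl,
    hexp_p_region = ht$p_value,
    frac_flagged_in_region = if (nrow(flagged_genes)) mean(in_region_fl) else NA_real_,
    span_flagged_chr1 = span,
    n_genes = nrow(genes),
    n_sites = nrow(sites)
  )
  list(truth = truth, sites = sites, genes = genes,
       filter_summary = filt$summary, metrics = metrics)
}

#' Repeat a scenario over seeds and stack the recovery metrics
#'
#' @param preset Preset name for [scenario_presets()].
#' @param seeds Integer vector of root seeds.
#' @param ... Overrides forwarded to [scenario_presets()] and then to
#'   [run_scenario()] (`n_i`, `n_j`, `threshold`, `min_coverage`, `test_mode`
#'   go to the pipeline; the rest to the generator).
#' @return Data.frame of per-run metrics, one row per seed.
#' @export
evaluate_recovery <- function(preset, seeds, ...) {
  dots <- list(...)
  pipe_keys <- intersect(names(dots),
                         c("n_i", "n_j", "threshold", "min_coverage", "test_mode"))
  gen_args <- dots[setdiff(names(dots), pipe_keys)]
  rows <- lapply(seeds, function(s) {
    cfg <- do.call(scenario_presets, c(list(preset = preset, seed = s), gen_args))
    res <- do.call(run_scenario, c(list(config = cfg), dots[pipe_keys]))
    cbind(seed = s, res$metrics)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
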