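# Inference layer: sex-linkage classification, regional male-heterozygosity
# tests, chromosome enrichment, category over-representation, cross-population
# comparison and distribution diagnostics.

#' Flag genes above the high-F_ST threshold
#'
#' A gene is flagged iff its F_ST is defined and `>= threshold` (inclusive, per
#' the 0.100 cut-off convention). Undefined F_ST is never flagged and is
#' counted separately in `attr(, "n_undefined")`.
#'
#' @param genes `GeneStats` data.frame from [gene_stats()].
#' @param threshold F_ST cut-off in `(0, 1]` (default 0.100).
#' @return `genes` with an added logical column `high_fst`.
#' @export
classify_high_fst <- function(genes, threshold = 0.100) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("configuration error: threshold must be in (0, 1]", call. = FALSE)
  }
  genes$high_fst <- !is.na(genes$fst) & genes$fst >= threshold
  attr(genes, "n_undefined") <- sum(is.na(genes$fst))
  genes
}

#' A genomic region specification
#'
#' @param chrom Chromosome name.
#' @param start,end 1-based closed bounds, `start < end`.
#' @param label Region label used in reports.
#' @return A one-row data.frame (`RegionSpec`).
#' @export
region_spec <- function(chrom, start, end, label) {
  if (!isTRUE(start < end)) {
    stop("configuration error: region start must be < end", call. = FALSE)
  }
  data.frame(label = label, chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

genes_in_region <- function(genes, region) {
  if (is.null(region)) return(rep(TRUE, nrow(genes)))
  genes$chrom == region$chrom &
    genes$midpoint >= region$start & genes$midpoint <= region$end
}

#' One-sided test for male heterozygosity excess in a region
#'
#' Tests whether mean gene-wise male expected heterozygosity exceeds the female
#' value over the genes of a region (gene membership by midpoint). Default is
#' a one-sided Welch unpaired t-test; `mode = "paired"` pairs the male and
#' female values by gene.
#'
#' @param genes `GeneStats` data.frame with `mean_hexp_*` columns.
#' @param region A [region_spec()] row, or `NULL` for all genes.
#' @param mode `"unpaired"` (Welch) or `"paired"`.
#' @param male,female Group names (default `"male"`, `"female"`).
#' @return A one-row data.frame (`TestResult`): `test`, `region`, `mode`, `n`,
#'   `statistic`, `p_value`, `mean_male`, `mean_female`, `direction`
#'   (male minus female mean). Fewer than 2 usable genes gives `p_value = NA`
#'   with a warning.
#' @export
male_hexp_test <- function(genes, region = NULL,
                           mode = c("unpaired", "paired"),
                           male = "male", female = "female") {
  mode <- match.arg(mode)
  sel <- genes_in_region(genes, region)
  hm <- genes[[paste0("mean_hexp_", male)]][sel]
  hf <- genes[[paste0("mean_hexp_", female)]][sel]
  ok <- !is.na(hm) & !is.na(hf)
  hm <- hm[ok]; hf <- hf[ok]
  label <- if (is.null(region)) "all" else region$label
  base <- data.frame(test = "male_hexp_gt_female", region = label, mode = mode,
                     n = length(hm), stringsAsFactors = FALSE)
  if (length(hm) < 2L) {
    warning("male_hexp_test: fewer than 2 genes with defined H_exp in region '",
            label, "'")
    return(cbind(base, statistic = NA_real_, p_value = NA_real_,
                 mean_male = if (length(hm)) mean(hm) else NA_real_,
                 mean_female = if (length(hf)) mean(hf) else NA_real_,
                 direction = NA_real_))
  }
  ht <- if (mode == "paired") {
    if (isTRUE(all.equal(stats::var(hm - hf), 0))) {
      # degenerate paired case (zero-variance differences): no evidence either way
      list(statistic = c(t = 0), p.value = if (mean(hm - hf) > 0) 0 else 0.5)
    } else {
      stats::t.test(hm, hf, alternative = "greater", paired = TRUE)
    }
  } else {
    stats::t.test(hm, hf, alternative = "greater", paired = FALSE,
                  var.equal = FALSE)
  }
  cbind(base, statistic = unname(ht$statistic), p_value = ht$p.value,
        mean_male = mean(hm), mean_female = mean(hf),
        direction = mean(hm) - mean(hf))
}

#' Descriptive regional heterozygosity report
#'
#' One row per region and group, mirroring the usual summary layout: mean,
#' median, variance, standard deviation, the +/- 1.96 sd interval half-width
#' printed alongside the mean, gene count, and the region's one-sided male
#' excess t-test p-value.
#'
#' @param genes `GeneStats` data.frame.
#' @param regions Data.frame of [region_spec()] rows (or `NULL` for a single
#'   whole-genome row).
#' @param mode,male,female Passed to [male_hexp_test()].
#' @return A data.frame, one row per region x group.
#' @export
region_hexp_summary <- function(genes, regions = NULL,
                                mode = "unpaired",
                                male = "male", female = "female") {
  region_list <- if (is.null(regions)) list(NULL) else
    split(regions, seq_len(nrow(regions)))
  rows <- lapply(region_list, function(region) {
    sel <- genes_in_region(genes, region)
    tt <- male_hexp_test(genes, region, mode = mode, male = male, female = female)
    do.call(rbind, lapply(c(female, male), function(g) {
      h <- genes[[paste0("mean_hexp_", g)]][sel]
      h <- h[!is.na(h)]
      data.frame(region = tt$region, group = g, n = length(h),
                 mean = mean(h), median = stats::median(h),
                 variance = stats::var(h), sd = stats::sd(h),
                 ci95_halfwidth = 1.96 * stats::sd(h),
                 t_p_male_gt_female = tt$p_value,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Upper-tail hypergeometric probability P(X >= k) with X ~ Hyper(N, K, n):
# k successes among n draws from a universe of N containing K successes.
hyper_upper <- function(k, K, N, n) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Per-chromosome enrichment of flagged genes
#'
#' For each chromosome, a one-sided Fisher's exact test (exact hypergeometric
#' upper tail) of the 2x2 table flagged/unflagged x this-chromosome/others, in
#' the enrichment direction.
#'
#' @param genes `GeneStats` data.frame carrying a `high_fst` column (see
#'   [classify_high_fst()]); alternatively supply `flagged`.
#' @param flagged Optional logical vector overriding `genes$high_fst`.
#' @param adjust `"none"` (default; raw p-values) or `"BH"`.
#' @return A data.frame with one row per chromosome: gene counts, flagged
#'   counts, odds ratio and the one-sided `p_value`.
#' @export
chromosome_enrichment <- function(genes, flagged = genes$high_fst,
                                  adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (is.null(flagged)) {
    stop("configuration error: no 'high_fst' column and no 'flagged' vector",
         call. = FALSE)
  }
  chroms <- sort(unique(genes$chrom))
  if (length(chroms) < 2L) {
    stop("configuration error: enrichment needs >= 2 chromosomes", call. = FALSE)
  }
  if (!any(flagged)) {
    warning("chromosome_enrichment: no flagged genes; all p-values are 1")
  }
  N <- length(flagged)
  K <- sum(flagged)
  rows <- lapply(chroms, function(ch) {
    on_ch <- genes$chrom == ch
    n_ch <- sum(on_ch)
    k_ch <- sum(flagged & on_ch)
    # odds ratio of the 2x2 table (sample odds; Inf/NaN possible at the margins)
    or <- (k_ch * (N - K - (n_ch - k_ch))) / ((K - k_ch) * (n_ch - k_ch))
    data.frame(chrom = ch, n_genes = n_ch, n_flagged = k_ch,
               n_genes_other = N - n_ch, n_flagged_other = K - k_ch,
               odds_ratio = or,
               p_value = hyper_upper(k_ch, K, N, n_ch),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust == "BH") out$p_adjust <- stats::p.adjust(out$p_value, "BH")
  rownames(out) <- NULL
  out
}

#' Hypergeometric category over-representation
#'
#' For every functional category, the upper-tail hypergeometric probability of
#' observing at least the seen number of selected members, given the category
#' size, universe size and selection size.
#'
#' @param universe Named character vector mapping gene id -> category label.
#' @param selected Character vector of selected gene ids (must be a subset of
#'   `names(universe)`; ids absent from the universe are dropped with a
#'   warning).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A data.frame with one row per category: sizes, overlap `k` and
#'   `p_value`.
#' @export
category_overrepresentation <- function(universe, selected,
                                        adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (is.null(names(universe))) {
    stop("configuration error: 'universe' must be a named gene -> category vector",
         call. = FALSE)
  }
  unknown <- setdiff(selected, names(universe))
  if (length(unknown)) {
    warning("category_overrepresentation: ", length(unknown),
            " selected gene(s) absent from the universe; dropped")
    selected <- intersect(selected, names(universe))
  }
  N <- length(universe)
  n <- length(selected)
  cats <- sort(unique(unname(universe)))
  sel_cat <- universe[selected]
  rows <- lapply(cats, function(cc) {
    K <- sum(universe == cc)
    k <- sum(sel_cat == cc)
    data.frame(category = cc, category_size = K, universe_size = N,
               selection_size = n, k = k,
               p_value = hyper_upper(k, K, N, n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust == "BH") out$p_adjust <- stats::p.adjust(out$p_value, "BH")
  rownames(out) <- NULL
  out
}

#' Intersect flagged gene sets from two populations
#'
#' @param flagged_a,flagged_b Character vectors of gene ids (same annotation
#'   namespace).
#' @param genes Optional gene interval data.frame used to tally the common set
#'   per chromosome.
#' @return A list with `common` (sorted gene ids) and, when `genes` is given,
#'   `by_chrom` (data.frame chromosome -> count).
#' @export
intersect_populations <- function(flagged_a, flagged_b, genes = NULL) {
  common <- sort(intersect(flagged_a, flagged_b))
  out <- list(common = common)
  if (!is.null(genes)) {
    ch <- genes$chrom[match(common, genes$gene_id)]
    tab <- table(factor(ch, levels = sort(unique(genes$chrom))))
    out$by_chrom <- data.frame(chrom = names(tab), n_common = as.integer(tab),
                               stringsAsFactors = FALSE)
  }
  out
}

#' Between-population F_ST for one sex
#'
#' Reuses the whole differentiation machinery with the two groups redefined as
#' (population X, sex k) vs (population Y, sex k) — e.g. female-vs-female —
#' after merging the two populations' readcount tables on shared sites.
#' Each population's table is expected to satisfy its own filters; the merged
#' table is re-filtered under the standard chain.
#'
#' @param counts_x,counts_y Readcount data.frames of the two populations.
#' @param pools_x,pools_y Their pool layouts.
#' @param group Sex to compare (a group name present in both layouts).
#' @param genes Optional gene intervals for gene-level output.
#' @param labels Length-2 population labels used as group names in the output.
#' @param min_coverage,concordance,monomorphic_drop Passed to [filter_sites()].
#' @param n_i,n_j Individuals per population pool (default 24 as in
#'   [site_stats()]).
#' @return A list with `sites`, `filter_summary` and (if `genes`) `genes`;
#'   schema identical to the inter-sex outputs, with population labels as
#'   group names.
#' @export
between_population_fst <- function(counts_x, counts_y, pools_x, pools_y, group,
                                   genes = NULL, labels = c("popX", "popY"),
                                   min_coverage = 15,
                                   concordance = "variant",
                                   monomorphic_drop = TRUE,
                                   n_i = 24, n_j = 24) {
  for (p in list(pools_x, pools_y)) {
    if (!group %in% names(p)) {
      stop("configuration error: group '", group, "' absent from a pool layout",
           call. = FALSE)
    }
  }
  take <- function(counts, reps, label) {
    sub <- counts[, c("chrom", "pos", "ref", count_columns(reps)), drop = FALSE]
    names(sub)[-(1:3)] <- count_columns(paste0(label, ".", reps))
    sub
  }
  gx <- paste0(labels[1L], "_", group)
  gy <- paste0(labels[2L], "_", group)
  merged <- merge(take(counts_x, pools_x[[group]], labels[1L]),
                  take(counts_y, pools_y[[group]], labels[2L]),
                  by = c("chrom", "pos", "ref"))
  merged <- merged[order(merged$chrom, merged$pos), , drop = FALSE]
  pools <- stats::setNames(
    list(paste0(labels[1L], ".", pools_x[[group]]),
         paste0(labels[2L], ".", pools_y[[group]])),
    c(gx, gy)
  )
  attr(merged, "pools") <- pools
  filt <- filter_sites(merged, pools, min_coverage = min_coverage,
                       concordance = concordance,
                       monomorphic_drop = monomorphic_drop)
  sites <- site_stats(filt$pooled, n_i = n_i, n_j = n_j)
  out <- list(sites = sites, filter_summary = filt$summary)
  if (!is.null(genes)) out$genes <- gene_stats(sites, genes)
  out
}

#' Method-of-moments beta fit for gene F_ST values
#'
#' Gene-wise F_ST values on (0, 1) are expected to be roughly beta
#' distributed. Values are restricted to defined ones; exact 0/1 (and
#' out-of-range negatives from the unclamped estimator) are shifted into
#' `(eps, 1 - eps)`. Shape estimates come from the sample mean `m` and
#' variance `v`: `alpha = m (m (1 - m) / v - 1)`, `beta = (1 - m) (m (1 - m) /
#' v - 1)`. A Kolmogorov-Smirnov distance against the fitted beta is reported
#' as a diagnostic only.
#'
#' @param x Numeric vector of gene F_ST values (NAs dropped).
#' @param eps Clamping epsilon (default 1e-6).
#' @return A list: `alpha`, `beta`, `n`, `mean`, `var`, `ks_stat`, `ks_p`.
#'   Degenerate input (n < 10 or zero variance) gives `NA` shapes with a
#'   warning.
#' @export
fit_beta <- function(x, eps = 1e-6) {
  x <- x[!is.na(x)]
  x <- pmin(pmax(x, eps), 1 - eps)
  n <- length(x)
  m <- mean(x)
  v <- stats::var(x)
  if (n < 10L || !isTRUE(v > 0)) {
    warning("fit_beta: fit undefined (need >= 10 values with positive variance)")
    return(list(alpha = NA_real_, beta = NA_real_, n = n,
                mean = if (n) m else NA_real_, var = v,
                ks_stat = NA_real_, ks_p = NA_real_))
  }
  scale <- m * (1 - m) / v - 1
  alpha <- m * scale
  beta <- (1 - m) * scale
  ks <- suppressWarnings(stats::ks.test(x, "pbeta", alpha, beta))
  list(alpha = alpha, beta = beta, n = n, mean = m, var = v,
       ks_stat = unname(ks$statistic), ks_p = ks$p.value)
}

#' Variant density per aligned kilobase
#'
#' `n_variants * 1000 / (n_aligned_reads * read_length)`: the number of variant
#' sites per thousand aligned nucleotides, used to compare polymorphism levels
#' across libraries of different size.
#'
#' @param n_variants Number of variant sites.
#' @param n_aligned_reads Number of aligned reads.
#' @param read_length Read length in nucleotides (default 100).
#' @return The ratio (vectorized).
#' @export
variant_alignment_ratio <- function(n_variants, n_aligned_reads,
                                    read_length = 100) {
  if (any(n_aligned_reads <= 0)) {
    stop("contract error: n_aligned_reads must be positive", call. = FALSE)
  }
  (n_variants * 1000) / (n_aligned_reads * read_length)
}
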