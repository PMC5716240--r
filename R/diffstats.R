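# Estimator core: per-SNP variance-component F_ST for pooled allele
# frequencies, Hardy-Weinberg expected heterozygosity per group, and gene-wise
# ratio-of-sums aggregation.
#
# For SNP site s with groups i and j, variant-allele frequencies p_i, p_j
# (read counts of the variant base over total nucleotide coverage), combined
# coverage-weighted frequency p_bar, and n_i, n_j individuals per group:
#
#   alpha_k = 2 p_k (1 - p_k)                         (expected heterozygosity)
#   b_s  = (n_i alpha_i + n_j alpha_j) / (n_i + n_j - 1)
#   a_s  = [4 n_i (p_i - p_bar)^2 + 4 n_j (p_j - p_bar)^2 - b_s]
#          / (2 * (2 n_i n_j / (n_i + n_j)))
#   F_ST(s) = a_s / (a_s + b_s)
#   F_ST(g) = sum_s a_s / sum_s (a_s + b_s)            (ratio of sums over a gene)

#' Variant-allele frequency from a pooled count map
#'
#' Count of the variant base divided by total nucleotide coverage (A+C+G+T;
#' indels excluded).
#'
#' @param counts Named numeric vector or single-row matrix with entries
#'   `A,C,G,T` (extra entries ignored).
#' @param variant_base The base designated as the variant.
#' @return Frequency in `[0, 1]`.
#' @export
allele_freq <- function(counts, variant_base) {
  counts <- unlist(counts)
  full <- stats::setNames(rep(0, 4L), NUC_BASES)
  present <- intersect(names(counts), NUC_BASES)
  full[present] <- counts[present]
  counts <- full
  total <- sum(counts)
  if (!isTRUE(total > 0)) {
    stop("contract error: zero nucleotide coverage", call. = FALSE)
  }
  if (!variant_base %in% NUC_BASES) {
    stop("contract error: variant_base must be one of A,C,G,T", call. = FALSE)
  }
  unname(counts[variant_base] / total)
}

#' Hardy-Weinberg expected heterozygosity
#'
#' `2 p (1 - p)`: symmetric in `p <-> 1 - p`, maximal (0.5) at `p = 0.5`.
#'
#' @param p Allele frequency (vectorized), each in `[0, 1]`.
#' @return Expected heterozygosity in `[0, 0.5]`.
#' @export
hexp <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("contract error: p must be in [0, 1]", call. = FALSE)
  }
  2 * p * (1 - p)
}

#' Per-site between- and within-group variance components
#'
#' Computes the coverage-weighted combined frequency `p_bar`, the within-group
#' component `b_s` and the between-group component `a_s` (see the formulas at
#' the top of this file). All arguments are vectorized over sites.
#'
#' @param p_i,p_j Variant-allele frequencies of the two groups.
#' @param cov_i,cov_j Total nucleotide coverages of the two groups (weights of
#'   `p_bar`).
#' @param n_i,n_j Numbers of individuals sampled per group.
#' @return A list with numeric vectors `a`, `b` and `p_bar`.
#' @export
site_components <- function(p_i, p_j, cov_i, cov_j, n_i, n_j) {
  if (any(n_i + n_j <= 1)) {
    stop("contract error: n_i + n_j must exceed 1", call. = FALSE)
  }
  if (any(cov_i <= 0) || any(cov_j <= 0)) {
    stop("contract error: coverages must be positive", call. = FALSE)
  }
  if (any(p_i < 0 | p_i > 1) || any(p_j < 0 | p_j > 1)) {
    stop("contract error: frequencies must be in [0, 1]", call. = FALSE)
  }
  p_bar <- (cov_i * p_i + cov_j * p_j) / (cov_i + cov_j)
  alpha_i <- 2 * p_i * (1 - p_i)
  alpha_j <- 2 * p_j * (1 - p_j)
  b <- (n_i * alpha_i + n_j * alpha_j) / (n_i + n_j - 1)
  a <- (4 * n_i * (p_i - p_bar)^2 + 4 * n_j * (p_j - p_bar)^2 - b) /
       (2 * (2 * n_i * n_j / (n_i + n_j)))
  list(a = a, b = b, p_bar = p_bar)
}

#' Per-site F_ST from variance components
#'
#' `a / (a + b)` where the denominator exceeds `tol`; `NA` (undefined)
#' otherwise. Undefined is a value, not an error: degenerate sites (both
#' components zero) simply carry no information.
#'
#' @param a,b Between- and within-group components (vectorized).
#' @param tol Denominator tolerance below which F_ST is undefined.
#' @return Numeric vector, `NA` where undefined; always `<= 1` where defined.
#' @export
site_fst <- function(a, b, tol = 1e-12) {
  denom <- a + b
  ifelse(is.na(denom) | denom <= tol, NA_real_, a / denom)
}

#' Per-SNP statistics for a pooled site table
#'
#' Derives, for every retained site, the two groups' variant-allele frequencies,
#' expected heterozygosities, variance components and F_ST.
#'
#' @param pooled Pooled site table from [filter_sites()] (`$pooled`).
#' @param n_i,n_j Individuals per group, in the order of `attr(pooled,
#'   "groups")`. Default 24: 12 mosquitoes per pool times 2 summed biological
#'   replicates.
#' @param tol Undefined-F_ST tolerance passed to [site_fst()].
#' @return A data.frame (`SiteStats`): `chrom`, `pos`, `ref`, `variant_base`,
#'   per-group `cov_*`, `p_*`, `hexp_*`, then `p_bar`, `a_s`, `b_s`, `fst`,
#'   sorted by chromosome and position. Groups recorded in `attr(, "groups")`.
#' @export
site_stats <- function(pooled, n_i = 24, n_j = 24, tol = 1e-12) {
  groups <- attr(pooled, "groups")
  if (is.null(groups) || length(groups) != 2L) {
    stop("pooled table must carry a two-group 'groups' attribute", call. = FALSE)
  }
  g1 <- groups[1L]; g2 <- groups[2L]
  n <- nrow(pooled)
  vidx <- match(pooled$variant_base, NUC_BASES)
  cov1 <- pooled[[paste0("cov_", g1)]]
  cov2 <- pooled[[paste0("cov_", g2)]]
  m1 <- as.matrix(pooled[, paste0(g1, "_", NUC_BASES), drop = FALSE])
  m2 <- as.matrix(pooled[, paste0(g2, "_", NUC_BASES), drop = FALSE])
  p1 <- m1[cbind(seq_len(n), vidx)] / cov1
  p2 <- m2[cbind(seq_len(n), vidx)] / cov2
  comp <- if (n) site_components(p1, p2, cov1, cov2, n_i, n_j)
          else list(a = numeric(0), b = numeric(0), p_bar = numeric(0))
  out <- data.frame(chrom = pooled$chrom, pos = pooled$pos, ref = pooled$ref,
                    variant_base = pooled$variant_base,
                    stringsAsFactors = FALSE)
  out[[paste0("cov_", g1)]] <- cov1
  out[[paste0("cov_", g2)]] <- cov2
  out[[paste0("p_", g1)]] <- p1
  out[[paste0("p_", g2)]] <- p2
  out[[paste0("hexp_", g1)]] <- 2 * p1 * (1 - p1)
  out[[paste0("hexp_", g2)]] <- 2 * p2 * (1 - p2)
  out$p_bar <- comp$p_bar
  out$a_s <- comp$a
  out$b_s <- comp$b
  out$fst <- site_fst(comp$a, comp$b, tol)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "groups") <- groups
  out
}

genes_to_granges <- function(genes) {
  GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end)
  )
}

#' Assign SNP sites to gene intervals
#'
#' A site is assigned to every gene whose 1-based closed span contains its
#' position (both endpoints inclusive); overlapping genes each receive the
#' site. Lookup uses an interval-tree overlap query.
#'
#' @param sites Data.frame with `chrom` and `pos` columns.
#' @param genes Gene interval data.frame ([parse_gene_intervals()]).
#' @return A data.frame with `site_row` (row index into `sites`) and `gene_id`.
#' @export
assign_sites_to_genes <- function(sites, genes) {
  site_gr <- GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$pos, width = 1L)
  )
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(site_gr, genes_to_granges(genes))
  )
  data.frame(site_row = S4Vectors::queryHits(hits),
             gene_id = genes$gene_id[S4Vectors::subjectHits(hits)],
             stringsAsFactors = FALSE)
}

#' Gene-wise F_ST for one set of sites
#'
#' Ratio of sums over the gene's SNPs — `sum(a_s) / sum(a_s + b_s)` — which is
#' NOT the mean of per-site ratios: sites with larger total variance weigh
#' more, exactly as in the per-site estimator.
#'
#' @param a,b Per-site components of the gene's SNPs.
#' @param tol Denominator tolerance below which the gene F_ST is undefined.
#' @return Single F_ST value, `NA` when undefined.
#' @export
gene_fst <- function(a, b, tol = 1e-12) {
  denom <- sum(a + b)
  if (is.na(denom) || denom <= tol) NA_real_ else sum(a) / denom
}

#' Gene-wise statistics
#'
#' Aggregates per-SNP statistics over gene intervals: SNP count `m`, component
#' sums, ratio-of-sums F_ST ([gene_fst()]) and the arithmetic mean expected
#' heterozygosity per group. Genes with no retained SNP are omitted.
#'
#' @param sites `SiteStats` data.frame from [site_stats()].
#' @param genes Gene interval data.frame.
#' @param tol Undefined-F_ST tolerance.
#' @return A data.frame (`GeneStats`): `gene_id`, `chrom`, `start`, `end`,
#'   `midpoint`, `m`, `sum_a`, `sum_b`, `fst`, per-group `mean_hexp_*`, sorted
#'   by chromosome and start. Groups recorded in `attr(, "groups")`.
#' @export
gene_stats <- function(sites, genes, tol = 1e-12) {
  groups <- attr(sites, "groups")
  if (is.null(groups)) stop("sites table must carry a 'groups' attribute", call. = FALSE)
  asg <- assign_sites_to_genes(sites, genes)
  if (!nrow(asg)) {
    out <- data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      midpoint = numeric(0), m = integer(0),
                      sum_a = numeric(0), sum_b = numeric(0), fst = numeric(0))
    out[[paste0("mean_hexp_", groups[1L])]] <- numeric(0)
    out[[paste0("mean_hexp_", groups[2L])]] <- numeric(0)
    attr(out, "groups") <- groups
    return(out)
  }
  f <- factor(asg$gene_id)
  a <- sites$a_s[asg$site_row]
  b <- sites$b_s[asg$site_row]
  h1 <- sites[[paste0("hexp_", groups[1L])]][asg$site_row]
  h2 <- sites[[paste0("hexp_", groups[2L])]][asg$site_row]
  sums <- rowsum(cbind(a = a, b = b, h1 = h1, h2 = h2), f)
  m <- as.integer(table(f))
  sum_a <- sums[, "a"]; sum_b <- sums[, "b"]
  denom <- sum_a + sum_b
  fst <- ifelse(denom <= tol, NA_real_, sum_a / denom)
  gi <- genes[match(levels(f), genes$gene_id), , drop = FALSE]
  out <- data.frame(gene_id = levels(f), chrom = gi$chrom,
                    start = gi$start, end = gi$end,
                    midpoint = (gi$start + gi$end) / 2,
                    m = m, sum_a = unname(sum_a), sum_b = unname(sum_b),
                    fst = unname(fst), stringsAsFactors = FALSE)
  out[[paste0("mean_hexp_", groups[1L])]] <- unname(sums[, "h1"]) / m
  out[[paste0("mean_hexp_", groups[2L])]] <- unname(sums[, "h2"]) / m
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "groups") <- groups
  out
}
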