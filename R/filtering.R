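# SNP-site inclusion rules for pooled replicate libraries.
#
# Chain: per-replicate minimum coverage -> replicate concordance (a shared
# non-reference base seen in every replicate of at least one group) ->
# replicate summation per group -> allele classification, dropping sites fixed
# for one identical base in both groups (monomorphic). Indel counts are carried
# through but excluded from all coverage and frequency arithmetic.

rep_count_matrix <- function(counts, replicate) {
  as.matrix(counts[, paste0(replicate, "_", NUC_BASES), drop = FALSE])
}

#' Minimum-coverage filter for one pool replicate
#'
#' A replicate passes at a site iff its total nucleotide coverage
#' (A+C+G+T, indels excluded) is at least `min_cov`. The boundary is inclusive:
#' total coverage exactly `min_cov` passes.
#'
#' @param counts Readcount data.frame from [parse_readcounts()].
#' @param replicate Single replicate name.
#' @param min_cov Minimum total site coverage per replicate (default 15).
#' @return Logical vector, one element per site.
#' @export
filter_min_coverage <- function(counts, replicate, min_cov = 15) {
  stopifnot(length(replicate) == 1L)
  if (!is.numeric(min_cov) || min_cov < 1) {
    stop("configuration error: min_cov must be >= 1", call. = FALSE)
  }
  rowSums(rep_count_matrix(counts, replicate)) >= min_cov
}

#' Replicate concordance within one group
#'
#' A site passes for a group iff every replicate of the group passes
#' [filter_min_coverage()] and, in `"variant"` mode, every replicate shows at
#' least one read of some shared non-reference base. `"coverage"` mode demands
#' coverage only (the looser reading of presence in both replicate libraries).
#'
#' @param counts Readcount data.frame.
#' @param replicates Character vector of the group's replicate names (>= 2).
#' @param min_cov Minimum per-replicate coverage.
#' @param mode `"variant"` (default) or `"coverage"`.
#' @return Logical vector, one element per site.
#' @export
replicate_concordance <- function(counts, replicates, min_cov = 15,
                                  mode = c("variant", "coverage")) {
  mode <- match.arg(mode)
  if (length(replicates) < 2L) {
    stop("configuration error: replicate concordance needs >= 2 replicates",
         call. = FALSE)
  }
  n <- nrow(counts)
  cov_ok <- rep(TRUE, n)
  for (r in replicates) {
    cov_ok <- cov_ok & filter_min_coverage(counts, r, min_cov)
  }
  if (mode == "coverage") return(cov_ok)
  shared <- matrix(TRUE, n, 4L)
  for (r in replicates) {
    shared <- shared & (rep_count_matrix(counts, r) > 0)
  }
  ref_idx <- match(counts$ref, NUC_BASES)          # NA for ref N: no base masked
  has_ref <- !is.na(ref_idx)
  shared[cbind(which(has_ref), ref_idx[has_ref])] <- FALSE
  cov_ok & (rowSums(shared) > 0)
}

#' Sum replicate counts within a group
#'
#' Element-wise sum of the group's per-replicate base counts (A, C, G, T,
#' indel). Sites are expected to have passed the group's filters; an all-zero
#' replicate violates that contract.
#'
#' @param counts Readcount data.frame.
#' @param replicates Character vector of replicate names.
#' @param check Enforce the no-all-zero-replicate contract (default TRUE).
#' @return Numeric matrix, one row per site, columns `A,C,G,T,indel`.
#' @export
combine_replicates <- function(counts, replicates, check = TRUE) {
  out <- matrix(0, nrow(counts), 5L, dimnames = list(NULL, c(NUC_BASES, "indel")))
  for (r in replicates) {
    m <- as.matrix(counts[, count_columns(r), drop = FALSE])
    if (check && nrow(m) && any(rowSums(m[, 1:4, drop = FALSE]) == 0)) {
      stop("contract error: replicate '", r,
           "' has zero nucleotide coverage at a combined site", call. = FALSE)
    }
    out <- out + m
  }
  out
}

#' Classify site alleles from the two groups' combined counts
#'
#' A site is monomorphic when both groups place 100% of their nucleotide
#' coverage on one identical base (whether or not it equals the reference);
#' such sites carry no differentiation signal. Otherwise the designated
#' variant base is the non-reference base with the highest summed coverage
#' across both groups, ties broken in fixed base order A < C < G < T.
#'
#' @param group1,group2 Numeric matrices of combined counts (columns A,C,G,T at
#'   least), one row per site.
#' @param ref Character vector of reference bases.
#' @return A list with `monomorphic` (logical) and `variant_base` (character,
#'   `NA` where monomorphic).
#' @export
classify_site_alleles <- function(group1, group2, ref) {
  g1 <- group1[, NUC_BASES, drop = FALSE]
  g2 <- group2[, NUC_BASES, drop = FALSE]
  n <- nrow(g1)
  tot1 <- rowSums(g1)
  tot2 <- rowSums(g2)
  if (any(tot1 == 0) || any(tot2 == 0)) {
    stop("contract error: zero nucleotide coverage in a group at a classified site",
         call. = FALSE)
  }
  top1 <- max.col(g1, ties.method = "first")
  top2 <- max.col(g2, ties.method = "first")
  idx <- seq_len(n)
  mono <- (g1[cbind(idx, top1)] == tot1) &
          (g2[cbind(idx, top2)] == tot2) &
          (top1 == top2)
  pooled <- g1 + g2
  ref_idx <- match(ref, NUC_BASES)
  has_ref <- !is.na(ref_idx)
  pooled[cbind(which(has_ref), ref_idx[has_ref])] <- -1  # never pick the reference
  variant_idx <- max.col(pooled, ties.method = "first")  # ties: A < C < G < T
  variant_base <- NUC_BASES[variant_idx]
  variant_base[mono] <- NA_character_
  list(monomorphic = mono, variant_base = variant_base)
}

#' Run the full site-filter chain and pool replicates per group
#'
#' Applies, in order: per-replicate minimum coverage in every replicate of both
#' groups; replicate concordance (a shared non-reference base in every
#' replicate of at least one group — requiring it of both groups would discard
#' every site fixed in one sex, i.e. precisely the sex-linked signal);
#' replicate summation per group; monomorphic-site removal. The chain is
#' idempotent on its retained output.
#'
#' @param counts Readcount data.frame from [parse_readcounts()].
#' @param pools Pool layout (two groups), see [validate_pools()]; defaults to
#'   `attr(counts, "pools")`.
#' @param min_coverage Minimum per-replicate total coverage (default 15).
#' @param concordance `"variant"` or `"coverage"`, see [replicate_concordance()].
#' @param monomorphic_drop Drop monomorphic sites (default TRUE).
#' @return A list with `pooled` (data.frame: `chrom`, `pos`, `ref`,
#'   `variant_base`, per-group combined counts `<group>_A .. <group>_indel` and
#'   coverages `cov_<group>`, groups recorded in `attr(, "groups")`) and
#'   `summary` (data.frame of per-category site counts).
#' @export
filter_sites <- function(counts, pools = attr(counts, "pools"),
                         min_coverage = 15,
                         concordance = c("variant", "coverage"),
                         monomorphic_drop = TRUE) {
  concordance <- match.arg(concordance)
  validate_pools(pools)
  groups <- names(pools)
  n <- nrow(counts)

  cov_ok <- rep(TRUE, n)
  for (r in unlist(pools, use.names = FALSE)) {
    cov_ok <- cov_ok & filter_min_coverage(counts, r, min_coverage)
  }
  conc_any <- rep(FALSE, n)
  for (g in groups) {
    conc_any <- conc_any | replicate_concordance(counts, pools[[g]],
                                                 min_coverage, concordance)
  }
  keep <- cov_ok & conc_any
  n_low_cov <- sum(!cov_ok)
  n_discord <- sum(cov_ok & !conc_any)

  kept <- counts[keep, , drop = FALSE]
  comb <- lapply(pools, function(reps) combine_replicates(kept, reps))
  if (nrow(kept)) {
    cls <- classify_site_alleles(comb[[1L]], comb[[2L]], kept$ref)
  } else {
    cls <- list(monomorphic = logical(0), variant_base = character(0))
  }
  n_mono <- sum(cls$monomorphic)
  retain <- if (monomorphic_drop) !cls$monomorphic else rep(TRUE, nrow(kept))

  pooled <- data.frame(chrom = kept$chrom, pos = kept$pos, ref = kept$ref,
                       variant_base = cls$variant_base,
                       stringsAsFactors = FALSE)
  for (g in groups) {
    m <- comb[[g]]
    colnames(m) <- paste0(g, "_", colnames(m))
    pooled <- cbind(pooled, as.data.frame(m))
    pooled[[paste0("cov_", g)]] <- rowSums(m[, paste0(g, "_", NUC_BASES), drop = FALSE])
  }
  pooled <- pooled[retain, , drop = FALSE]
  rownames(pooled) <- NULL
  attr(pooled, "groups") <- groups

  summary <- data.frame(
    category = c("input", "low_coverage", "no_concordant_variant",
                 "monomorphic", "retained"),
    count = c(n, n_low_cov, n_discord,
              if (monomorphic_drop) n_mono else 0L, nrow(pooled))
  )
  list(pooled = pooled, summary = summary)
}

#' Write the filter-summary table
#'
#' @param summary The `summary` component of [filter_sites()].
#' @param path Output path.
#' @param params Named list recorded in the comment header.
#' @return `path`, invisibly.
#' @export
write_filter_summary <- function(summary, path, params = list()) {
  write_tsv_with_header(summary, path, params, signif_digits = NULL)
}
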