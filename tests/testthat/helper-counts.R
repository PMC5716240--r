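# Builders for toy readcount tables (two groups, two replicates each unless
# stated otherwise).

default_pools <- function() list(female = c("F1", "F2"), male = c("M1", "M2"))

# One readcount row; unstated replicates/bases default to zero counts.
counts_row <- function(chrom, pos, ref, ..., pools = default_pools()) {
  reps <- list(...)
  out <- data.frame(chrom = chrom, pos = pos, ref = ref,
                    stringsAsFactors = FALSE)
  for (r in unlist(pools, use.names = FALSE)) {
    v <- c(A = 0, C = 0, G = 0, T = 0, indel = 0)
    if (!is.null(reps[[r]])) v[names(reps[[r]])] <- reps[[r]]
    block <- as.data.frame(as.list(v))
    names(block) <- count_columns(r)
    out <- cbind(out, block)
  }
  out
}

bind_counts <- function(..., pools = default_pools()) {
  df <- do.call(rbind, list(...))
  rownames(df) <- NULL
  attr(df, "pools") <- pools
  df
}

# A site with the same counts in every replicate of each group.
uniform_site <- function(chrom, pos, ref, female, male, pools = default_pools()) {
  args <- c(list(chrom = chrom, pos = pos, ref = ref),
            stats::setNames(rep(list(female), length(pools$female)), pools$female),
            stats::setNames(rep(list(male), length(pools$male)), pools$male),
            list(pools = pools))
  do.call(counts_row, args)
}
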