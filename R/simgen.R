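# Synthetic pool-seq generator with a configurable proto-Y architecture.
#
# The generator emulates pooled exome sequencing of male and female mosquito
# pools (12 individuals each, two biological replicates per sex): background
# SNPs share one population allele frequency between the sexes; SNPs inside
# the sex-linked region (with probability d, when recombination is suppressed)
# carry divergent X and Y haplotype alleles, so true female frequency = p_X
# and true male frequency = (p_X + p_Y) / 2 (males are X/Y heterozygotes, Mm).
# Read counts are drawn in three stages per pool replicate: finite-pool
# resampling of 2 * pool_size allele copies, negative-binomial depth, binomial
# variant reads, then symmetric base miscalls.

# Child seeds per stage, derived deterministically from the root seed; kept
# below 2^31 - 1 (exact in doubles for any 32-bit root seed).
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) %% 2146483L) * 1000L + stream)
}

#' Simulation configuration
#'
#' Defaults describe an exome-like design: 3 chromosomes of 60 genes (2 kb
#' genes separated by 1 kb), 5 SNPs per gene, pools of 12 mosquitoes with 2
#' replicate libraries per sex, negative-binomial per-replicate depth (mean
#' 180, size 10), per-read miscall rate 1e-3 (Q30 data), background
#' variant-allele frequencies from Beta(0.2, 1.8) (right-skewed site
#' heterozygosity, mean about 0.1), and a proto-Y region covering the central
#' third of chromosome 1 in which a fraction `d = 0.5` of SNPs are X-Y
#' divergent (`x_freq` on X, `y_freq` on Y; fixed difference by default).
#'
#' @param seed Root RNG seed; all stages derive child seeds from it.
#' @param n_chrom Number of chromosomes.
#' @param genes_per_chrom Genes per chromosome.
#' @param gene_length,gene_spacing Gene span and intergenic gap (bp).
#' @param snps_per_gene SNP sites per gene.
#' @param pool_size Mosquitoes per pool replicate.
#' @param replicates Replicate libraries per sex.
#' @param depth_mean,depth_size Negative-binomial depth mean and dispersion
#'   (size) per replicate and site.
#' @param error_rate Per-read symmetric miscall probability.
#' @param bg_alpha,bg_beta Beta law of background variant-allele frequencies.
#' @param diversity_scale Multiplier on `bg_alpha` (raises background
#'   diversity in both sexes).
#' @param sexlink_region A [region_spec()] row; default central third of
#'   chromosome 1.
#' @param d Probability that a region SNP is X-Y divergent.
#' @param recomb_suppressed Whether males carry an intact Y haplotype across
#'   the region (otherwise the region behaves as background).
#' @param x_freq,y_freq Variant-allele frequency on the X and Y haplotypes of
#'   divergent SNPs (defaults 0 and 1: fixed difference; intermediate `y_freq`
#'   gives partial divergence).
#' @return A `sim_config` list, with `chrom_names` and `chrom_length` derived.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 3L,
                       genes_per_chrom = 60L,
                       gene_length = 2000L,
                       gene_spacing = 1000L,
                       snps_per_gene = 5L,
                       pool_size = 12L,
                       replicates = 2L,
                       depth_mean = 180,
                       depth_size = 10,
                       error_rate = 1e-3,
                       bg_alpha = 0.2,
                       bg_beta = 1.8,
                       diversity_scale = 1,
                       sexlink_region = NULL,
                       d = 0.5,
                       recomb_suppressed = TRUE,
                       x_freq = 0,
                       y_freq = 1) {
  if (d < 0 || d > 1) stop("configuration error: d must be in [0, 1]", call. = FALSE)
  if (depth_mean <= 0) stop("configuration error: depth_mean must be > 0", call. = FALSE)
  if (pool_size < 1) stop("configuration error: pool_size must be >= 1", call. = FALSE)
  if (replicates < 2) stop("configuration error: need >= 2 replicates per sex", call. = FALSE)
  if (snps_per_gene > gene_length) {
    stop("configuration error: more SNPs than bases per gene", call. = FALSE)
  }
  if (gene_spacing < 2) stop("configuration error: gene_spacing must be >= 2", call. = FALSE)
  chrom_length <- genes_per_chrom * (gene_length + gene_spacing)
  if (is.null(sexlink_region)) {
    sexlink_region <- region_spec("chr1", floor(chrom_length / 3) + 1,
                                  floor(2 * chrom_length / 3), "chr1-central-third")
  }
  structure(list(
    seed = as.integer(seed), n_chrom = n_chrom,
    genes_per_chrom = genes_per_chrom, gene_length = gene_length,
    gene_spacing = gene_spacing, snps_per_gene = snps_per_gene,
    pool_size = pool_size, replicates = replicates,
    depth_mean = depth_mean, depth_size = depth_size,
    error_rate = error_rate, bg_alpha = bg_alpha, bg_beta = bg_beta,
    diversity_scale = diversity_scale, sexlink_region = sexlink_region,
    d = d, recomb_suppressed = recomb_suppressed,
    x_freq = x_freq, y_freq = y_freq,
    chrom_names = paste0("chr", seq_len(n_chrom)),
    chrom_length = chrom_length
  ), class = "sim_config")
}

#' Named scenario presets
#'
#' * `aaa_like`: proto-Y cluster confined to the central third of chromosome 1
#'   with suppressed recombination (depth mean 180).
#' * `senaae_like`: divergent region spanning 90% of chromosome 1, elevated
#'   background diversity in both sexes, depth mean 261.
#' * `null`: no sex-linked sites (`d = 0`).
#'
#' @param preset One of `"aaa_like"`, `"senaae_like"`, `"null"`.
#' @param seed Root seed.
#' @param ... Overrides forwarded to [sim_config()].
#' @return A `sim_config`.
#' @export
scenario_presets <- function(preset = c("aaa_like", "senaae_like", "null"),
                             seed = 1L, ...) {
  preset <- match.arg(preset)
  args <- list(seed = seed, ...)
  defaults <- switch(preset,
    aaa_like = list(),
    senaae_like = {
      L <- do.call(sim_config, args)$chrom_length
      list(depth_mean = 261,
           diversity_scale = 2,
           sexlink_region = region_spec("chr1", floor(0.05 * L) + 1,
                                        floor(0.95 * L), "chr1-wide"))
    },
    null = list(d = 0)
  )
  cfg <- do.call(sim_config, utils::modifyList(defaults, args))
  cfg$preset <- preset
  cfg
}

#' Simulate the gene annotation and SNP positions
#'
#' Genes are laid on a regular non-overlapping grid per chromosome; SNP
#' positions are drawn uniformly without replacement within each gene span.
#' Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return A list with `genes` (gene interval data.frame) and `snps`
#'   (data.frame `chrom`, `pos`, `gene_id`, sorted by chrom then pos).
#' @export
simulate_genome <- function(config) {
  set.seed(derive_seed(config$seed, 1L))
  unit <- config$gene_length + config$gene_spacing
  offset <- floor(config$gene_spacing / 2)
  k <- seq_len(config$genes_per_chrom)
  genes <- do.call(rbind, lapply(config$chrom_names, function(ch) {
    start <- (k - 1L) * unit + offset + 1L
    data.frame(gene_id = sprintf("%s_g%03d", ch, k), chrom = ch,
               start = start, end = start + config$gene_length - 1L,
               strand = ".", stringsAsFactors = FALSE)
  }))
  snps <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    data.frame(chrom = genes$chrom[i],
               pos = sort(sample(genes$start[i]:genes$end[i],
                                 config$snps_per_gene)),
               gene_id = genes$gene_id[i], stringsAsFactors = FALSE)
  }))
  snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]
  rownames(genes) <- rownames(snps) <- NULL
  list(genes = genes, snps = snps)
}

#' Simulate ground-truth allele frequencies
#'
#' Background SNPs receive one population variant-allele frequency
#' `p ~ Beta(bg_alpha * diversity_scale, bg_beta)` shared by the sexes.
#' Region SNPs become X-Y divergent with probability `d` (when recombination
#' is suppressed): females are X/X with true frequency `x_freq`, males X/Y
#' with true frequency `(x_freq + y_freq) / 2`. Reference and variant bases
#' are drawn per site.
#'
#' @param config A [sim_config()].
#' @param genome Output of [simulate_genome()].
#' @return A `SimTruth` data.frame: `chrom`, `pos`, `gene_id`, `ref`,
#'   `variant`, `sexlinked`, `p_x`, `p_y`, `p_female`, `p_male`, `fst_true`
#'   (per-site F_ST at the true frequencies, `n = pool_size` per pool), plus a
#'   per-gene expected F_ST table in `attr(, "gene_truth")`.
#' @export
simulate_frequencies <- function(config, genome) {
  set.seed(derive_seed(config$seed, 2L))
  snps <- genome$snps
  n <- nrow(snps)
  ref_idx <- sample.int(4L, n, replace = TRUE)
  shift <- sample.int(3L, n, replace = TRUE)
  var_idx <- ((ref_idx - 1L + shift) %% 4L) + 1L
  region <- config$sexlink_region
  in_region <- snps$chrom == region$chrom &
    snps$pos >= region$start & snps$pos <= region$end
  sexlinked <- in_region & config$recomb_suppressed &
    (stats::runif(n) < config$d)
  p_bg <- stats::rbeta(n, config$bg_alpha * config$diversity_scale,
                       config$bg_beta)
  p_x <- ifelse(sexlinked, config$x_freq, p_bg)
  p_y <- ifelse(sexlinked, config$y_freq, p_bg)
  p_female <- p_x
  p_male <- (p_x + p_y) / 2
  comp <- site_components(p_female, p_male, 1, 1,
                          config$pool_size, config$pool_size)
  truth <- data.frame(chrom = snps$chrom, pos = snps$pos,
                      gene_id = snps$gene_id,
                      ref = NUC_BASES[ref_idx], variant = NUC_BASES[var_idx],
                      sexlinked = sexlinked,
                      p_x = p_x, p_y = p_y,
                      p_female = p_female, p_male = p_male,
                      fst_true = site_fst(comp$a, comp$b),
                      stringsAsFactors = FALSE)
  gsum <- rowsum(cbind(a = comp$a, ab = comp$a + comp$b,
                       sexlinked = as.numeric(sexlinked)),
                 truth$gene_id)
  attr(truth, "gene_truth") <- data.frame(
    gene_id = rownames(gsum),
    expected_fst = ifelse(gsum[, "ab"] > 1e-12, gsum[, "a"] / gsum[, "ab"], NA_real_),
    n_sexlinked = as.integer(gsum[, "sexlinked"]),
    row.names = NULL, stringsAsFactors = FALSE
  )
  truth
}

# Split integer counts uniformly over three bins (miscall redistribution).
split3 <- function(nvec) {
  c1 <- stats::rbinom(length(nvec), nvec, 1 / 3)
  rem <- nvec - c1
  c2 <- stats::rbinom(length(nvec), rem, 1 / 2)
  cbind(c1, c2, rem - c2)
}

# Indices of the three non-b bases for each site, ascending base order.
other_bases <- function(b_idx) {
  n <- length(b_idx)
  all_idx <- matrix(rep(1:4, each = n), n, 4L)
  matrix(t(all_idx)[t(all_idx != b_idx)], n, 3L, byrow = TRUE)
}

#' Simulate a readcount table from ground truth
#'
#' Per pool replicate and site: (1) the replicate's finite-pool frequency is
#' `Binomial(2 * pool_size, p_true) / (2 * pool_size)` (each replicate is an
#' independent pool of individuals); (2) depth is negative binomial; (3)
#' variant reads are binomial at the pool frequency, and every read miscalls
#' with probability `error_rate`, redistributed uniformly over the other three
#' bases. Replicates are named `F1..Fk`, `M1..Mk`.
#'
#' @param config A [sim_config()].
#' @param truth Output of [simulate_frequencies()].
#' @return A readcount data.frame in the [parse_readcounts()] dialect, with
#'   the pool layout in `attr(, "pools")`.
#' @export
simulate_readcounts <- function(config, truth) {
  set.seed(derive_seed(config$seed, 3L))
  n <- nrow(truth)
  ref_idx <- match(truth$ref, NUC_BASES)
  var_idx <- match(truth$variant, NUC_BASES)
  oth_ref <- other_bases(ref_idx)
  oth_var <- other_bases(var_idx)
  copies <- 2L * config$pool_size
  out <- data.frame(chrom = truth$chrom, pos = truth$pos, ref = truth$ref,
                    stringsAsFactors = FALSE)
  pools <- list(female = paste0("F", seq_len(config$replicates)),
                male = paste0("M", seq_len(config$replicates)))
  for (g in names(pools)) {
    p_true <- truth[[paste0("p_", g)]]
    for (r in pools[[g]]) {
      pool_p <- stats::rbinom(n, copies, p_true) / copies
      depth <- stats::rnbinom(n, mu = config$depth_mean, size = config$depth_size)
      var_reads <- stats::rbinom(n, depth, pool_p)
      ref_reads <- depth - var_reads
      mis_ref <- stats::rbinom(n, ref_reads, config$error_rate)
      mis_var <- stats::rbinom(n, var_reads, config$error_rate)
      counts <- matrix(0, n, 4L)
      idx <- seq_len(n)
      counts[cbind(idx, ref_idx)] <- counts[cbind(idx, ref_idx)] + ref_reads - mis_ref
      counts[cbind(idx, var_idx)] <- counts[cbind(idx, var_idx)] + var_reads - mis_var
      sp_ref <- split3(mis_ref)
      sp_var <- split3(mis_var)
      for (k in 1:3) {
        counts[cbind(idx, oth_ref[, k])] <- counts[cbind(idx, oth_ref[, k])] + sp_ref[, k]
        counts[cbind(idx, oth_var[, k])] <- counts[cbind(idx, oth_var[, k])] + sp_var[, k]
      }
      block <- cbind(counts, 0)
      colnames(block) <- count_columns(r)
      out <- cbind(out, as.data.frame(block))
    }
  }
  rownames(out) <- NULL
  attr(out, "pools") <- pools
  out
}

#' Run the generator and write a complete synthetic dataset
#'
#' Emits `readcounts.tsv`, `genes.bed`, `truth.tsv` and the fully resolved
#' configuration `config.yaml` under `out_dir`.
#'
#' @param config A [sim_config()] or [scenario_presets()] result.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with `genome`, `truth`, `counts` and `paths`.
#' @export
run_simulate <- function(config, out_dir) {
  genome <- simulate_genome(config)
  truth <- simulate_frequencies(config, genome)
  counts <- simulate_readcounts(config, truth)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    readcounts = file.path(out_dir, "readcounts.tsv"),
    genes = file.path(out_dir, "genes.bed"),
    truth = file.path(out_dir, "truth.tsv"),
    config = file.path(out_dir, "config.yaml")
  )
  params <- list(generator = "sexfst-simgen", seed = config$seed,
                 preset = if (is.null(config$preset)) "custom" else config$preset)
  write_readcounts(counts, paths$readcounts, params)
  write_gene_bed(genome$genes, paths$genes)
  write_tsv_with_header(truth, paths$truth, params)
  cfg <- config
  cfg$sexlink_region <- as.list(cfg$sexlink_region)
  yaml::write_yaml(unclass(cfg), paths$config)
  invisible(list(genome = genome, truth = truth, counts = counts, paths = paths))
}
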