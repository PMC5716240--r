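# Sex-linkage classification, regional tests, enrichment and diagnostics.

fake_genes <- function(fst, chrom = "chr1", hexp_m = NULL, hexp_f = NULL,
                       start = NULL) {
  n <- length(fst)
  if (is.null(start)) start <- seq(100L, by = 1000L, length.out = n)
  g <- data.frame(gene_id = sprintf("g%03d", seq_len(n)), chrom = chrom,
                  start = start, end = start + 500L,
                  midpoint = start + 250, m = 1L,
                  sum_a = fst, sum_b = 1 - fst, fst = fst,
                  stringsAsFactors = FALSE)
  g$mean_hexp_female <- if (is.null(hexp_f)) rep(0.1, n) else hexp_f
  g$mean_hexp_male <- if (is.null(hexp_m)) rep(0.1, n) else hexp_m
  attr(g, "groups") <- c("female", "male")
  g
}

test_that("the high-F_ST flag is inclusive at the threshold and skips undefined values", {
  g <- classify_high_fst(fake_genes(c(0.100, 0.0999, NA, 0.5)), 0.100)
  expect_equal(g$high_fst, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(attr(g, "n_undefined"), 1L)
  expect_error(classify_high_fst(fake_genes(0.2), 0), "threshold")
})

test_that("flagged counts are monotone non-increasing in the threshold", {
  withr::local_seed(3)
  g <- fake_genes(runif(300))
  counts <- vapply(seq(0.05, 0.95, 0.05),
                   function(t) sum(classify_high_fst(g, t)$high_fst), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the male heterozygosity test is one-sided with the expected symmetries", {
  withr::local_seed(4)
  base <- runif(60, 0.05, 0.3)
  even <- male_hexp_test(fake_genes(rep(0.2, 60), hexp_m = base, hexp_f = base))
  expect_equal(even$statistic, 0)
  expect_equal(even$p_value, 0.5, tolerance = 1e-12)

  lower <- male_hexp_test(fake_genes(rep(0.2, 60), hexp_m = base - 0.02,
                                     hexp_f = base))
  expect_gt(lower$p_value, 0.5)

  # label swap reverses the direction: one-sided p-values sum to >= 1 (Welch)
  m <- base + 0.01
  p_fwd <- male_hexp_test(fake_genes(rep(0.2, 60), hexp_m = m, hexp_f = base))$p_value
  p_rev <- male_hexp_test(fake_genes(rep(0.2, 60), hexp_m = base, hexp_f = m))$p_value
  expect_gte(p_fwd + p_rev, 1)

  # invariance to gene order
  perm <- sample(60)
  p_perm <- male_hexp_test(fake_genes(rep(0.2, 60), hexp_m = m[perm],
                                      hexp_f = base[perm]))$p_value
  expect_equal(p_fwd, p_perm)
})

test_that("a 0.05 shift over 200 genes matches the closed-form Welch computation", {
  withr::local_seed(5)
  f <- rnorm(200, 0.10, 0.04)
  m <- f + 0.05
  got <- male_hexp_test(fake_genes(rep(0.2, 200), hexp_m = m, hexp_f = f))
  # independent reference: Welch statistic and Satterthwaite df by hand
  se <- sqrt(var(m) / 200 + var(f) / 200)
  tstat <- (mean(m) - mean(f)) / se
  df <- se^4 / ((var(m) / 200)^2 / 199 + (var(f) / 200)^2 / 199)
  expect_equal(got$statistic, tstat, tolerance = 1e-12)
  expect_equal(got$p_value, pt(tstat, df, lower.tail = FALSE), tolerance = 1e-12)
  expect_lt(got$p_value, 1e-10)
  # the paired variant is even sharper for a constant shift
  paired <- male_hexp_test(fake_genes(rep(0.2, 200), hexp_m = m, hexp_f = f),
                           mode = "paired")
  expect_lt(paired$p_value, 1e-10)
})

test_that("regions select genes by midpoint and tiny regions warn", {
  g <- fake_genes(rep(0.2, 10), hexp_m = seq(0.1, 0.19, 0.01),
                  hexp_f = rep(0.1, 10))
  reg <- region_spec("chr1", 1, 1000, "left-edge")   # only one gene midpoint inside
  expect_warning(res <- male_hexp_test(g, reg), "fewer than 2")
  expect_true(is.na(res$p_value))
  expect_error(region_spec("chr1", 10, 10, "bad"), "start must be < end")
})

test_that("chromosome enrichment matches the exact hypergeometric tail", {
  g <- fake_genes(c(rep(0.5, 10), rep(0.01, 90),    # chr1: 10/100 flagged
                    rep(0.5, 1), rep(0.01, 99)),    # chr2: 1/100 flagged
                  chrom = rep(c("chr1", "chr2"), each = 100))
  g <- classify_high_fst(g, 0.1)
  enr <- chromosome_enrichment(g)
  want_chr1 <- oracle_fisher_greater(10, 1, 90, 99)
  expect_equal(enr$p_value[enr$chrom == "chr1"], want_chr1, tolerance = 1e-12)
  # agreement with the canonical implementation
  ft <- fisher.test(matrix(c(10, 90, 1, 99), 2, byrow = TRUE),
                    alternative = "greater")
  expect_equal(enr$p_value[enr$chrom == "chr1"], ft$p.value, tolerance = 1e-9)

  # identical proportions: no enrichment anywhere
  g2 <- classify_high_fst(fake_genes(rep(c(0.5, 0.01, 0.01, 0.01), 50),
                                     chrom = rep(c("chr1", "chr2"), each = 100)), 0.1)
  enr2 <- chromosome_enrichment(g2)
  expect_true(all(enr2$p_value >= 0.5))

  # all flagged genes on one chromosome: decisive enrichment there
  g3 <- classify_high_fst(fake_genes(c(rep(0.5, 30), rep(0.01, 70), rep(0.01, 100)),
                                     chrom = rep(c("chr1", "chr2"), each = 100)), 0.1)
  expect_lt(chromosome_enrichment(g3)$p_value[1], 1e-6)

  expect_warning(chromosome_enrichment(classify_high_fst(
    fake_genes(rep(0.01, 40), chrom = rep(c("chr1", "chr2"), 20)), 0.1)),
    "no flagged genes")
})

test_that("category over-representation is the exact upper hypergeometric tail", {
  universe <- setNames(rep(c("repair", "other"), c(10, 90)), sprintf("g%03d", 1:100))
  selected <- c(sprintf("g%03d", 1:5), sprintf("g%03d", 50:54))  # 5 of 10 repair genes
  res <- category_overrepresentation(universe, selected)
  want <- oracle_hyper_upper(5, 10, 100, 10)
  expect_equal(res$p_value[res$category == "repair"], want, tolerance = 1e-12)

  # a category that covers the whole universe can never be enriched
  uni_all <- setNames(rep("everything", 50), sprintf("g%03d", 1:50))
  expect_equal(category_overrepresentation(uni_all, sprintf("g%03d", 1:10))$p_value, 1)
  # zero overlap is never enriched
  res0 <- category_overrepresentation(universe, sprintf("g%03d", 11:20))
  expect_equal(res0$p_value[res0$category == "repair"], 1)
  expect_warning(category_overrepresentation(universe, c("g001", "nope")), "absent")
})

test_that("population intersection is an exact sorted set operation", {
  expect_equal(intersect_populations(c("g1", "g2", "g3"), c("g2", "g3", "g4"))$common,
               c("g2", "g3"))
  expect_equal(intersect_populations(c("g1"), c("g9"))$common, character(0))
  expect_equal(intersect_populations(c("g1", "g2"), c("g3", "g2", "g1"))$common,
               c("g1", "g2"))
  genes <- fake_genes(rep(0.2, 4), chrom = c("chr1", "chr1", "chr2", "chr3"))
  tally <- intersect_populations(genes$gene_id[1:3], genes$gene_id[2:4],
                                 genes)$by_chrom
  expect_equal(tally$n_common, c(1L, 1L, 0L))
})

test_that("between-population F_ST reuses the estimator with the expected limits", {
  cfg <- sim_config(seed = 21, genes_per_chrom = 6, depth_mean = 80)
  genome <- simulate_genome(cfg)
  truth <- simulate_frequencies(cfg, genome)
  counts <- simulate_readcounts(cfg, truth)
  pools <- attr(counts, "pools")

  # identical count tables in both populations: no between-group variance
  res <- between_population_fst(counts, counts, pools, pools, "female",
                                genes = genome$genes)
  defined <- res$sites$fst[!is.na(res$sites$fst)]
  expect_gt(length(defined), 0)
  expect_true(all(defined <= 0))
  # output schema identical to the inter-sex site table
  inter <- site_stats(filter_sites(counts, pools)$pooled)
  expect_equal(sub("popX_female|popY_female", "GROUP", names(res$sites)),
               sub("female|male", "GROUP", names(inter)))

  # a fully fixed difference gives gene F_ST of 1
  fx <- bind_counts(uniform_site("chr1", 600, "A",
                                 female = c(C = 40), male = c(C = 40)))
  fy <- bind_counts(uniform_site("chr1", 600, "A",
                                 female = c(A = 40), male = c(A = 40)))
  res2 <- between_population_fst(fx, fy, default_pools(), default_pools(),
                                 "female", genes = genome$genes,
                                 monomorphic_drop = FALSE)
  expect_equal(res2$genes$fst, 1)
})

test_that("beta fitting recovers shapes by method of moments", {
  # the method-of-moments identity itself
  x <- c(0.2, 0.4, 0.25, 0.3, 0.35, 0.22, 0.28, 0.31, 0.26, 0.38)
  fit <- fit_beta(x)
  m <- mean(x); v <- var(x)
  expect_equal(fit$alpha, m * (m * (1 - m) / v - 1), tolerance = 1e-12)
  expect_equal(fit$beta, (1 - m) * (m * (1 - m) / v - 1), tolerance = 1e-12)

  withr::local_seed(6)
  draws <- rbeta(10000, 2, 5)
  fit2 <- fit_beta(draws)
  expect_lt(abs(fit2$alpha - 2) / 2, 0.10)
  expect_lt(abs(fit2$beta - 5) / 5, 0.10)
  expect_true(is.finite(fit2$ks_stat))

  expect_warning(const <- fit_beta(rep(0.3, 50)), "undefined")
  expect_true(is.na(const$alpha))
})

test_that("variant density per aligned kilobase is scale-free arithmetic", {
  expect_equal(variant_alignment_ratio(2000, 1e6, 100), 0.02)
  expect_equal(variant_alignment_ratio(0, 1e6), 0)
  expect_equal(variant_alignment_ratio(4000, 2e6, 100),
               variant_alignment_ratio(2000, 1e6, 100))
  expect_error(variant_alignment_ratio(10, 0), "positive")
})
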