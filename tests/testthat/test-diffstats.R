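# Estimator core: frequencies, heterozygosity, variance components, F_ST and
# gene aggregation.

test_that("variant-allele frequency is variant coverage over nucleotide coverage", {
  expect_equal(allele_freq(c(A = 30, C = 10), "C"), 0.25)
  expect_equal(allele_freq(c(C = 40), "C"), 1.0)
  expect_equal(allele_freq(c(A = 7, C = 1, G = 2), "C"), 0.1)
  expect_equal(allele_freq(c(A = 10, C = 5, indel = 100), "C"), 1 / 3)  # indels excluded
  expect_error(allele_freq(c(A = 0), "C"), "zero nucleotide coverage")
})

test_that("expected heterozygosity is 2p(1-p), symmetric with maximum 0.5", {
  expect_equal(hexp(0.5), 0.5)
  expect_equal(hexp(0), 0)
  expect_equal(hexp(0.25), 0.375)
  expect_equal(hexp(0.3), hexp(0.7))
  expect_error(hexp(1.2), "contract error")
})

test_that("the fully sex-linked worked case reproduces the hand-derived components", {
  # n_i = n_j = 12, p_i = 1, p_j = 0.5, equal coverage:
  #   b = (12*0 + 12*0.5)/23 = 6/23, a = (6 - 6/23)/24, a + b = 1/2 exactly
  comp <- site_components(1.0, 0.5, 100, 100, 12, 12)
  expect_equal(comp$a, 11 / 46, tolerance = 1e-12)   # (6 - 6/23) / 24
  expect_equal(comp$b, 6 / 23, tolerance = 1e-12)
  expect_lt(abs(comp$a - 0.239130), 1e-6)
  expect_lt(abs(comp$b - 0.260870), 1e-6)
  expect_equal(comp$a + comp$b, 0.5, tolerance = 1e-12)
  expect_lt(abs(site_fst(comp$a, comp$b) - 0.478261), 1e-6)

  # identical intermediate frequencies give a legally negative between component
  comp2 <- site_components(0.5, 0.5, 100, 100, 12, 12)
  expect_equal(comp2$b, 12 / 23, tolerance = 1e-12)
  expect_equal(comp2$a, -(12 / 23) / 24, tolerance = 1e-12)

  # all terms vanish at p_i = p_j = 0
  comp3 <- site_components(0, 0, 50, 80, 12, 12)
  expect_equal(comp3$a, 0)
  expect_equal(comp3$b, 0)
})

test_that("site F_ST handles the degenerate and fixed-difference limits", {
  expect_true(is.na(site_fst(0, 0)))
  expect_equal(site_fst(0.4, 0), 1.0)
  expect_error(site_components(0.5, 0.5, 100, 100, 0.5, 0.5), "n_i \\+ n_j")
  expect_error(site_components(0.5, 0.5, 0, 100, 12, 12), "coverages")
  expect_error(site_components(1.5, 0.5, 10, 10, 12, 12), "frequencies")
})

test_that("components match an independent transcription on randomized inputs", {
  withr::local_seed(1)
  n_cases <- 2000
  p_i <- runif(n_cases); p_j <- runif(n_cases)
  cov_i <- runif(n_cases, 15, 400); cov_j <- runif(n_cases, 15, 400)
  n_i <- sample(1:50, n_cases, replace = TRUE)
  n_j <- sample(2:50, n_cases, replace = TRUE)
  comp <- site_components(p_i, p_j, cov_i, cov_j, n_i, n_j)
  for (k in seq_len(n_cases)) {
    want <- oracle_components(p_i[k], p_j[k], cov_i[k], cov_j[k], n_i[k], n_j[k])
    expect_equal(comp$a[k], unname(want["a"]), tolerance = 1e-12)
    expect_equal(comp$b[k], unname(want["b"]), tolerance = 1e-12)
  }
  # structural invariants over the same sweep
  expect_true(all(comp$b >= 0))
  expect_true(all(comp$a + comp$b >= -1e-12))
  fst <- site_fst(comp$a, comp$b)
  expect_true(all(fst[!is.na(fst)] <= 1 + 1e-12))
})

test_that("F_ST equals one exactly when the within component vanishes", {
  comp <- site_components(0, 1, 120, 90, 12, 12)   # fixed difference
  expect_equal(comp$b, 0)
  expect_gt(comp$a, 0)
  expect_equal(site_fst(comp$a, comp$b), 1)
})

test_that("site F_ST grows with frequency divergence at equal coverage", {
  for (p_j in c(0.2, 0.5)) {
    up <- vapply(seq(p_j, 1, 0.01), function(p_i) {
      comp <- site_components(p_i, p_j, 100, 100, 12, 12)
      site_fst(comp$a, comp$b)
    }, numeric(1))
    down <- vapply(seq(p_j, 0, -0.01), function(p_i) {
      comp <- site_components(p_i, p_j, 100, 100, 12, 12)
      site_fst(comp$a, comp$b)
    }, numeric(1))
    expect_true(all(diff(up) >= -1e-12))
    expect_true(all(diff(down) >= -1e-12))
  }
})

test_that("the half-fixed case approaches F_ST 0.5 as sample size grows", {
  fst_at <- function(n) {
    comp <- site_components(0, 0.5, 100, 100, n, n)
    site_fst(comp$a, comp$b)
  }
  ns <- c(10, 100, 1000, 10000)
  gaps <- abs(vapply(ns, fst_at, numeric(1)) - 0.5)
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[length(gaps)], 1e-4)
})

test_that("gene F_ST is the ratio of sums, not the mean of ratios", {
  a <- c(0.1, 0.1); b <- c(0.1, 0.7)
  expect_equal(gene_fst(a, b), 0.2)
  expect_false(isTRUE(all.equal(gene_fst(a, b), mean(a / (a + b)))))  # 0.3125
  expect_equal(mean(a / (a + b)), 0.3125)

  expect_lt(abs(gene_fst(11 / 46, 6 / 23) - 0.478261), 1e-6)  # reduces to site_fst
  withr::local_seed(2)
  a <- runif(9); b <- runif(9)
  perm <- sample(9)
  expect_equal(gene_fst(a, b), gene_fst(a[perm], b[perm]))
  expect_true(is.na(gene_fst(0, 0)))
})

test_that("sites land in every covering gene with closed-interval boundaries", {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                      start = c(100L, 180L), end = c(200L, 260L), strand = ".",
                      stringsAsFactors = FALSE)
  sites <- data.frame(chrom = "chr1", pos = c(99L, 100L, 150L, 200L, 190L, 261L))
  asg <- assign_sites_to_genes(sites, genes)
  hits <- split(asg$gene_id, asg$site_row)
  expect_null(hits[["1"]])                      # 99 outside
  expect_equal(hits[["2"]], "gA")               # start boundary inclusive
  expect_equal(hits[["4"]], c("gA", "gB"))      # end boundary + overlap region
  expect_equal(sort(hits[["5"]]), c("gA", "gB"))  # inside two overlapping genes
  expect_null(hits[["6"]])
})

test_that("gene statistics aggregate site components and mean heterozygosity", {
  pooled <- filter_sites(bind_counts(
    uniform_site("chr1", 110, "A", female = c(C = 40), male = c(A = 20, C = 20)),
    uniform_site("chr1", 120, "A", female = c(A = 30, C = 10), male = c(A = 20, C = 20)),
    uniform_site("chr2", 50, "A", female = c(A = 30, C = 10), male = c(A = 35, C = 5))
  ))$pooled
  sites <- site_stats(pooled, n_i = 12, n_j = 12)
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = c("chr1", "chr2"),
                      start = c(100L, 40L), end = c(150L, 60L), strand = ".",
                      stringsAsFactors = FALSE)
  gs <- gene_stats(sites, genes)
  expect_equal(gs$m, c(2L, 1L))
  i <- which(gs$gene_id == "g1")
  rows <- sites$chrom == "chr1"
  expect_equal(gs$sum_a[i], sum(sites$a_s[rows]))
  expect_equal(gs$fst[i], sum(sites$a_s[rows]) / sum(sites$a_s[rows] + sites$b_s[rows]))
  expect_equal(gs[[paste0("mean_hexp_female")]][i], mean(sites$hexp_female[rows]))
  # genes without any retained SNP are omitted
  genes3 <- rbind(genes, data.frame(gene_id = "g3", chrom = "chr3",
                                    start = 1L, end = 10L, strand = "."))
  expect_equal(nrow(gene_stats(sites, genes3)), 2L)
})
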