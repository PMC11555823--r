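de_tbl <- function(genes, lfc, padj, bm = NULL) {
  x <- tibble::tibble(gene = genes, log2fc = lfc, p_adj = padj)
  if (!is.null(bm)) x$base_mean <- bm
  x
}

test_that("merging by symbol takes the intersection and rejects duplicates", {
  a <- de_tbl(c("g1", "g2", "g3"), c(1, 2, 3), c(0.1, 0.2, 0.3))
  b <- de_tbl(c("g2", "g3", "g4"), c(-2, -3, -4), c(0.01, 0.02, 0.03))
  j <- merge_by_symbol(a, b)
  expect_equal(j$gene, c("g2", "g3"))

  dupe <- de_tbl(c("g1", "g1"), c(1, 1), c(0.1, 0.1))
  expect_error(merge_by_symbol(dupe, b), "duplicate",
               class = "asorescue_duplicate_id")
})

test_that("symbol case is respected unless folding is requested", {
  a <- de_tbl("Sox13", 1, 0.01)
  b <- de_tbl("SOX13", -1, 0.01)
  expect_equal(nrow(merge_by_symbol(a, b)), 0)
  expect_equal(nrow(merge_by_symbol(a, b, case_fold = TRUE)), 1)
})

test_that("NA effects stay in the universe but out of the correlation", {
  a <- de_tbl(c("g1", "g2", "g3"), c(1, 2, 3), c(0.01, 0.01, 0.01))
  b <- de_tbl(c("g1", "g2", "g3"), c(-1, NA, -3), c(0.01, 0.01, 0.01))
  j <- merge_by_symbol(a, b)
  expect_equal(nrow(j), 3)
  res <- directional_correlation(j)
  expect_equal(res$n, 2)
})

test_that("shared significance uses the AND rule and is monotone in alpha", {
  j <- merge_by_symbol(
    de_tbl(c("g1", "g2", "g3"), c(1, 1, 1), c(0.04, 0.04, 0.2)),
    de_tbl(c("g1", "g2", "g3"), c(1, 1, 1), c(0.06, 0.01, 0.01)))
  expect_equal(shared_signature(j, 0.05), "g2")
  expect_equal(shared_signature(j, 1), c("g1", "g2", "g3"))
  expect_true(all(shared_signature(j, 0.05) %in% shared_signature(j, 0.1)))
})

test_that("fisher_overlap equals the exhaustive hypergeometric oracle", {
  expect_equal(fisher_overlap(100, 10, 10, 10),
               hyper_tail_oracle(100, 10, 10, 10), tolerance = 1e-12)
  p_indep <- fisher_overlap(100, 50, 50, 25)
  expect_gt(p_indep, 0.05)
  expect_lt(p_indep, 0.7)
  expect_equal(fisher_overlap(100, 0, 10, 0), 1)

  # exhaustive sweep over small universes
  for (N in c(1:12, 30)) {
    for (a in 0:N) for (b in 0:N) {
      for (s in max(0, a + b - N):min(a, b)) {
        expect_equal(fisher_overlap(N, a, b, s),
                     hyper_tail_oracle(N, a, b, s), tolerance = 1e-10)
      }
    }
  }
})

test_that("fisher_overlap agrees with fisher.test and validates counts", {
  set.seed(10)
  for (i in 1:20) {
    N <- sample(20:200, 1)
    a <- pick1(0:N); b <- pick1(0:N)
    s <- pick1(max(0, a + b - N):min(a, b))
    tab <- matrix(c(s, a - s, b - s, N - a - b + s), 2, 2)
    expect_equal(fisher_overlap(N, a, b, s),
                 stats::fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-8)
  }
  expect_error(fisher_overlap(10, 12, 3, 1), "inconsistent")
  expect_error(fisher_overlap(10, 3, 3, 4), "inconsistent")
})

test_that("directional correlation hits the exact reciprocal limits", {
  a <- de_tbl(paste0("g", 1:10), rnorm(10), rep(0.01, 10))
  b_anti <- de_tbl(a$gene, -a$log2fc, rep(0.01, 10))
  b_same <- de_tbl(a$gene, a$log2fc, rep(0.01, 10))
  expect_equal(directional_correlation(merge_by_symbol(a, b_anti))$r, -1)
  expect_equal(directional_correlation(merge_by_symbol(a, b_same))$r, 1)
})

test_that("r is scale-invariant and antisymmetric under negation", {
  set.seed(11)
  a <- de_tbl(paste0("g", 1:50), rnorm(50), rep(0.01, 50))
  b <- de_tbl(a$gene, 0.3 * a$log2fc + rnorm(50, 0, 0.5), rep(0.01, 50))
  r0 <- directional_correlation(merge_by_symbol(a, b))$r
  b_scaled <- dplyr::mutate(b, log2fc = 7 * log2fc)
  expect_equal(directional_correlation(merge_by_symbol(a, b_scaled))$r, r0,
               tolerance = 1e-12)
  b_neg <- dplyr::mutate(b, log2fc = -log2fc)
  expect_equal(directional_correlation(merge_by_symbol(a, b_neg))$r, -r0,
               tolerance = 1e-12)
})

test_that("small shared sets report r without a p-value", {
  a <- de_tbl(c("g1", "g2"), c(1, 2), c(0.01, 0.01))
  b <- de_tbl(c("g1", "g2"), c(2, 1), c(0.01, 0.01))
  res <- directional_correlation(merge_by_symbol(a, b))
  expect_true(is.na(res$p))
  expect_false(is.na(res$r))
})

test_that("compare_signatures assembles counts, test and correlation", {
  set.seed(12)
  genes <- paste0("g", 1:300)
  lfc <- rnorm(300)
  a <- de_tbl(genes, lfc, c(rep(0.01, 100), runif(200, 0.1, 1)))
  b <- de_tbl(genes, -lfc, c(rep(0.01, 80), runif(220, 0.1, 1)))
  res <- compare_signatures(a, b)
  expect_equal(res$n_universe, 300)
  expect_equal(res$n_shared, 80)
  expect_lt(res$fisher_p, 1e-6)
  expect_equal(res$pearson_r, -1)
  g <- glance(res)
  expect_equal(g$n_sig_a, 100)
  expect_equal(g$n_sig_b, 80)
})
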