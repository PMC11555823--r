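pooled_fixture <- function() {
  # genes x 4 canonical pools, log2 scale
  m <- rbind(gA = c(1, 2, 3, 4),
             gB = c(4, 3, 2, 1),
             gC = c(2, 2, 2, 2))
  colnames(m) <- c("unaffected_control", "unaffected_ASO1",
                   "affected_control", "affected_ASO1")
  m
}

test_that("pooled group CPM reduces to single-sample values and means", {
  m <- matrix(c(10, 90, 10, 90, 30, 70), 2, 3,
              dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  single <- pooled_group_cpm(m, list(one = "s3"))
  expect_equal(unname(single[, "one"]), log2(cpm(m)[, "s3"] + 0.5),
               ignore_attr = TRUE)
  pair <- pooled_group_cpm(m, list(two = c("s1", "s2")))
  expect_equal(unname(pair[, "two"]),
               unname(rowMeans(log2(cpm(m)[, c("s1", "s2")] + 0.5))))
  perm <- pooled_group_cpm(m, list(two = c("s2", "s1")))
  expect_equal(pair, perm)
  expect_error(pooled_group_cpm(m, list(none = character())), "empty")
})

test_that("dose pooling averages the per-dose samples", {
  sim <- shared_sim()
  d <- sim$design
  pools_pooled <- rescue_pools(d, pool_doses = TRUE)
  pools_split <- rescue_pools(d, pool_doses = FALSE)
  expect_setequal(pools_pooled$affected_ASO1,
                  c(pools_split$affected_ASO1_6.6, pools_split$affected_ASO1_20))
  m <- counts_matrix(sim$counts)[1:50, ]
  p1 <- pooled_group_cpm(m, pools_pooled)
  p2 <- pooled_group_cpm(m, pools_split)
  # equal per-dose sample counts make the pooled mean the mean of means
  expect_equal(unname(p1[, "affected_ASO1"]),
               unname((p2[, "affected_ASO1_6.6"] + p2[, "affected_ASO1_20"]) / 2))
})

test_that("the sign-flip rule classifies the canonical cases", {
  pooled <- rbind(up_rescued = c(0, 0, 0.8, 0.5),    # treat ratio -0.3
                  up_missed = c(0, 0, 0.8, 0.9),     # treat ratio +0.1
                  down_rescued = c(0.8, 0.8, 0, 0.3),
                  down_missed = c(0.8, 0.8, 0, -0.2))
  colnames(pooled) <- colnames(pooled_fixture())
  sig <- extract_signature(tibble::tibble(
    gene = rownames(pooled),
    log2fc = c(0.8, 0.8, -0.8, -0.8),
    p_adj = rep(1e-4, 4)))
  rep <- sign_flip_rescue(pooled, sig)
  expect_equal(rep$rescued,
               c(TRUE, FALSE, TRUE, FALSE)[match(rep$gene, rownames(pooled))])
  s <- glance(rep)
  expect_equal(sort(s$percent_rescued), c(50, 50))
})

test_that("rescue flags are invariant under a global sign flip", {
  set.seed(13)
  pooled <- matrix(rnorm(80), 20, 4,
                   dimnames = list(paste0("g", 1:20),
                                   colnames(pooled_fixture())))
  sig <- extract_signature(tibble::tibble(
    gene = rownames(pooled),
    log2fc = pooled[, "affected_control"] - pooled[, "unaffected_control"],
    p_adj = rep(1e-4, 20)))
  r1 <- sign_flip_rescue(pooled, sig)
  # negate both ratios by swapping the roles of the two genotype baselines
  flipped <- pooled
  flipped[, "affected_control"] <- -pooled[, "affected_control"]
  flipped[, "unaffected_control"] <- -pooled[, "unaffected_control"]
  flipped[, "affected_ASO1"] <- -pooled[, "affected_ASO1"]
  flipped[, "unaffected_ASO1"] <- -pooled[, "unaffected_ASO1"]
  sig_f <- extract_signature(tibble::tibble(
    gene = rownames(flipped),
    log2fc = flipped[, "affected_control"] - flipped[, "unaffected_control"],
    p_adj = rep(1e-4, 20)))
  r2 <- sign_flip_rescue(flipped, sig_f)
  expect_equal(r1$rescued, r2$rescued)
})

test_that("percent rescued equals the mean of the per-gene flags", {
  sim <- shared_sim()
  de <- run_contrast_scheme(sim$counts, sim$design)
  sig <- extract_signature(de$disease_signature)
  pooled <- pooled_group_cpm(sim$counts, rescue_pools(sim$design),
                             signature = sig)
  rep <- sign_flip_rescue(pooled, sig)
  s <- glance(rep)
  for (i in seq_len(nrow(s))) {
    flags <- rep$rescued[rep$arm == s$arm[i] & rep$direction == s$direction[i]]
    expect_equal(s$percent_rescued[i], 100 * mean(flags))
    expect_gte(s$percent_rescued[i], 0)
    expect_lte(s$percent_rescued[i], 100)
  }
})

test_that("rank patterns are permutations of 1..4 with canonical tie-break", {
  rp <- rank_order_patterns(pooled_fixture(), k = 2)
  expect_equal(unname(rp$ranks[rp$ranks$gene == "gA", 2:5] |> unlist()),
               1:4)
  expect_equal(unname(rp$ranks[rp$ranks$gene == "gB", 2:5] |> unlist()),
               4:1)
  # exact ties resolve in canonical column order
  expect_equal(unname(rp$ranks[rp$ranks$gene == "gC", 2:5] |> unlist()),
               1:4)
  expect_error(rank_order_patterns(pooled_fixture()[, 1:3]), "four")
})

test_that("rank clustering is invariant to gene input order", {
  set.seed(14)
  pooled <- matrix(rnorm(200), 50, 4,
                   dimnames = list(paste0("g", 1:50),
                                   colnames(pooled_fixture())))
  r1 <- rank_order_patterns(pooled, k = 4)
  perm <- sample(50)
  r2 <- rank_order_patterns(pooled[perm, ], k = 4)
  j <- dplyr::inner_join(r1$ranks, r2$ranks, by = "gene")
  expect_gt(adjusted_rand(j$cluster.x, j$cluster.y), 0.999)
})

test_that("halfway rescue places treated-affected pools between genotypes", {
  cfg <- sim_config(n_genes = 3000, n_dosage_up = 100, n_dosage_down = 200,
                    rescue_fraction = 0.9, rescue_strength = 0.5,
                    aberrant_strength = 0.5,
                    line_sd_log2 = 0.05, line_shared_sd_log2 = 0.1,
                    arms = default_arms(n_replicates = 2L))
  sim <- simulate_dataset(cfg, seed = 41)
  pooled <- pooled_group_cpm(sim$counts, rescue_pools(sim$design))
  resp <- sim$truth$gene[sim$truth$responsive]
  lo <- pmin(pooled[resp, "unaffected_control"], pooled[resp, "affected_control"])
  hi <- pmax(pooled[resp, "unaffected_control"], pooled[resp, "affected_control"])
  between <- pooled[resp, "affected_ASO1"] > lo & pooled[resp, "affected_ASO1"] < hi
  expect_gte(mean(between), 0.9)

  # the dominant rank clusters track target-gene dosage
  de <- run_contrast_scheme(sim$counts, sim$design)
  sig <- extract_signature(de$disease_signature)
  four <- pooled[intersect(sig$gene, rownames(pooled)),
                 c("unaffected_control", "unaffected_ASO1",
                   "affected_control", "affected_ASO1")]
  rp <- rank_order_patterns(four, sig)
  cons <- rp$clusters$dosage_consistent
  expect_gt(sum(rp$clusters$n_genes[cons]) / sum(rp$clusters$n_genes), 0.6)
})

test_that("PC shifts vanish when treatment does nothing", {
  cfg <- sim_config(n_genes = 800, n_dosage_up = 40, n_dosage_down = 80,
                    rescue_fraction = 0, knockdown_per_dose = c("6.6" = 1, "20" = 1))
  sim <- simulate_dataset(cfg, seed = 43)
  de <- run_contrast_scheme(sim$counts, sim$design)
  sig <- extract_signature(de$disease_signature)
  ps <- pc_shift_test(sim$counts, sim$design, sig)
  expect_true(all(ps$tests$p_value > 0.01, na.rm = TRUE))
})

test_that("PC orientation makes repeated runs identical in sign", {
  sim <- shared_sim()
  de <- run_contrast_scheme(sim$counts, sim$design)
  sig <- extract_signature(de$disease_signature)
  a <- pc_shift_test(sim$counts, sim$design, sig)
  b <- pc_shift_test(sim$counts, sim$design, sig)
  expect_identical(a$samples$delta, b$samples$delta)
  aff_ctrl <- dplyr::filter(a$samples, genotype == "affected",
                            treatment %in% c("naive", "scramble"))
  expect_gte(mean(aff_ctrl$score), 0)
})

test_that("treated samples without untreated line-mates are an error", {
  sim <- shared_sim()
  d <- sim$design
  keep <- !(d$cell_line == "A1" & d$treatment %in% c("naive", "scramble"))
  de <- run_contrast_scheme(sim$counts, sim$design)
  sig <- extract_signature(de$disease_signature)
  expect_error(
    pc_shift_test(sim$counts[, c("gene", d$sample_id[keep])], d[keep, ], sig),
    "A1")
})
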