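test_that("simulated dataset has the configured shape and valid tables", {
  cfg <- sim_config(
    n_genes = 2000, n_dosage_up = 50, n_dosage_down = 100,
    arms = tibble::tibble(
      treatment = c("naive", "scramble", "targeting", "targeting"),
      aso_sequence = c("none", "SCR", "ASO1", "ASO1"),
      dose = c(0, 20, 6.6, 20), n_replicates = 2L))
  sim <- simulate_dataset(cfg, seed = 1)
  expect_equal(nrow(sim$counts), 2000)
  expect_equal(ncol(sim$counts) - 1, 2 * 4 * 4 * 2)  # gt x line x arm x rep
  expect_silent(validate_counts(sim$counts))
  expect_silent(validate_design(sim$design))
  expect_equal(sum(sim$truth$class == "dosage_up"), 50)
  expect_equal(sum(sim$truth$class == "dosage_down"), 100)
  expect_true(all(sim$truth$true_lfc[sim$truth$class == "null"] == 0))
})

test_that("identical seeds reproduce bit-identical datasets", {
  cfg <- sim_config(n_genes = 300, n_dosage_up = 10, n_dosage_down = 20)
  a <- simulate_dataset(cfg, seed = 7)
  b <- simulate_dataset(cfg, seed = 7)
  expect_identical(a$counts, b$counts)
  expect_identical(a$design, b$design)
  c <- simulate_dataset(cfg, seed = 8)
  expect_false(identical(a$counts, c$counts))
})

test_that("appending arms does not perturb earlier arms' draws", {
  base_arms <- default_arms()[1:2, ]
  cfg1 <- sim_config(n_genes = 300, n_dosage_up = 10, n_dosage_down = 20,
                     arms = base_arms)
  cfg2 <- sim_config(n_genes = 300, n_dosage_up = 10, n_dosage_down = 20,
                     arms = default_arms()[1:3, ])
  a <- simulate_dataset(cfg1, seed = 3)
  b <- simulate_dataset(cfg2, seed = 3)
  shared <- intersect(names(a$counts), names(b$counts))
  expect_identical(a$counts[, shared], b$counts[, shared])
})

test_that("a null configuration carries no signal into the DE stage", {
  cfg <- sim_config(n_genes = 1500, n_dosage_up = 0, n_dosage_down = 0,
                    knockdown_per_dose = c("6.6" = 1, "20" = 1),
                    target_lfc = 0,
                    line_sd_log2 = 0, line_shared_sd_log2 = 0)
  sim <- simulate_dataset(cfg, seed = 11)
  d <- sim$design
  de <- nb_wald_test(
    sim$counts,
    d$sample_id[d$genotype == "affected" & d$treatment %in% c("naive", "scramble")],
    d$sample_id[d$genotype == "unaffected" & d$treatment %in% c("naive", "scramble")])
  expect_lt(sum(de$p_adj < 0.05, na.rm = TRUE), 5)
  p <- de$p_value[!is.na(de$p_value)]
  expect_lt(suppressWarnings(stats::ks.test(p, "punif")$statistic), 0.06)
})

test_that("per-gene means converge to the model mean at high replication", {
  cfg <- sim_config(n_genes = 400, n_dosage_up = 0, n_dosage_down = 0,
                    line_sd_log2 = 0, line_shared_sd_log2 = 0,
                    target_lfc = 0, effect_sdlog = 0,
                    library_size_range = c(1e6, 1e6),
                    arms = tibble::tibble(treatment = "naive",
                                          aso_sequence = "none", dose = 0,
                                          n_replicates = 25L))
  sim <- simulate_dataset(cfg, seed = 13)
  m <- counts_matrix(sim$counts)
  emp <- rowMeans(m)
  # with all effects off the model mean is library x relative baseline
  rel <- emp / sum(emp)
  expect_gt(stats::cor(log(emp + 1), log(1e6 * rel + 1)), 0.999)
  keep <- emp > 50
  expect_lt(stats::sd(log(rowMeans(m)[keep]) -
                        log(1e6 * rel[keep])), 0.2)
})

test_that("realized expected fold-changes match the configured signs", {
  sim <- shared_sim()
  pools <- rescue_pools(sim$design)
  pooled <- pooled_group_cpm(sim$counts, pools)
  base_ratio <- pooled[, "affected_control"] - pooled[, "unaffected_control"]
  tr <- sim$truth
  strong <- tr$class != "null" & abs(tr$true_lfc) > 0.5 & !tr$is_target
  agree <- sign(base_ratio[tr$gene[strong]]) ==
    sign(tr$true_lfc[strong])
  expect_gt(mean(agree), 0.95)
})

test_that("target-gene knockdown recovers the configured residual fraction", {
  cfg <- sim_config(n_genes = 1000, n_dosage_up = 30, n_dosage_down = 60,
                    arms = default_arms(n_replicates = 6L))
  sim <- simulate_dataset(cfg, seed = 17)
  m <- counts_matrix(sim$counts)
  d <- sim$design
  cm <- cpm(m)
  scr <- d$sample_id[d$genotype == "affected" & d$treatment == "scramble"]
  top <- d$sample_id[d$genotype == "affected" & d$treatment == "targeting" &
                       d$dose == 20]
  ratio <- mean(cm["TARGET", top]) / mean(cm["TARGET", scr])
  expect_lt(abs(log2(ratio) - log2(0.35)), 0.35)
})

test_that("companion table is exactly anticorrelated at full inversion", {
  sim <- shared_sim()
  comp <- simulate_companion_lof(sim$truth, inversion_fraction = 1,
                                 noise_sd = 0, seed = 5)
  truth_de <- dplyr::transmute(
    dplyr::filter(sim$truth, class != "null", !is_target),
    gene, log2fc = true_lfc, p_adj = 1e-6)
  joined <- merge_by_symbol(truth_de, comp)
  res <- directional_correlation(joined)
  expect_equal(res$r, -1)
  expect_true(all(res$labels$concordance == "inverse"))
})

test_that("half inversion gives near-zero expected correlation", {
  cfg <- sim_config(n_genes = 6000, n_dosage_up = 1000, n_dosage_down = 1000)
  sim <- simulate_dataset(cfg, seed = 19)
  comp <- simulate_companion_lof(sim$truth, inversion_fraction = 0.5,
                                 noise_sd = 0, seed = 23)
  truth_de <- dplyr::transmute(
    dplyr::filter(sim$truth, class != "null", !is_target),
    gene, log2fc = true_lfc, p_adj = 1e-6)
  res <- directional_correlation(merge_by_symbol(truth_de, comp))
  expect_lt(abs(res$r), 0.1)
})

test_that("an empty signature yields an empty companion table", {
  cfg <- sim_config(n_genes = 200, n_dosage_up = 0, n_dosage_down = 0)
  sim <- simulate_dataset(cfg, seed = 29)
  comp <- simulate_companion_lof(sim$truth, seed = 1)
  expect_equal(nrow(comp), 0)
})

test_that("config invariants are validated before sampling", {
  expect_error(sim_config(n_genes = 100, n_dosage_up = 60, n_dosage_down = 60),
               "null genes")
  expect_error(sim_config(rescue_fraction = 1.5), "rescue_fraction")
  expect_error(sim_config(knockdown_per_dose = c("6.6" = 0, "20" = 0.35)),
               "knockdown")
  expect_error(sim_config(knockdown_per_dose = c("20" = 0.35)), "6.6")
})
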