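#' Default treatment-arm layout
#'
#' One replicate per cell line of: naive (vehicle), scramble ASO at the top
#' 20 uM dose, and two independent targeting ASO sequences at 6.6 and 20 uM.
#' This mirrors the usual dose-response layout of ASO knockdown experiments
#' in patient-derived neurons.
#'
#' @param doses Targeting doses in uM.
#' @param aso_sequences Targeting ASO sequence labels.
#' @param n_replicates Replicates per cell line per arm.
#' @return A tibble with columns `treatment`, `aso_sequence`, `dose`,
#'   `n_replicates`.
#' @export
default_arms <- function(doses = c(6.6, 20), aso_sequences = c("ASO1", "ASO2"),
                         n_replicates = 1L) {
  base <- tibble(
    treatment = c("naive", "scramble"),
    aso_sequence = c("none", "SCR"),
    dose = c(0, 20),
    n_replicates = as.integer(n_replicates))
  targ <- tidyr::expand_grid(aso_sequence = aso_sequences, dose = doses)
  targ <- tibble(treatment = "targeting",
                 aso_sequence = targ$aso_sequence,
                 dose = targ$dose,
                 n_replicates = as.integer(n_replicates))
  bind_rows(base, targ)
}

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-count generator. The
#' defaults describe the emulated study: two genotypes (affected carries a
#' duplication of the target gene) with four cell lines each, a naive arm,
#' a scramble-ASO arm at 20 uM and two targeting ASO sequences at 6.6 and
#' 20 uM, ~12k genes of which 500 are truly up- and 1000 truly down-regulated
#' in the affected genotype (two thirds down), and a target gene knocked down
#' dose-dependently to 35% residual expression at the top dose.
#'
#' @param n_genes Number of genes.
#' @param n_lines_per_genotype Cell lines per genotype.
#' @param arms Arm layout tibble, see [default_arms()].
#' @param n_dosage_up,n_dosage_down Numbers of genes truly up/down in the
#'   affected genotype.
#' @param effect_size_log2 Mean |log2 fold-change| of true signature genes.
#' @param effect_sdlog Log-normal spread of per-gene effect magnitudes
#'   (0 gives every signature gene exactly `effect_size_log2`).
#' @param rescue_fraction Proportion of signature genes responsive to the
#'   targeting ASO.
#' @param rescue_strength Fraction of the disease effect reversed in the
#'   affected genotype by a targeting arm (0.5 = halfway back to baseline).
#' @param aberrant_strength Fraction of the disease effect applied with
#'   opposite sign in the *unaffected* genotype by a targeting arm, pushing
#'   responsive genes past their own baseline (the acute depletion response).
#' @param knockdown_per_dose Named numeric vector mapping dose label to the
#'   residual fraction of target-gene expression under a targeting ASO.
#' @param target_lfc True log2 fold-change of the target gene itself in the
#'   affected genotype (1 = the 2-fold dosage effect of a duplication).
#' @param line_sd_log2 SD of gene-specific, line-specific log2 offsets.
#' @param line_shared_sd_log2 SD of the per-line scalar on a shared
#'   gene-loading axis; this makes replicate samples of one individual
#'   cluster together and puts individual-of-origin variance on a single
#'   principal axis.
#' @param dispersion Two-parameter mean-dispersion trend: dispersion(mu) =
#'   `asymptotic` + `scale`/mu on the normalized-count scale.
#' @param library_size_range Range of per-sample total counts.
#' @param baseline_log2_mean,baseline_log2_sd Log2-normal distribution of
#'   baseline per-gene abundance (relative units).
#' @param target_gene Symbol used for the dose-responsive target gene.
#' @return A validated `sim_config` object (a list).
#' @export
sim_config <- function(n_genes = 12000,
                       n_lines_per_genotype = 4,
                       arms = default_arms(),
                       n_dosage_up = 500,
                       n_dosage_down = 1000,
                       effect_size_log2 = 1,
                       effect_sdlog = 0.25,
                       rescue_fraction = 0.5,
                       rescue_strength = 0.5,
                       aberrant_strength = 0.5,
                       knockdown_per_dose = c("2.2" = 0.65, "6.6" = 0.5,
                                              "20" = 0.35),
                       target_lfc = 1,
                       line_sd_log2 = 0.15,
                       line_shared_sd_log2 = 0.3,
                       dispersion = c(asymptotic = 0.02, scale = 1.5),
                       library_size_range = c(8e6, 12e6),
                       baseline_log2_mean = 5,
                       baseline_log2_sd = 2,
                       target_gene = "TARGET") {
  cfg <- list(n_genes = as.integer(n_genes),
              n_lines_per_genotype = as.integer(n_lines_per_genotype),
              arms = as_tibble(arms),
              n_dosage_up = as.integer(n_dosage_up),
              n_dosage_down = as.integer(n_dosage_down),
              effect_size_log2 = effect_size_log2,
              effect_sdlog = effect_sdlog,
              rescue_fraction = rescue_fraction,
              rescue_strength = rescue_strength,
              aberrant_strength = aberrant_strength,
              knockdown_per_dose = knockdown_per_dose,
              target_lfc = target_lfc,
              line_sd_log2 = line_sd_log2,
              line_shared_sd_log2 = line_shared_sd_log2,
              dispersion = dispersion,
              library_size_range = library_size_range,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              target_gene = as.character(target_gene))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_genes < 1) abort("n_genes must be positive.")
    if (n_lines_per_genotype < 1) abort("need at least one cell line per genotype.")
    if (n_dosage_up < 0 || n_dosage_down < 0 ||
        n_dosage_up + n_dosage_down > n_genes - 1) {
      abort("n_dosage_up + n_dosage_down must leave room for null genes.")
    }
    if (rescue_fraction < 0 || rescue_fraction > 1) {
      abort("rescue_fraction must lie in [0, 1].")
    }
    if (any(knockdown_per_dose <= 0 | knockdown_per_dose > 1)) {
      abort("knockdown fractions must lie in (0, 1].")
    }
    req <- c("treatment", "aso_sequence", "dose", "n_replicates")
    if (!all(req %in% names(arms))) {
      abort(sprintf("arms must have columns: %s", paste(req, collapse = ", ")))
    }
    targ_doses <- unique(arms$dose[arms$treatment == "targeting"])
    miss <- setdiff(format_dose(targ_doses), names(knockdown_per_dose))
    if (length(miss) > 0) {
      abort(sprintf("no knockdown fraction configured for dose(s): %s",
                    paste(miss, collapse = ", ")))
    }
    if (length(library_size_range) != 2 || any(library_size_range <= 0)) {
      abort("library_size_range must be two positive numbers.")
    }
  })
  cfg
}

# canonical string label for a dose (used as map key; avoids float-key pitfalls)
format_dose <- function(dose) {
  vapply(dose, function(d) format(d, trim = TRUE, scientific = FALSE),
         character(1))
}

#' Simulate a gene-by-sample count dataset with known ground truth
#'
#' Draws counts from a negative-binomial model with a log-linear mean:
#' library size x baseline abundance x 2^(genotype effect + cell-line effect
#' + treatment effect), with dispersion following the configured
#' mean-dispersion trend. Signature genes carry the configured up/down
#' genotype effects; targeting arms knock the target gene down to the
#' configured residual fraction in both genotypes and move responsive
#' signature genes a configured fraction of the way back toward baseline
#' (and, in the unaffected genotype, past it). Scramble arms have zero
#' treatment effect. The master seed expands through fixed per-stage child
#' seeds, so identical seeds give bit-identical output and appending arms
#' does not perturb earlier draws.
#'
#' @param config A [sim_config()].
#' @param seed Master integer seed.
#' @return A list of class `aso_simulation` with elements `counts` (tibble),
#'   `design` (tibble), and `truth` (per-gene tibble with class, responsive
#'   flag and true genotype log2 fold-change; per-arm treatment effects in
#'   `attr(truth, "arm_effects")`).
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1) {
  cfg <- validate_sim_config(config)
  G <- cfg$n_genes

  # --- gene-level parameters -------------------------------------------------
  set.seed(child_seed(seed, 1))
  genes <- sprintf("G%05d", seq_len(G))
  genes[1] <- cfg$target_gene
  baseline <- 2^stats::rnorm(G, cfg$baseline_log2_mean, cfg$baseline_log2_sd)

  # the target gene occupies one slot of its direction's budget, so the
  # realized class counts equal the configured ones
  class_vec <- rep("null", G)
  n_up_rand <- cfg$n_dosage_up - (cfg$target_lfc > 0 && cfg$n_dosage_up > 0)
  n_down_rand <- cfg$n_dosage_down -
    (cfg$target_lfc < 0 && cfg$n_dosage_down > 0)
  n_sig <- n_up_rand + n_down_rand
  sig_idx <- if (n_sig > 0) 1 + sample.int(G - 1, n_sig) else integer(0)
  up_idx <- utils::head(sig_idx, n_up_rand)
  down_idx <- utils::tail(sig_idx, n_down_rand)
  class_vec[up_idx] <- "dosage_up"
  class_vec[down_idx] <- "dosage_down"

  magnitude <- if (cfg$effect_sdlog > 0) {
    cfg$effect_size_log2 *
      stats::rlnorm(G, -cfg$effect_sdlog^2 / 2, cfg$effect_sdlog)
  } else {
    rep(cfg$effect_size_log2, G)
  }
  true_lfc <- rep(0, G)
  true_lfc[up_idx] <- magnitude[up_idx]
  true_lfc[down_idx] <- -magnitude[down_idx]
  true_lfc[1] <- cfg$target_lfc
  class_vec[1] <- if (cfg$target_lfc > 0) "dosage_up" else
    if (cfg$target_lfc < 0) "dosage_down" else "null"

  responsive <- rep(FALSE, G)
  responsive[sig_idx] <- stats::runif(n_sig) < cfg$rescue_fraction
  responsive[1] <- FALSE  # the target gene follows the knockdown map instead

  shared_loading <- stats::rnorm(G)  # individual-of-origin axis

  # --- cell-line effects -----------------------------------------------------
  set.seed(child_seed(seed, 2))
  n_lines <- 2 * cfg$n_lines_per_genotype
  line_ids <- c(paste0("U", seq_len(cfg$n_lines_per_genotype)),
                paste0("A", seq_len(cfg$n_lines_per_genotype)))
  line_geno <- rep(.genotypes, each = cfg$n_lines_per_genotype)
  rho <- stats::rnorm(n_lines, 0, cfg$line_shared_sd_log2)
  line_eff <- outer(shared_loading, rho) +
    matrix(stats::rnorm(G * n_lines, 0, cfg$line_sd_log2), G, n_lines)
  colnames(line_eff) <- line_ids

  # --- samples ---------------------------------------------------------------
  design <- tidyr::expand_grid(line = seq_len(n_lines),
                               arm = seq_len(nrow(cfg$arms)))
  design <- bind_cols(design, cfg$arms[design$arm, ])
  design <- design[rep(seq_len(nrow(design)), design$n_replicates), ]
  design$replicate <- stats::ave(design$line, design$line, design$arm,
                                 FUN = seq_along)
  design <- design |>
    mutate(cell_line = line_ids[.data$line],
           genotype = line_geno[.data$line],
           sample_id = sprintf("%s_%s_%s_d%s_r%d", .data$cell_line,
                               .data$treatment,
                               .data$aso_sequence, format_dose(.data$dose),
                               .data$replicate))

  # --- per-sample expected means and NB draws (one child stream per arm) -----
  counts <- matrix(0, G, nrow(design))
  colnames(counts) <- design$sample_id
  arm_effect_rows <- list()
  kd_log2 <- log2(cfg$knockdown_per_dose)

  for (a in seq_len(nrow(cfg$arms))) {
    set.seed(child_seed(seed, 100 + a))
    arm <- cfg$arms[a, ]
    idx <- which(design$arm == a)
    treat_eff <- matrix(0, G, 2, dimnames = list(NULL, .genotypes))
    if (arm$treatment == "targeting") {
      kd <- kd_log2[[format_dose(arm$dose)]]
      treat_eff[1, ] <- kd
      resp <- responsive
      treat_eff[resp, "affected"] <- -true_lfc[resp] * cfg$rescue_strength
      treat_eff[resp, "unaffected"] <- -true_lfc[resp] * cfg$aberrant_strength
    }
    for (j in idx) {
      gt <- design$genotype[j]
      lib <- stats::runif(1, cfg$library_size_range[1],
                          cfg$library_size_range[2])
      eta <- (if (gt == "affected") true_lfc else 0) +
        line_eff[, design$cell_line[j]] + treat_eff[, gt]
      rel <- baseline * 2^eta
      mu <- lib * rel / sum(rel)
      alpha <- cfg$dispersion[["asymptotic"]] + cfg$dispersion[["scale"]] / mu
      counts[, j] <- stats::rnbinom(G, mu = mu, size = 1 / alpha)
    }
    for (gt in .genotypes) {
      arm_effect_rows[[length(arm_effect_rows) + 1]] <- tibble(
        gene = genes, genotype = gt, treatment = arm$treatment,
        aso_sequence = arm$aso_sequence, dose = arm$dose,
        true_treatment_lfc = treat_eff[, gt])
    }
  }

  counts_tbl <- bind_cols(tibble(gene = genes),
                          as_tibble(counts, .name_repair = "minimal"))
  design_tbl <- design |>
    select("sample_id", "genotype", "cell_line", "treatment",
           "aso_sequence", "dose") |>
    as_tibble()

  truth <- tibble(gene = genes, class = class_vec, responsive = responsive,
                  true_lfc = true_lfc,
                  is_target = genes == cfg$target_gene)
  attr(truth, "arm_effects") <- bind_rows(arm_effect_rows)

  out <- list(counts = validate_counts(counts_tbl),
              design = validate_design(design_tbl),
              truth = truth,
              config = cfg, seed = seed)
  class(out) <- "aso_simulation"
  out
}

#' @export
print.aso_simulation <- function(x, ...) {
  cat(sprintf("<aso_simulation> %d genes x %d samples (seed %s)\n",
              nrow(x$counts), ncol(x$counts) - 1, format(x$seed)))
  cat(sprintf("  signature: %d up / %d down; responsive fraction %.2f\n",
              sum(x$truth$class == "dosage_up"),
              sum(x$truth$class == "dosage_down"),
              x$config$rescue_fraction))
  invisible(x)
}

#' Simulate a companion loss-of-function DE table
#'
#' Builds an external-style differential-expression table (gene, log2fc,
#' p_adj, base_mean) for a companion dataset in which a configured fraction
#' of the signature genes carry sign-inverted effects relative to the
#' gain-of-dosage truth, plus Gaussian noise. Background null genes are
#' included with null effects and uniform adjusted p-values so the table has
#' a realistic expressed universe.
#'
#' @param truth Ground-truth tibble from [simulate_dataset()].
#' @param inversion_fraction Probability that a signature gene's companion
#'   effect has the opposite sign of its gain-of-dosage effect.
#' @param noise_sd SD of Gaussian noise added to companion log2 fold-changes.
#' @param frac_significant Fraction of signature genes significant
#'   (p_adj < 0.05) in the companion table.
#' @param n_background Number of null genes carried along as the expressed
#'   background.
#' @param seed Integer seed.
#' @return A tibble with columns `gene`, `log2fc`, `p_adj`, `base_mean`.
#' @export
simulate_companion_lof <- function(truth, inversion_fraction = 0.8,
                                   noise_sd = 0.3, frac_significant = 1,
                                   n_background = 2000, seed = 1) {
  if (inversion_fraction < 0 || inversion_fraction > 1) {
    abort("inversion_fraction must lie in [0, 1].")
  }
  set.seed(child_seed(seed, 7))
  sig <- truth |> filter(.data$class != "null", !.data$is_target)
  null_pool <- truth |> filter(.data$class == "null")
  bg <- null_pool[utils::head(seq_len(nrow(null_pool)), n_background), ]

  n <- nrow(sig)
  if (n == 0) {
    return(tibble(gene = character(), log2fc = numeric(),
                  p_adj = numeric(), base_mean = numeric()))
  }
  flip <- stats::runif(n) < inversion_fraction
  s <- ifelse(flip, -1, 1)
  lfc <- s * sig$true_lfc +
    (if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0)
  is_sig <- stats::runif(n) < frac_significant
  p_adj <- ifelse(is_sig, stats::runif(n, 0, 0.049),
                  stats::runif(n, 0.05, 1))
  out_sig <- tibble(gene = sig$gene, log2fc = lfc, p_adj = p_adj,
                    base_mean = 2^stats::rnorm(n, 6, 1.5))
  out_bg <- tibble(gene = bg$gene,
                   log2fc = stats::rnorm(nrow(bg), 0, max(noise_sd, 0.05)),
                   p_adj = stats::runif(nrow(bg), 0.05, 1),
                   base_mean = 2^stats::rnorm(nrow(bg), 6, 1.5))
  bind_rows(out_sig, out_bg)
}
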