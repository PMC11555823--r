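#' Run the full rescue pipeline from a config
#'
#' Executes, in order: data loading (or simulation), the batch-normalized
#' contrast scheme, disease-signature extraction, the reciprocal comparison
#' (when a companion table is configured), and rescue scoring (sign-flip,
#' rank patterns, PC shift), writing every result table as TSV plus a
#' machine-readable run manifest. Identical config and seed give
#' byte-identical outputs. When the config has no `rescue` block the run
#' stops cleanly after the signature stage with a message.
#'
#' @param config Path to a YAML file or an equivalent named list. Keys:
#'   `seed` (integer), `output_dir`, `alpha` (default 0.05), either
#'   `simulate:` (arguments to [sim_config()]) or `inputs: {counts, design}`
#'   (TSV paths), optionally `companion:` (`path:` to an external DE TSV or
#'   `simulate: {inversion_fraction, noise_sd}`), and optionally `rescue:`
#'   (`doses`, `pool_doses`, `pc_component`).
#' @param output_dir Overrides the config's output directory.
#' @return Invisibly, a list with the pipeline objects and the manifest.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) abort("`config` must be a YAML path or a list.")
  out_dir <- output_dir %||% cfg$output_dir %||%
    abort("config must name an `output_dir`.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed %||% 1L)
  alpha <- cfg$alpha %||% 0.05
  log_msg <- function(...) message(sprintf(...))
  funnel <- list()

  # --- stage: inputs ---------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    sc <- do.call(sim_config, cfg$simulate)
    sim <- simulate_dataset(sc, seed = seed)
    counts <- sim$counts; design <- sim$design; truth <- sim$truth
    write_table(truth, file.path(out_dir, "truth.tsv"))
  } else if (!is.null(cfg$inputs)) {
    counts <- read_count_matrix(cfg$inputs$counts)
    design <- read_design(cfg$inputs$design)
    truth <- NULL
  } else {
    abort("config needs either a `simulate` or an `inputs` block.")
  }
  write_table(counts, file.path(out_dir, "counts.tsv"))
  write_table(design, file.path(out_dir, "design.tsv"))
  funnel$genes_read <- nrow(counts)
  funnel$samples <- nrow(design)
  log_msg("[inputs] %d genes x %d samples", nrow(counts), nrow(design))

  # --- stage: differential expression ---------------------------------------
  scheme <- default_contrast_scheme(design)
  de <- run_contrast_scheme(counts, design, scheme)
  for (nm in names(de)) {
    write_table(de[[nm]], file.path(out_dir, sprintf("de_%s.tsv", nm)))
  }
  funnel$contrasts <- length(de)
  funnel$genes_tested <- sum(!is.na(de$disease_signature$p_value))
  log_msg("[de] %d contrasts in %d normalization batches", length(de),
          length(unique(vapply(scheme, `[[`, character(1), "batch"))))

  # --- stage: signature ------------------------------------------------------
  signature <- extract_signature(de$disease_signature, alpha = alpha)
  write_table(signature, file.path(out_dir, "signature.tsv"))
  funnel$genes_significant <- nrow(signature)
  log_msg("[signature] %d genes at padj < %s (%d up / %d down)",
          nrow(signature), format(alpha), attr(signature, "n_up"),
          attr(signature, "n_down"))

  # --- stage: reciprocal (optional) ------------------------------------------
  overlap <- NULL
  if (!is.null(cfg$companion)) {
    companion <- if (!is.null(cfg$companion$path)) {
      read_external_de(cfg$companion$path)
    } else {
      if (is.null(truth)) {
        abort("companion simulation requires a simulated dataset.")
      }
      args <- cfg$companion$simulate %||% list()
      do.call(simulate_companion_lof,
              c(list(truth = truth, seed = seed), args))
    }
    overlap <- compare_signatures(de$disease_signature, companion,
                                  alpha = alpha)
    write_table(glance(overlap), file.path(out_dir, "overlap.tsv"))
    write_table(tidy(overlap), file.path(out_dir, "overlap_genes.tsv"))
    funnel$genes_shared <- overlap$n_shared
    log_msg("[reciprocal] %d shared genes, Fisher p = %.3g, r = %.3f",
            overlap$n_shared, overlap$fisher_p, overlap$pearson_r)
  }

  # --- stage: rescue ---------------------------------------------------------
  rescue <- NULL
  if (is.null(cfg$rescue)) {
    log_msg("[rescue] no `rescue` block in config; stopping after signature.")
  } else if (nrow(signature) == 0) {
    log_msg("[rescue] empty signature; nothing to score.")
  } else {
    rc <- cfg$rescue
    pools <- rescue_pools(design, doses = rc$doses,
                          pool_doses = rc$pool_doses %||% TRUE)
    pooled <- pooled_group_cpm(counts, pools, signature = signature)
    report <- sign_flip_rescue(pooled, signature)
    write_table(tidy(report), file.path(out_dir, "rescue_report.tsv"))
    write_table(glance(report), file.path(out_dir, "rescue_summary.tsv"))

    seqs <- unique(design$aso_sequence[design$treatment == "targeting"])
    ranks <- lapply(seqs, function(sq) {
      four <- pooled[, c("unaffected_control", paste0("unaffected_", sq),
                         "affected_control", paste0("affected_", sq))]
      rank_order_patterns(four, signature)
    })
    names(ranks) <- seqs
    for (sq in seqs) {
      write_table(ranks[[sq]]$ranks,
                  file.path(out_dir, sprintf("rank_patterns_%s.tsv", sq)))
    }

    shift <- pc_shift_test(counts, design, signature,
                           component = rc$pc_component %||% 2)
    write_table(tidy(shift), file.path(out_dir, "pc_shift.tsv"))
    write_table(augment(shift), file.path(out_dir, "pc_shift_samples.tsv"))
    rescue <- list(pooled = pooled, report = report, ranks = ranks,
                   shift = shift)
    funnel$genes_rescued_any_arm <-
      length(unique(report$gene[report$rescued]))
    log_msg("[rescue] %d arms scored; %d genes rescued in at least one arm",
            length(unique(report$arm)), funnel$genes_rescued_any_arm)
  }

  # the output directory is where the manifest itself lives; leaving it out
  # keeps manifests (and their hashes) identical across relocated runs
  cfg_record <- cfg
  cfg_record$output_dir <- NULL
  manifest <- list(
    package = "asorescue",
    package_version = as.character(utils::packageVersion("asorescue")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed, alpha = alpha,
    config = cfg_record, config_hash = rlang::hash(cfg_record),
    funnel = funnel)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(counts = counts, design = design, truth = truth, de = de,
                 signature = signature, overlap = overlap, rescue = rescue,
                 manifest = manifest, output_dir = out_dir))
}
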