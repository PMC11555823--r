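#' Canonical sample pools for rescue scoring
#'
#' Builds the named sample groups the rescue statistics compare: one control
#' pool per genotype (naive plus scramble samples — the untreated baseline)
#' and one pool per genotype per targeting ASO sequence, averaging the
#' listed doses together (dose pooling) or kept per dose.
#'
#' @param design Design tibble.
#' @param doses Targeting doses to include; `NULL` keeps every targeting
#'   dose present.
#' @param pool_doses Pool the doses of one sequence into a single arm?
#' @param control_treatments Treatments forming the control pools.
#' @return Named list of sample-id character vectors. Control pools are
#'   named `<genotype>_control`; targeting pools `<genotype>_<sequence>` or
#'   `<genotype>_<sequence>_<dose>`.
#' @export
rescue_pools <- function(design, doses = NULL, pool_doses = TRUE,
                         control_treatments = c("naive", "scramble")) {
  design <- validate_design(design)
  pools <- list()
  for (gt in intersect(.genotypes, unique(design$genotype))) {
    ids <- design$sample_id[design$genotype == gt &
                              design$treatment %in% control_treatments]
    pools[[paste0(gt, "_control")]] <- ids
  }
  targ <- design |> filter(.data$treatment == "targeting")
  if (!is.null(doses)) targ <- targ |> filter(.data$dose %in% doses)
  if (nrow(targ) > 0) {
    key <- if (pool_doses) {
      paste(targ$genotype, targ$aso_sequence, sep = "_")
    } else {
      paste(targ$genotype, targ$aso_sequence, format_dose(targ$dose),
            sep = "_")
    }
    for (k in unique(key)) {
      pools[[k]] <- targ$sample_id[key == k]
    }
  }
  empty <- names(pools)[lengths(pools) == 0]
  if (length(empty) > 0) {
    abort(sprintf("empty sample pool(s): %s", paste(empty, collapse = ", ")))
  }
  pools
}

#' Pooled group log2 CPM
#'
#' Per-sample log2 CPM (with pseudocount), averaged within each named sample
#' pool; optionally restricted to signature genes. With `average = "cpm"`
#' the arithmetic mean of CPM is taken before the log instead.
#'
#' @param counts Counts tibble or matrix.
#' @param pools Named list of sample-id vectors (see [rescue_pools()]).
#' @param signature Optional `disease_signature` (or character vector of
#'   genes) to restrict to.
#' @param pseudocount Pseudocount for the log2.
#' @param average `"log"` (mean of log2 CPM, default) or `"cpm"` (log2 of
#'   mean CPM).
#' @return A genes x pools numeric matrix of pooled log2 expression.
#' @export
pooled_group_cpm <- function(counts, pools, signature = NULL,
                             pseudocount = 0.5,
                             average = c("log", "cpm")) {
  average <- match.arg(average)
  m <- if (is.matrix(counts)) counts else counts_matrix(counts)
  empty <- names(pools)[lengths(pools) == 0]
  if (length(empty) > 0) {
    abort(sprintf("empty sample pool(s): %s", paste(empty, collapse = ", ")))
  }
  missing <- setdiff(unlist(pools), colnames(m))
  if (length(missing) > 0) {
    abort(sprintf("pool samples not in counts: %s",
                  paste(missing, collapse = ", ")))
  }
  genes <- if (is.null(signature)) rownames(m) else {
    gs <- if (is.data.frame(signature)) signature$gene else signature
    miss <- setdiff(gs, rownames(m))
    if (length(miss) > 0) {
      abort(sprintf("signature genes not in counts: %s",
                    paste(utils::head(miss, 5), collapse = ", ")))
    }
    gs
  }
  cm <- cpm(m, log = FALSE)
  out <- vapply(pools, function(ids) {
    sub <- cm[genes, ids, drop = FALSE]
    if (average == "log") {
      rowMeans(log2(sub + pseudocount))
    } else {
      log2(rowMeans(sub) + pseudocount)
    }
  }, numeric(length(genes)))
  out <- matrix(out, nrow = length(genes),
                dimnames = list(genes, names(pools)))
  out
}

#' Sign-flip rescue scoring
#'
#' For each signature gene, the baseline dysregulation is the log2 ratio of
#' pooled affected-control to pooled unaffected-control expression, and each
#' targeting arm's treatment ratio is the log2 ratio of the arm's pooled
#' expression to the affected-control pool. A gene counts as (partially,
#' qualitatively) rescued in an arm when the treatment ratio's sign is the
#' opposite of the baseline ratio's sign — no magnitude threshold, exactly
#' the sign rule. Percent rescued is aggregated per arm and signature
#' direction.
#'
#' @param pooled Genes x pools matrix from [pooled_group_cpm()] (log2
#'   scale); must contain `affected_control` and `unaffected_control`
#'   columns.
#' @param signature A `disease_signature` restricted to which scoring is
#'   done (genes absent from `pooled` are an error).
#' @param arms Targeting pool column names; defaults to every `affected_*`
#'   column except the control.
#' @param min_abs_treatment Optional minimum |treatment log ratio| for a
#'   flip to count (default 0: pure sign rule).
#' @return A `rescue_report` tibble (one row per gene x arm) with the
#'   per-arm/direction percent-rescued summary in `attr(, "summary")` and
#'   available via [glance()].
#' @export
sign_flip_rescue <- function(pooled, signature, arms = NULL,
                             min_abs_treatment = 0) {
  need <- c("affected_control", "unaffected_control")
  if (!all(need %in% colnames(pooled))) {
    abort(sprintf("`pooled` must contain columns: %s",
                  paste(need, collapse = ", ")))
  }
  if (is.null(arms)) {
    arms <- setdiff(grep("^affected_", colnames(pooled), value = TRUE),
                    "affected_control")
  }
  if (length(arms) == 0) abort("no targeting arms to score.")
  genes <- intersect(signature$gene, rownames(pooled))
  if (nrow(signature) > 0 && length(genes) == 0) {
    abort("no signature genes present in `pooled`.")
  }
  sig <- signature[match(genes, signature$gene), , drop = FALSE]
  base_ratio <- pooled[genes, "affected_control"] -
    pooled[genes, "unaffected_control"]

  rows <- lapply(arms, function(a) {
    treat_ratio <- pooled[genes, a] - pooled[genes, "affected_control"]
    rescued <- sign(treat_ratio) == -sign(base_ratio) &
      sign(base_ratio) != 0 & abs(treat_ratio) >= min_abs_treatment
    tibble(gene = genes, direction = sig$direction, arm = a,
           baseline_log_ratio = unname(base_ratio),
           treatment_log_ratio = unname(treat_ratio),
           rescued = unname(rescued))
  })
  out <- bind_rows(rows)
  summary <- out |>
    group_by(.data$arm, .data$direction) |>
    summarise(n_genes = n(),
              n_rescued = sum(.data$rescued),
              percent_rescued = 100 * mean(.data$rescued),
              .groups = "drop")
  class(out) <- c("rescue_report", class(out))
  attr(out, "summary") <- summary
  out
}

#' @export
print.rescue_report <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("<rescue_report> %d signature genes x %d arm(s)\n",
              length(unique(x$gene)), length(unique(x$arm))))
  print(as.data.frame(s), row.names = FALSE)
  invisible(x)
}

#' @method tidy rescue_report
#' @export
tidy.rescue_report <- function(x, ...) {
  as_tibble(unclass(x)[c("gene", "direction", "arm", "baseline_log_ratio",
                         "treatment_log_ratio", "rescued")])
}

#' @method glance rescue_report
#' @export
glance.rescue_report <- function(x, ...) attr(x, "summary")

#' 1-4 rank-order patterns across the four canonical pools
#'
#' Ranks each signature gene's pooled expression across the four canonical
#' groups — unaffected control, unaffected treated, affected control,
#' affected treated — from 1 (lowest) to 4 (highest), clusters the rank
#' vectors hierarchically (Euclidean distance), and flags clusters whose
#' mean rank vector tracks the nominal target-gene dosage order. Under
#' knockdown the dosage order is: unaffected treated < unaffected control <
#' affected treated < affected control, so an up-regulated, fully
#' dosage-tracking gene ranks (2, 1, 4, 3) in the canonical column order
#' and a down-regulated one (3, 4, 1, 2). Exact ties are broken by the
#' canonical column order.
#'
#' @param pooled Genes x 4 matrix from [pooled_group_cpm()] with columns
#'   (in order) `unaffected_control`, `unaffected_<arm>`,
#'   `affected_control`, `affected_<arm>` — any column names are accepted
#'   but exactly four columns are required and interpreted in that order.
#' @param signature Optional `disease_signature` to attach directions.
#' @param k Number of clusters to cut the tree into.
#' @param dosage_threshold Minimum |Spearman correlation| between a cluster
#'   mean rank vector and the dosage order for the cluster to count as
#'   dosage-consistent.
#' @param linkage Agglomeration method.
#' @return A `rank_patterns` list: `ranks` (per-gene tibble with rank
#'   columns, cluster id), `clusters` (per-cluster mean ranks, Spearman
#'   correlation with dosage, consistency flag), and the `hclust` tree.
#' @export
rank_order_patterns <- function(pooled, signature = NULL, k = 6,
                                dosage_threshold = 0.8,
                                linkage = "average") {
  if (ncol(pooled) != 4) {
    abort(sprintf("exactly four pooled groups required, got %d.",
                  ncol(pooled)))
  }
  grp <- colnames(pooled)
  ranks <- t(apply(pooled, 1, rank, ties.method = "first"))
  colnames(ranks) <- grp
  # cluster the distinct rank patterns (at most 24 with four groups), then
  # map genes onto their pattern's cluster: invariant to gene input order
  pat_key <- apply(ranks, 1, paste, collapse = "")
  u_key <- sort(unique(pat_key))
  u <- ranks[match(u_key, pat_key), , drop = FALSE]
  k <- min(k, nrow(u))
  hc <- stats::hclust(stats::dist(u, method = "euclidean"), method = linkage)
  cl_pat <- stats::cutree(hc, k = k)
  cl <- unname(cl_pat[match(pat_key, u_key)])

  # nominal target-gene dosage by group: unaffected+ASO lowest, affected
  # control highest; expression of a dosage-tracking up-gene follows it.
  dosage <- c(2, 1, 4, 3)
  clusters <- lapply(sort(unique(cl)), function(ci) {
    mr <- colMeans(ranks[cl == ci, , drop = FALSE])
    rho <- suppressWarnings(stats::cor(mr, dosage, method = "spearman"))
    tibble(cluster = ci, n_genes = sum(cl == ci),
           !!!stats::setNames(as.list(mr), paste0("mean_rank_", grp)),
           spearman_dosage = rho,
           dosage_consistent = is.finite(rho) & abs(rho) >= dosage_threshold,
           tracking_direction = ifelse(!is.finite(rho), NA_character_,
                                       ifelse(rho > 0, "up", "down")))
  })
  ranks_tbl <- bind_cols(tibble(gene = rownames(pooled)),
                         as_tibble(ranks, .name_repair = "minimal"),
                         tibble(cluster = unname(cl)))
  if (!is.null(signature)) {
    ranks_tbl <- ranks_tbl |>
      left_join(signature |> select("gene", "direction"), by = "gene")
  }
  structure(list(ranks = ranks_tbl, clusters = bind_rows(clusters),
                 hclust = hc, dosage_order = stats::setNames(dosage, grp)),
            class = "rank_patterns")
}

#' @export
print.rank_patterns <- function(x, ...) {
  cat(sprintf("<rank_patterns> %d genes in %d clusters (%d dosage-consistent)\n",
              nrow(x$ranks), nrow(x$clusters),
              sum(x$clusters$dosage_consistent)))
  print(as.data.frame(x$clusters), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Principal-component shift test for global rescue
#'
#' Computes a PCA of all samples on the signature genes' log2 CPM, orients
#' each component so the affected-control group mean is non-negative
#' (removing the arbitrary PC sign), and measures, for every ASO-treated
#' sample, the difference between its score on the chosen component and the
#' mean score of the untreated (naive/scramble) samples of its own cell
#' line. Differences are averaged per ASO sequence across doses per
#' genotype, and tested with Student's t-test: by default two-sample
#' against the untreated samples' own leave-one-out differences, or
#' one-sample against zero.
#'
#' @param counts Counts tibble.
#' @param design Design tibble.
#' @param signature A non-empty `disease_signature`.
#' @param component Which principal component to test (default 2).
#' @param control_treatments Treatments forming the matched untreated pool.
#' @param test `"two_sample"` (default) or `"one_sample"`.
#' @param pseudocount Pseudocount for the log2 CPM.
#' @return A `pc_shift` list: `samples` (per-sample scores and deltas),
#'   `tests` (per genotype x ASO sequence mean delta and p-value),
#'   `var_explained`, and the tested `component`.
#' @export
pc_shift_test <- function(counts, design, signature, component = 2,
                          control_treatments = c("naive", "scramble"),
                          test = c("two_sample", "one_sample"),
                          pseudocount = 0.5) {
  test <- match.arg(test)
  if (nrow(signature) == 0) abort("`signature` is empty.")
  ad <- align_samples(counts, design)
  design <- ad$design
  genes <- intersect(signature$gene, ad$counts$gene)
  if (length(genes) < 2) abort("need at least 2 signature genes in counts.")
  lc <- cpm(ad$counts, log = TRUE, pseudocount = pseudocount)[genes, ,
                                                              drop = FALSE]
  pc <- stats::prcomp(t(lc), center = TRUE, scale. = FALSE)
  if (component > ncol(pc$x)) {
    abort(sprintf("component %d not available (only %d).", component,
                  ncol(pc$x)))
  }
  scores <- pc$x
  aff_ctrl <- design$sample_id[design$genotype == "affected" &
                                 design$treatment %in% control_treatments]
  for (j in seq_len(ncol(scores))) {
    if (length(aff_ctrl) > 0 && mean(scores[aff_ctrl, j]) < 0) {
      scores[, j] <- -scores[, j]
    }
  }
  sc <- scores[, component]

  untreated <- design$treatment %in% control_treatments
  delta <- rep(NA_real_, nrow(design))
  for (i in seq_len(nrow(design))) {
    mates <- design$sample_id[untreated &
                                design$cell_line == design$cell_line[i] &
                                design$sample_id != design$sample_id[i]]
    if (!untreated[i] && length(mates) == 0) {
      abort(sprintf("treated sample '%s' has no matched untreated sample in line '%s'.",
                    design$sample_id[i], design$cell_line[i]))
    }
    if (length(mates) > 0) {
      delta[i] <- sc[design$sample_id[i]] - mean(sc[mates])
    }
  }
  samples <- design |>
    mutate(score = unname(sc[design$sample_id]), delta = delta,
           role = ifelse(untreated, "untreated", "treated"))

  treated <- samples |> filter(.data$treatment == "targeting")
  ref <- samples |>
    filter(.data$role == "untreated", !is.na(.data$delta))
  tests <- treated |>
    group_by(.data$genotype, .data$aso_sequence) |>
    summarise(n = n(), mean_delta = mean(.data$delta), .groups = "drop")
  tests$p_value <- vapply(seq_len(nrow(tests)), function(i) {
    d <- treated$delta[treated$genotype == tests$genotype[i] &
                         treated$aso_sequence == tests$aso_sequence[i]]
    res <- tryCatch({
      if (test == "one_sample") {
        stats::t.test(d, mu = 0)$p.value
      } else {
        stats::t.test(d, ref$delta)$p.value
      }
    }, error = function(e) NA_real_)
    if (is.na(res) && stats::sd(d) == 0 && all(d == 0)) 1 else res
  }, numeric(1))

  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(samples = samples, tests = tests,
                 var_explained = ve, component = component,
                 method = test),
            class = "pc_shift")
}

#' @export
print.pc_shift <- function(x, ...) {
  cat(sprintf("<pc_shift> component %d (%.1f%% variance), %s t-test\n",
              x$component, 100 * x$var_explained[x$component],
              gsub("_", "-", x$method)))
  print(as.data.frame(x$tests), row.names = FALSE, digits = 3)
  invisible(x)
}

#' @method tidy pc_shift
#' @export
tidy.pc_shift <- function(x, ...) x$tests

#' @method augment pc_shift
#' @export
augment.pc_shift <- function(x, ...) x$samples
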