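#' Merge two DE tables by gene symbol
#'
#' Inner join on gene symbol (case-sensitive by default, as gene symbols
#' are), keeping genes expressed in both datasets. "Expressed" is
#' operationalized as present with a non-`NA` base mean wherever a
#' `base_mean` column exists; each table's own upstream expression filter is
#' otherwise trusted. Duplicate symbols in either input are an error: silent
#' aggregation would distort the overlap universe.
#'
#' @param de_a,de_b Tables with columns `gene`, `log2fc`, `p_adj` (and
#'   optionally `base_mean`).
#' @param case_fold Fold symbols to upper case before joining?
#' @return A joined tibble with suffixed columns `log2fc_a`, `p_adj_a`,
#'   `log2fc_b`, `p_adj_b` (and base means when available).
#' @export
merge_by_symbol <- function(de_a, de_b, case_fold = FALSE) {
  prep <- function(x, side) {
    req <- c("gene", "log2fc", "p_adj")
    if (!all(req %in% names(x))) {
      abort(sprintf("table %s must have columns: %s", side,
                    paste(req, collapse = ", ")))
    }
    x <- as_tibble(x)[, intersect(c("gene", "log2fc", "p_adj", "base_mean"),
                                  names(x))]
    if (case_fold) x$gene <- toupper(x$gene)
    dup <- unique(x$gene[duplicated(x$gene)])
    if (length(dup) > 0) {
      abort(sprintf("duplicate gene symbol(s) in table %s: %s", side,
                    paste(utils::head(dup, 5), collapse = ", ")),
            class = "asorescue_duplicate_id")
    }
    if ("base_mean" %in% names(x)) x <- x[!is.na(x$base_mean), ]
    names(x)[-1] <- paste0(names(x)[-1], "_", side)
    x
  }
  inner_join(prep(de_a, "a"), prep(de_b, "b"), by = "gene")
}

#' Genes significant in both datasets
#'
#' @param joined Output of [merge_by_symbol()].
#' @param alpha Adjusted-p threshold applied to both datasets (AND rule).
#' @return Character vector of shared signature genes.
#' @export
shared_signature <- function(joined, alpha = 0.05) {
  joined$gene[!is.na(joined$p_adj_a) & !is.na(joined$p_adj_b) &
                joined$p_adj_a < alpha & joined$p_adj_b < alpha]
}

#' Hypergeometric overlap test for two gene sets
#'
#' One-sided (enrichment) tail probability of observing at least `n_shared`
#' genes in the intersection of two sets of sizes `n_sig_a` and `n_sig_b`
#' drawn from a universe of `n_universe` genes; the classic Fisher-exact
#' gene-set overlap test. `alternative = "two.sided"` delegates to
#' [stats::fisher.test()] on the 2x2 table.
#'
#' @param n_universe,n_sig_a,n_sig_b,n_shared Overlap counts.
#' @param alternative `"greater"` (enrichment, default) or `"two.sided"`.
#' @return The p-value.
#' @export
fisher_overlap <- function(n_universe, n_sig_a, n_sig_b, n_shared,
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  k <- c(n_universe, n_sig_a, n_sig_b, n_shared)
  if (any(k < 0) || any(k != round(k))) {
    abort("overlap counts must be non-negative integers.")
  }
  if (n_sig_a > n_universe || n_sig_b > n_universe ||
      n_shared > min(n_sig_a, n_sig_b) ||
      n_shared < n_sig_a + n_sig_b - n_universe) {
    abort("inconsistent overlap counts.")
  }
  if (alternative == "greater") {
    stats::phyper(n_shared - 1, n_sig_a, n_universe - n_sig_a, n_sig_b,
                  lower.tail = FALSE)
  } else {
    tab <- matrix(c(n_shared, n_sig_a - n_shared,
                    n_sig_b - n_shared,
                    n_universe - n_sig_a - n_sig_b + n_shared), 2, 2)
    stats::fisher.test(tab, alternative = "two.sided")$p.value
  }
}

#' Directional correlation of fold-changes over a gene set
#'
#' Pearson correlation of the two log2 fold-change columns over the given
#' genes, with the usual t-distribution p-value, plus per-gene concordance
#' labels (`inverse` when the two effects have opposite signs, `concordant`
#' when they agree; defined only where both effects are nonzero).
#'
#' @param joined Output of [merge_by_symbol()].
#' @param genes Genes to correlate over (e.g. from [shared_signature()]);
#'   `NULL` uses all joined genes.
#' @return A list with `r`, `p` (`NA` when fewer than 3 genes), `n`, and a
#'   `labels` tibble.
#' @export
directional_correlation <- function(joined, genes = NULL) {
  x <- joined
  if (!is.null(genes)) x <- x[x$gene %in% genes, , drop = FALSE]
  x <- x[is.finite(x$log2fc_a) & is.finite(x$log2fc_b), , drop = FALSE]
  if (nrow(x) == 0) abort("no genes with finite fold-changes in both tables.")
  r <- stats::cor(x$log2fc_a, x$log2fc_b)
  p <- if (nrow(x) >= 3 && is.finite(r) && abs(r) < 1) {
    stats::cor.test(x$log2fc_a, x$log2fc_b)$p.value
  } else if (nrow(x) >= 3 && isTRUE(abs(r) == 1)) {
    0
  } else {
    NA_real_
  }
  nz <- x$log2fc_a != 0 & x$log2fc_b != 0
  labels <- tibble(gene = x$gene[nz],
                   concordance = ifelse(sign(x$log2fc_a[nz]) ==
                                          sign(x$log2fc_b[nz]),
                                        "concordant", "inverse"))
  list(r = r, p = p, n = nrow(x), labels = labels)
}

#' Compare two disease signatures end to end
#'
#' Merges the two DE tables by symbol, takes the joined expressed set as the
#' overlap universe (overridable), counts genes significant in each and in
#' both, tests overlap enrichment with [fisher_overlap()], and computes the
#' directional correlation of fold-changes over the shared genes.
#'
#' @param de_a,de_b Tables with `gene`, `log2fc`, `p_adj`.
#' @param alpha Significance threshold for both datasets.
#' @param universe Overlap universe size; defaults to the joined expressed
#'   set.
#' @param case_fold Fold gene symbols to upper case before joining?
#' @return An `overlap_result` list: counts, `fisher_p`, `pearson_r`,
#'   `pearson_p`, per-gene labels, and the joined table.
#' @export
compare_signatures <- function(de_a, de_b, alpha = 0.05, universe = NULL,
                               case_fold = FALSE) {
  joined <- merge_by_symbol(de_a, de_b, case_fold = case_fold)
  n_universe <- universe %||% nrow(joined)
  sig_a <- joined$gene[!is.na(joined$p_adj_a) & joined$p_adj_a < alpha]
  sig_b <- joined$gene[!is.na(joined$p_adj_b) & joined$p_adj_b < alpha]
  shared <- shared_signature(joined, alpha)
  fisher_p <- if (nrow(joined) == 0) 1 else {
    fisher_overlap(n_universe, length(sig_a), length(sig_b), length(shared))
  }
  corr <- if (length(shared) > 0) {
    directional_correlation(joined, shared)
  } else {
    list(r = NA_real_, p = NA_real_, n = 0L,
         labels = tibble(gene = character(), concordance = character()))
  }
  structure(list(n_universe = n_universe, n_sig_a = length(sig_a),
                 n_sig_b = length(sig_b), n_shared = length(shared),
                 shared_genes = shared, fisher_p = fisher_p,
                 pearson_r = corr$r, pearson_p = corr$p,
                 labels = corr$labels, joined = joined, alpha = alpha),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result> universe %d; A %d, B %d, shared %d (Fisher p = %.3g)\n",
              x$n_universe, x$n_sig_a, x$n_sig_b, x$n_shared, x$fisher_p))
  cat(sprintf("  Pearson r over shared genes: %.3f (p = %.3g)\n",
              x$pearson_r, x$pearson_p))
  invisible(x)
}

#' @method tidy overlap_result
#' @export
tidy.overlap_result <- function(x, ...) {
  x$joined |>
    mutate(shared = .data$gene %in% x$shared_genes) |>
    left_join(x$labels, by = "gene")
}

#' @method glance overlap_result
#' @export
glance.overlap_result <- function(x, ...) {
  tibble(n_universe = x$n_universe, n_sig_a = x$n_sig_a, n_sig_b = x$n_sig_b,
         n_shared = x$n_shared, fisher_p = x$fisher_p,
         pearson_r = x$pearson_r, pearson_p = x$pearson_p, alpha = x$alpha)
}
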