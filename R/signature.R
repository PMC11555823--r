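#' Extract a disease signature from a DE result
#'
#' The signature is the set of genes with adjusted p below `alpha`, labelled
#' `up` or `down` by the sign of the log2 fold-change of the
#' affected-vs-unaffected contrast.
#'
#' @param de A `de_result` tibble (or any table with `gene`, `log2fc`,
#'   `p_adj`).
#' @param alpha Adjusted-p threshold, in (0, 1).
#' @return A `disease_signature` tibble with columns `gene`, `direction`,
#'   `log2fc`, `p_adj`; attributes record `alpha` and the up/down counts.
#' @export
extract_signature <- function(de, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single number in (0, 1).")
  }
  req <- c("gene", "log2fc", "p_adj")
  if (!all(req %in% names(de))) {
    abort(sprintf("`de` must have columns: %s", paste(req, collapse = ", ")))
  }
  hit <- de |>
    filter(!is.na(.data$p_adj), .data$p_adj < alpha, .data$log2fc != 0) |>
    mutate(direction = ifelse(.data$log2fc > 0, "up", "down")) |>
    select("gene", "direction", "log2fc", "p_adj") |>
    arrange(.data$p_adj)
  if (anyDuplicated(hit$gene)) {
    abort("duplicate gene symbols in the DE table.")
  }
  out <- as_tibble(hit)
  class(out) <- c("disease_signature", class(out))
  attr(out, "alpha") <- alpha
  attr(out, "n_up") <- sum(hit$direction == "up")
  attr(out, "n_down") <- sum(hit$direction == "down")
  out
}

#' @export
print.disease_signature <- function(x, ...) {
  nd <- attr(x, "n_down"); nu <- attr(x, "n_up")
  pct <- if (nrow(x) > 0) 100 * nd / nrow(x) else NA_real_
  cat(sprintf("<disease_signature> %d genes (padj < %s): %d up, %d down (%.1f%% down)\n",
              nrow(x), format(attr(x, "alpha")), nu, nd, pct))
  NextMethod()
}

#' @method glance disease_signature
#' @export
glance.disease_signature <- function(x, ...) {
  n <- nrow(x)
  tibble(n_genes = n, n_up = attr(x, "n_up"), n_down = attr(x, "n_down"),
         pct_down = if (n > 0) 100 * attr(x, "n_down") / n else NA_real_,
         alpha = attr(x, "alpha"))
}

#' Z-scored expression matrix with clustering orders for a signature heatmap
#'
#' Restricts to the most significant signature genes (adjusted p below
#' `alpha_strict`), z-scores each gene's log2 CPM across samples
#' (zero-variance genes get all-zero rows rather than being dropped), and
#' hierarchically clusters rows and columns with Euclidean distance.
#'
#' @param counts Counts tibble.
#' @param design Design tibble (used to annotate columns).
#' @param signature A `disease_signature`.
#' @param alpha_strict Stricter adjusted-p threshold for heatmap genes.
#' @param linkage Agglomeration method for [stats::hclust()].
#' @param pseudocount Pseudocount for the log2 CPM.
#' @return A `signature_heatmap` list: `z` (gene x sample matrix),
#'   `row_order`, `col_order`, the two `hclust` trees, and the design.
#' @export
signature_heatmap_matrix <- function(counts, design, signature,
                                     alpha_strict = 0.005,
                                     linkage = "average", pseudocount = 0.5) {
  if (nrow(signature) == 0) abort("`signature` is empty.")
  ad <- align_samples(counts, design)
  genes <- signature$gene[signature$p_adj < alpha_strict]
  if (length(genes) < 2) {
    abort(sprintf("fewer than 2 signature genes at padj < %s.",
                  format(alpha_strict)))
  }
  lc <- cpm(ad$counts, log = TRUE, pseudocount = pseudocount)
  lc <- lc[genes, , drop = FALSE]
  mu <- rowMeans(lc)
  sdv <- apply(lc, 1, stats::sd)
  z <- (lc - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0

  hr <- stats::hclust(stats::dist(z, method = "euclidean"), method = linkage)
  hc <- stats::hclust(stats::dist(t(z), method = "euclidean"), method = linkage)
  structure(list(z = z, row_order = hr$order, col_order = hc$order,
                 row_hclust = hr, col_hclust = hc, design = ad$design),
            class = "signature_heatmap")
}
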