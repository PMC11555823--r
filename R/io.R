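#' Read a gene-by-sample count matrix from TSV
#'
#' The file must have a header row of sample identifiers, a first column of
#' gene symbols, and integer counts in the body. Row and column order are
#' preserved. Duplicate identifiers, negative counts, and non-integer values
#' are rejected with positional error messages.
#'
#' @param path Path to a tab-separated file.
#' @param delim Field delimiter, default tab.
#' @return A counts tibble (`gene` column plus one integer column per sample).
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\ts1\ts2", "g1\t0\t1", "g2\t2\t3"), tf)
#' read_count_matrix(tf)
read_count_matrix <- function(path, delim = "\t") {
  if (!file.exists(path)) abort(sprintf("count file not found: %s", path))
  x <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                         progress = FALSE, show_col_types = FALSE)
  if (ncol(x) < 1) abort("count file has no columns.")
  names(x)[1] <- "gene"
  x$gene <- as.character(x$gene)
  validate_counts(x)
}

#' Read a sample design table from TSV
#'
#' Expects columns `sample_id`, `genotype`, `cell_line`, `treatment`,
#' `aso_sequence`, `dose`. Categorical levels are normalized to lower case
#' and the treatment/dose invariants are enforced (see [validate_design()]).
#'
#' @param path Path to a tab-separated file.
#' @return A validated design tibble.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) abort(sprintf("design file not found: %s", path))
  x <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                       show_col_types = FALSE)
  validate_design(x)
}

#' Read an external differential-expression table
#'
#' Accepts any TSV carrying a gene symbol, a log2 fold-change and an adjusted
#' p-value under common column aliases (e.g. `log2FoldChange`/`log2fc`,
#' `padj`/`p_adj`). `NA` values are allowed in the numeric columns.
#'
#' @param path Path to a tab-separated file.
#' @param aliases Named list mapping canonical names (`gene`, `log2fc`,
#'   `p_adj`, `base_mean`) to acceptable column names in the file.
#' @return A tibble with columns `gene`, `log2fc`, `p_adj` and, when present,
#'   `base_mean`.
#' @export
read_external_de <- function(path,
                             aliases = list(
                               gene = c("gene", "symbol", "gene_symbol"),
                               log2fc = c("log2fc", "log2FoldChange", "logFC"),
                               p_adj = c("p_adj", "padj", "adj.P.Val"),
                               base_mean = c("base_mean", "baseMean", "AveExpr"))) {
  if (!file.exists(path)) abort(sprintf("DE table not found: %s", path))
  x <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                       show_col_types = FALSE)
  pick <- function(canon, required = TRUE) {
    hit <- intersect(aliases[[canon]], names(x))
    if (length(hit) == 0) {
      if (required) abort(sprintf("no column matching '%s' (tried: %s)",
                                  canon, paste(aliases[[canon]], collapse = ", ")))
      return(NULL)
    }
    x[[hit[1]]]
  }
  out <- tibble(gene = as.character(pick("gene")),
                log2fc = as.numeric(pick("log2fc")),
                p_adj = as.numeric(pick("p_adj")))
  bm <- pick("base_mean", required = FALSE)
  if (!is.null(bm)) out$base_mean <- as.numeric(bm)
  out
}

#' Write a result table to TSV
#'
#' Columns are written in their current (deterministic) order; reals are
#' rendered with enough digits to round-trip to at least 12 significant
#' digits, integers exactly.
#'
#' @param result A data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(result, path) {
  if (is.null(result)) abort("`result` must be non-NULL.")
  result <- as.data.frame(result)
  num <- vapply(result, function(v) is.numeric(v) && !is.integer(v), logical(1))
  for (j in which(num)) {
    result[[j]] <- vapply(result[[j]], function(v) {
      if (is.na(v)) NA_character_ else format(v, digits = 15, scientific = FALSE,
                                              trim = TRUE)
    }, character(1))
  }
  utils::write.table(result, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}
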