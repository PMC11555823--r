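#' @importFrom rlang abort %||% .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join bind_rows bind_cols across all_of n
#' @importFrom tibble tibble as_tibble is_tibble
NULL

# Canonical factor levels used throughout the pipeline.
.genotypes  <- c("unaffected", "affected")
.treatments <- c("naive", "scramble", "targeting")

#' Convert a counts tibble to an integer matrix
#'
#' Pipeline counts travel as a tibble whose first column, `gene`, holds gene
#' symbols and whose remaining columns hold per-sample integer read counts.
#' Internal numerics work on the plain matrix form.
#'
#' @param counts A counts tibble (`gene` column plus one column per sample).
#' @return An integer matrix with genes as rownames and samples as colnames.
#' @export
counts_matrix <- function(counts) {
  counts <- validate_counts(counts)
  m <- as.matrix(counts[, setdiff(names(counts), "gene"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- counts$gene
  m
}

#' Validate a counts tibble
#'
#' Checks the structural invariants of the count table: a `gene` first column,
#' unique gene and sample identifiers, and non-negative integer counts.
#'
#' @param counts A data frame with a `gene` column and sample count columns.
#' @return The validated counts as a tibble (invisibly usable in pipes).
#' @export
validate_counts <- function(counts) {
  if (!is.data.frame(counts)) {
    abort("`counts` must be a data frame with a `gene` column.")
  }
  counts <- as_tibble(counts)
  if (!identical(names(counts)[1], "gene")) {
    abort("first column of `counts` must be named `gene`.")
  }
  dup <- counts$gene[duplicated(counts$gene)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate gene symbol(s): %s",
                  paste(unique(dup), collapse = ", ")),
          class = "asorescue_duplicate_id")
  }
  smp <- setdiff(names(counts), "gene")
  if (anyDuplicated(smp)) {
    abort(sprintf("duplicate sample identifier(s): %s",
                  paste(unique(smp[duplicated(smp)]), collapse = ", ")),
          class = "asorescue_duplicate_id")
  }
  if (nrow(counts) == 0) {
    for (s in smp) counts[[s]] <- numeric(0)
    return(counts)
  }
  for (s in smp) {
    v <- counts[[s]]
    if (!is.numeric(v)) {
      abort(sprintf("non-numeric counts in sample column '%s'.", s))
    }
    bad <- which(!is.finite(v) | v < 0 | v != round(v))
    if (length(bad) > 0) {
      abort(sprintf(
        "invalid count at gene '%s', sample '%s': counts must be non-negative integers.",
        counts$gene[bad[1]], s))
    }
  }
  counts
}

#' Validate a sample design tibble
#'
#' Checks the per-sample factor table: required columns, unique sample ids,
#' canonical genotype/treatment levels, and the dose/treatment consistency
#' rules (naive samples carry dose 0 and no ASO sequence; dosed treatments
#' carry a positive dose).
#'
#' @param design A data frame with columns `sample_id`, `genotype`,
#'   `cell_line`, `treatment`, `aso_sequence`, `dose`.
#' @return The validated design as a tibble with normalized factor levels.
#' @export
validate_design <- function(design) {
  req <- c("sample_id", "genotype", "cell_line", "treatment",
           "aso_sequence", "dose")
  if (!is.data.frame(design)) abort("`design` must be a data frame.")
  missing_cols <- setdiff(req, names(design))
  if (length(missing_cols) > 0) {
    abort(sprintf("design is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  design <- as_tibble(design)
  dup <- design$sample_id[duplicated(design$sample_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate sample_id(s): %s",
                  paste(unique(dup), collapse = ", ")),
          class = "asorescue_duplicate_id")
  }
  design$genotype  <- tolower(trimws(as.character(design$genotype)))
  design$treatment <- tolower(trimws(as.character(design$treatment)))
  design$cell_line <- as.character(design$cell_line)
  design$aso_sequence <- as.character(design$aso_sequence)
  design$aso_sequence[design$aso_sequence %in% c("", "NA", "na")] <- "none"
  design$aso_sequence[is.na(design$aso_sequence)] <- "none"
  design$dose <- as.numeric(design$dose)

  bad_gt <- setdiff(unique(design$genotype), .genotypes)
  if (length(bad_gt) > 0) {
    abort(sprintf("unknown genotype level(s): %s (expected %s)",
                  paste(bad_gt, collapse = ", "),
                  paste(.genotypes, collapse = ", ")))
  }
  bad_tr <- setdiff(unique(design$treatment), .treatments)
  if (length(bad_tr) > 0) {
    abort(sprintf("unknown treatment level(s): %s (expected %s)",
                  paste(bad_tr, collapse = ", "),
                  paste(.treatments, collapse = ", ")))
  }
  if (any(!is.finite(design$dose) | design$dose < 0)) {
    abort("`dose` must be a non-negative number for every sample.")
  }
  naive_bad <- design$sample_id[design$treatment == "naive" &
                                  (design$dose != 0 | design$aso_sequence != "none")]
  if (length(naive_bad) > 0) {
    abort(sprintf(
      "naive sample(s) with nonzero dose or an ASO sequence: %s",
      paste(naive_bad, collapse = ", ")), class = "asorescue_invariant")
  }
  dosed_bad <- design$sample_id[design$treatment %in% c("scramble", "targeting") &
                                  design$dose <= 0]
  if (length(dosed_bad) > 0) {
    abort(sprintf("ASO-treated sample(s) with dose <= 0: %s",
                  paste(dosed_bad, collapse = ", ")),
          class = "asorescue_invariant")
  }
  design
}

#' Align a counts table with a design table
#'
#' Joins the count matrix samples with the design rows. By default the two
#' must describe exactly the same sample set; with `require_equal = FALSE`
#' the intersection is used.
#'
#' @param counts Counts tibble.
#' @param design Design tibble.
#' @param require_equal If `TRUE` (default) error unless the sample sets are
#'   identical; otherwise restrict both to their intersection.
#' @return A list with elements `counts` and `design`, sample-aligned
#'   (design rows ordered as the count columns).
#' @export
align_samples <- function(counts, design, require_equal = TRUE) {
  counts <- validate_counts(counts)
  design <- validate_design(design)
  cs <- setdiff(names(counts), "gene")
  if (require_equal) {
    miss_counts <- setdiff(design$sample_id, cs)
    miss_design <- setdiff(cs, design$sample_id)
    if (length(miss_counts) > 0 || length(miss_design) > 0) {
      abort(sprintf(
        "sample sets differ: missing from counts [%s]; missing from design [%s]",
        paste(miss_counts, collapse = ", "),
        paste(miss_design, collapse = ", ")))
    }
    keep <- cs
  } else {
    keep <- intersect(cs, design$sample_id)
  }
  counts <- counts[, c("gene", keep), drop = FALSE]
  design <- design[match(keep, design$sample_id), , drop = FALSE]
  list(counts = counts, design = design)
}

# deterministic child seed from a master seed and a small counter;
# stays below 2^31 so set.seed() accepts it on 32-bit integers.
child_seed <- function(seed, counter) {
  (as.double(seed) * 1009 + 31L * as.double(counter)) %% 2147483647
}
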