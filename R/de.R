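#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment. `NA` entries are ignored (they
#' do not enter the denominator) and returned as `NA` in place; order is
#' preserved.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`, `NA` allowed.
#' @return Adjusted p-values, same length and order as the input.
#' @export
benjamini_hochberg <- function(p_values) {
  if (!is.numeric(p_values)) abort("`p_values` must be numeric.")
  bad <- which(!is.na(p_values) & (p_values < 0 | p_values > 1))
  if (length(bad) > 0) {
    abort(sprintf("p-value outside [0, 1] at position %d.", bad[1]))
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Define a differential-expression contrast
#'
#' A contrast names two disjoint sample groups by predicates on the design
#' table, plus the normalization batch it belongs to (samples of one batch
#' are size-factor-normalized together).
#'
#' @param name Contrast label.
#' @param numerator,denominator Predicates on design columns, given as
#'   strings (e.g. `'treatment == "scramble" & genotype == "affected"'`) or
#'   one-sided formulas.
#' @param batch Normalization batch identifier (defaults to the contrast
#'   name, i.e. per-contrast normalization).
#' @return A `contrast_spec` object.
#' @export
contrast_spec <- function(name, numerator, denominator, batch = name) {
  as_pred <- function(x) {
    if (inherits(x, "formula")) x <- deparse(x[[2]])
    if (!is.character(x) || length(x) != 1) {
      abort("contrast predicates must be strings or one-sided formulas.")
    }
    x
  }
  structure(list(name = name, numerator = as_pred(numerator),
                 denominator = as_pred(denominator), batch = batch),
            class = "contrast_spec")
}

contrast_samples <- function(design, spec) {
  sel <- function(pred) {
    keep <- rlang::eval_tidy(rlang::parse_expr(pred), data = design)
    design$sample_id[keep]
  }
  num <- sel(spec$numerator)
  den <- sel(spec$denominator)
  if (length(num) == 0 || length(den) == 0) {
    abort(sprintf("contrast '%s' selects an empty %s group.", spec$name,
                  if (length(num) == 0) "numerator" else "denominator"))
  }
  if (length(intersect(num, den)) > 0) {
    abort(sprintf("contrast '%s': numerator and denominator overlap.",
                  spec$name))
  }
  list(numerator = num, denominator = den)
}

#' Negative-binomial Wald test between two sample groups
#'
#' A simplified Wald analog of standard negative-binomial differential
#' expression: per-gene log2 fold-change of size-factor-normalized group
#' means (with a pseudocount for finiteness at zeros), a standard error from
#' the NB variance model `mu + dispersion * mu^2` propagated through the log,
#' a two-sided normal-approximation p-value, and Benjamini-Hochberg
#' adjustment over all tested genes. Genes with mean normalized count below
#' `min_mean` across the contrast's samples are reported with `NA` p-values
#' and excluded from the BH denominator.
#'
#' When `lines` is supplied and every cell line involved has samples on both
#' sides of the contrast, per-line log-mean centering absorbs baseline
#' line-to-line differences (the "+ cell line" covariate); for nested
#' designs (e.g. a genotype contrast, where each line sits on one side) the
#' centering is skipped automatically.
#'
#' @param counts Counts tibble or matrix.
#' @param numerator,denominator Character vectors of sample identifiers.
#' @param factors Size factors for (at least) the contrast samples; computed
#'   on the contrast samples when `NULL`.
#' @param dispersions Per-gene dispersions; estimated from the two groups
#'   when `NULL`.
#' @param lines Named character vector mapping sample id to cell line, or
#'   `NULL` to skip line centering.
#' @param pseudocount Normalized-count pseudocount added to each group mean
#'   before the log2 ratio.
#' @param min_mean Expression floor (mean normalized count) for testing.
#' @param name Contrast label stored on the result.
#' @return A `de_result` tibble: `gene`, `base_mean`, `log2fc`, `se`,
#'   `stat`, `p_value`, `p_adj`.
#' @export
nb_wald_test <- function(counts, numerator, denominator, factors = NULL,
                         dispersions = NULL, lines = NULL,
                         pseudocount = 0.5, min_mean = 1,
                         name = "contrast") {
  m <- if (is.matrix(counts)) counts else counts_matrix(counts)
  num <- as.character(numerator); den <- as.character(denominator)
  missing <- setdiff(c(num, den), colnames(m))
  if (length(missing) > 0) {
    abort(sprintf("samples not in counts: %s", paste(missing, collapse = ", ")))
  }
  if (length(intersect(num, den)) > 0) {
    abort("numerator and denominator samples must be disjoint.")
  }
  all_s <- c(num, den)
  if (is.null(factors)) {
    factors <- size_factors(m[, all_s, drop = FALSE])
  }
  sf <- factors[all_s]
  y <- sweep(m[, all_s, drop = FALSE], 2, sf, "/")

  # optional within-line centering of log-means (cell-line covariate)
  if (!is.null(lines)) {
    ln <- lines[all_s]
    spans <- tapply(all_s %in% num, ln, function(z) any(z) && any(!z))
    if (all(unlist(spans))) {
      l <- log2(y + pseudocount)
      grand <- rowMeans(l)
      for (lv in unique(ln)) {
        j <- which(ln == lv)
        l[, j] <- l[, j] - rowMeans(l[, j, drop = FALSE]) + grand
      }
      y <- pmax(2^l - pseudocount, 0)
    }
  }

  group <- ifelse(all_s %in% num, "num", "den")
  if (is.null(dispersions)) {
    dispersions <- estimate_dispersion(m[, all_s, drop = FALSE], sf, group)
  }
  alpha <- unname(dispersions[rownames(m)])

  n1 <- length(num); n0 <- length(den)
  mu1 <- rowMeans(y[, group == "num", drop = FALSE])
  mu0 <- rowMeans(y[, group == "den", drop = FALSE])
  base_mean <- rowMeans(y)

  lfc <- log2(mu1 + pseudocount) - log2(mu0 + pseudocount)
  inv_sf1 <- mean(1 / sf[group == "num"])
  inv_sf0 <- mean(1 / sf[group == "den"])
  v1 <- (mu1 * inv_sf1 + alpha * mu1^2) / n1
  v0 <- (mu0 * inv_sf0 + alpha * mu0^2) / n0
  log2e <- 1 / log(2)
  se <- sqrt(v1 * (log2e / (mu1 + pseudocount))^2 +
               v0 * (log2e / (mu0 + pseudocount))^2)
  stat <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * stats::pnorm(-abs(stat))

  tested <- base_mean >= min_mean
  p[!tested] <- NA_real_
  out <- tibble(gene = rownames(m), base_mean = unname(base_mean),
                log2fc = unname(lfc), se = unname(se), stat = unname(stat),
                p_value = unname(p),
                p_adj = unname(benjamini_hochberg(p)))
  class(out) <- c("de_result", class(out))
  attr(out, "contrast") <- name
  attr(out, "n_samples") <- c(numerator = n1, denominator = n0)
  out
}

#' The default five-normalization, eleven-contrast scheme
#'
#' Builds the study's contrast layout from a design table: one
#' scramble-vs-naive negative control per genotype (each its own
#' normalization batch), one disease-signature contrast of affected vs
#' unaffected controls (naive and scramble pooled as control; its own
#' batch), and one targeting-vs-scramble contrast per genotype per ASO
#' sequence per dose (normalized per genotype). With two sequences and two
#' doses this yields eleven contrasts across five batches.
#'
#' @param design A validated design tibble.
#' @return A named list of [contrast_spec()] objects.
#' @export
default_contrast_scheme <- function(design) {
  design <- validate_design(design)
  scheme <- list()
  for (gt in intersect(.genotypes, unique(design$genotype))) {
    nm <- sprintf("scramble_vs_naive_%s", gt)
    scheme[[nm]] <- contrast_spec(
      nm,
      sprintf('treatment == "scramble" & genotype == "%s"', gt),
      sprintf('treatment == "naive" & genotype == "%s"', gt),
      batch = sprintf("control_%s", gt))
  }
  scheme[["disease_signature"]] <- contrast_spec(
    "disease_signature",
    'genotype == "affected" & treatment %in% c("naive", "scramble")',
    'genotype == "unaffected" & treatment %in% c("naive", "scramble")',
    batch = "signature")
  targ <- design |>
    filter(.data$treatment == "targeting") |>
    dplyr::distinct(.data$genotype, .data$aso_sequence, .data$dose) |>
    arrange(.data$genotype, .data$aso_sequence, .data$dose)
  for (i in seq_len(nrow(targ))) {
    gt <- targ$genotype[i]; seq_ <- targ$aso_sequence[i]; d <- targ$dose[i]
    nm <- sprintf("aso_%s_%s_%s", seq_, format_dose(d), gt)
    scheme[[nm]] <- contrast_spec(
      nm,
      sprintf('treatment == "targeting" & aso_sequence == "%s" & dose == %s & genotype == "%s"',
              seq_, format_dose(d), gt),
      sprintf('treatment == "scramble" & genotype == "%s"', gt),
      batch = sprintf("aso_%s", gt))
  }
  scheme
}

#' Run a batch-normalized contrast scheme
#'
#' Executes each contrast with size factors computed once per normalization
#' batch (over the union of that batch's contrast samples), estimating
#' dispersions per contrast and applying the cell-line covariate where the
#' design permits.
#'
#' @param counts Counts tibble.
#' @param design Design tibble.
#' @param scheme Named list of [contrast_spec()]s; defaults to
#'   [default_contrast_scheme()].
#' @param use_line_covariate Pass cell-line assignments to [nb_wald_test()]?
#' @param ... Further arguments forwarded to [nb_wald_test()].
#' @return A named list of `de_result` tibbles, one per contrast.
#' @export
run_contrast_scheme <- function(counts, design,
                                scheme = default_contrast_scheme(design),
                                use_line_covariate = TRUE, ...) {
  ad <- align_samples(counts, design)
  counts <- ad$counts; design <- ad$design
  m <- counts_matrix(counts)
  lines <- stats::setNames(design$cell_line, design$sample_id)

  groups <- lapply(scheme, contrast_samples, design = design)
  batch_of <- vapply(scheme, `[[`, character(1), "batch")
  batch_sf <- lapply(split(names(scheme), batch_of), function(cn) {
    ids <- unique(unlist(lapply(groups[cn],
                                function(g) c(g$numerator, g$denominator))))
    size_factors(m[, ids, drop = FALSE])
  })

  out <- lapply(names(scheme), function(nm) {
    g <- groups[[nm]]
    nb_wald_test(m, g$numerator, g$denominator,
                 factors = batch_sf[[batch_of[[nm]]]],
                 lines = if (use_line_covariate) lines else NULL,
                 name = nm, ...)
  })
  stats::setNames(out, names(scheme))
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("<de_result> contrast '%s': %d genes, %d tested, %d at padj < 0.05\n",
              attr(x, "contrast") %||% "?", nrow(x), sum(!is.na(x$p_value)),
              sum(x$p_adj < 0.05, na.rm = TRUE)))
  NextMethod()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' @method tidy de_result
#' @export
tidy.de_result <- function(x, ...) {
  tibble(gene = x$gene, estimate = x$log2fc, std.error = x$se,
         statistic = x$stat, p.value = x$p_value, p.adjusted = x$p_adj,
         base_mean = x$base_mean)
}

#' @method glance de_result
#' @export
glance.de_result <- function(x, alpha = 0.05, ...) {
  tibble(contrast = attr(x, "contrast") %||% NA_character_,
         n_genes = nrow(x),
         n_tested = sum(!is.na(x$p_value)),
         n_significant = sum(x$p_adj < alpha, na.rm = TRUE),
         alpha = alpha)
}
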