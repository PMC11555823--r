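#' Median-of-ratios size factors
#'
#' Computes per-sample scaling factors as the median, over reference genes,
#' of the ratio of each sample's count to the per-gene geometric mean across
#' samples. Reference genes are those with strictly positive counts in every
#' sample; if none exist, genes positive in at least `fallback_fraction` of
#' samples are used, with the geometric mean and ratios taken over their
#' positive entries only. Factors are rescaled to geometric mean 1, so two
#' identical samples get factors of exactly 1 and a global scalar change of
#' library size is absorbed.
#'
#' @param counts Counts tibble (or numeric matrix with gene rownames).
#' @param fallback_fraction Minimum fraction of positive samples a gene needs
#'   to enter the fallback reference set.
#' @return A named numeric vector of positive size factors, one per sample,
#'   with attribute `fallback` indicating whether the fallback reference was
#'   used.
#' @export
size_factors <- function(counts, fallback_fraction = 0.9) {
  m <- if (is.matrix(counts)) counts else counts_matrix(counts)
  if (ncol(m) < 1) abort("need at least one sample.")
  log_m <- log(m)
  log_geo <- rowMeans(log_m)  # -Inf whenever any sample has a zero
  all_pos <- is.finite(log_geo)
  fallback <- FALSE
  if (any(all_pos)) {
    ratios <- log_m[all_pos, , drop = FALSE] - log_geo[all_pos]
    lf <- apply(ratios, 2, stats::median)
  } else {
    pos_frac <- rowMeans(m > 0)
    use <- pos_frac >= fallback_fraction & pos_frac > 0
    if (!any(use)) {
      abort(paste0("no gene is positive in enough samples to build a ",
                   "reference; lower `fallback_fraction` or filter samples."))
    }
    fallback <- TRUE
    lf <- vapply(seq_len(ncol(m)), function(j) {
      ratios <- vapply(which(use), function(g) {
        pos <- m[g, ] > 0
        if (!pos[j]) return(NA_real_)
        log(m[g, j]) - mean(log(m[g, pos]))
      }, numeric(1))
      stats::median(ratios, na.rm = TRUE)
    }, numeric(1))
  }
  lf <- lf - mean(lf)  # geometric-mean-1 convention
  sf <- exp(lf)
  names(sf) <- colnames(m)
  attr(sf, "fallback") <- fallback
  sf
}

#' Counts per million
#'
#' Scales each sample's counts to a library of one million; the unlogged
#' columns sum exactly to 1e6. With `log = TRUE` returns
#' `log2(CPM + pseudocount)`.
#'
#' @param counts Counts tibble or matrix.
#' @param log Return log2-transformed values?
#' @param pseudocount Added to CPM before the log (ignored when `log = FALSE`).
#' @return A numeric matrix (genes x samples).
#' @export
cpm <- function(counts, log = FALSE, pseudocount = 1) {
  m <- if (is.matrix(counts)) counts else counts_matrix(counts)
  lib <- colSums(m)
  if (any(lib <= 0)) {
    abort(sprintf("zero library size in sample(s): %s",
                  paste(colnames(m)[lib <= 0], collapse = ", ")))
  }
  out <- sweep(m, 2, lib, "/") * 1e6
  if (log) out <- log2(out + pseudocount)
  out
}

#' Method-of-moments negative-binomial dispersion
#'
#' Estimates a per-gene dispersion from within-group residual variance of
#' size-factor-normalized counts, optionally shrunk toward a fitted
#' mean-dispersion trend `a0 + a1/mean`. For each gene the pooled
#' within-group variance `s^2` (over groups with at least two replicates)
#' gives the moment estimate `(s^2 - mean)/mean^2`, floored at a small
#' positive value. Shrinkage averages the gene estimate with the trend,
#' weighting the gene by its residual degrees of freedom against
#' `prior_df` pseudo-observations from the trend.
#'
#' @param counts Counts tibble or matrix.
#' @param factors Size factors from [size_factors()] (computed if `NULL`).
#' @param groups Character/factor vector assigning each sample to a design
#'   group (replicates share a group).
#' @param floor Lower bound for the dispersion.
#' @param shrink Shrink toward the fitted trend?
#' @param prior_df Weight (in pseudo degrees of freedom) of the trend.
#' @return Numeric vector of per-gene dispersions with attribute `trend`
#'   (the fitted trend coefficients).
#' @export
estimate_dispersion <- function(counts, factors = NULL, groups,
                                floor = 1e-8, shrink = TRUE, prior_df = 20) {
  m <- if (is.matrix(counts)) counts else counts_matrix(counts)
  if (length(groups) != ncol(m)) {
    abort("`groups` must have one entry per sample.")
  }
  if (is.null(factors)) factors <- size_factors(m)
  y <- sweep(m, 2, factors, "/")
  groups <- as.character(groups)
  tab <- table(groups)
  rep_groups <- names(tab)[tab >= 2]
  if (length(rep_groups) == 0) {
    abort("dispersion estimation needs at least one group with replicates.")
  }
  ss <- 0; df <- 0; mu_num <- 0; mu_den <- 0
  for (g in rep_groups) {
    j <- which(groups == g)
    mu_g <- rowMeans(y[, j, drop = FALSE])
    ss <- ss + rowSums((y[, j, drop = FALSE] - mu_g)^2)
    df <- df + length(j) - 1
    mu_num <- mu_num + length(j) * mu_g
    mu_den <- mu_den + length(j)
  }
  s2 <- ss / df
  mu <- mu_num / mu_den
  raw <- ifelse(mu > 0, (s2 - mu) / mu^2, floor)
  raw <- pmax(raw, floor)

  trend_coef <- c(asymptotic = NA_real_, scale = NA_real_)
  disp <- raw
  if (shrink) {
    ok <- mu > 0 & is.finite(raw) & raw > floor
    if (sum(ok) >= 50) {
      fit <- stats::lm(raw[ok] ~ I(1 / mu[ok]))
      a0 <- max(unname(stats::coef(fit)[1]), 1e-4)
      a1 <- max(unname(stats::coef(fit)[2]), 0)
      trend_coef <- c(asymptotic = a0, scale = a1)
      trend <- ifelse(mu > 0, a0 + a1 / mu, a0)
      disp <- (df * raw + prior_df * trend) / (df + prior_df)
    }
  }
  disp <- pmax(disp, floor)
  names(disp) <- rownames(m)
  attr(disp, "trend") <- trend_coef
  disp
}
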