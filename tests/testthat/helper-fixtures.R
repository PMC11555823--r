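# Small programmatic fixtures shared across test files.

tiny_counts <- function() {
  tibble::tibble(gene = c("g1", "g2", "g3"),
                 s1 = c(0L, 2L, 4L), s2 = c(1L, 3L, 5L))
}

tiny_design <- function() {
  tibble::tibble(
    sample_id = c("s1", "s2"),
    genotype = c("unaffected", "affected"),
    cell_line = c("U1", "A1"),
    treatment = c("naive", "naive"),
    aso_sequence = c("none", "none"),
    dose = c(0, 0))
}

# the baseline control layout: 4 lines per genotype, naive + scramble each,
# one sample dropped from the affected side to give the 8-vs-7 comparison
baseline_design <- function() {
  tidyr::expand_grid(genotype = c("unaffected", "affected"),
                     line = 1:4,
                     treatment = c("naive", "scramble")) |>
    dplyr::mutate(
      cell_line = paste0(ifelse(genotype == "unaffected", "U", "A"), line),
      aso_sequence = ifelse(treatment == "scramble", "SCR", "none"),
      dose = ifelse(treatment == "scramble", 20, 0),
      sample_id = paste(cell_line, treatment, sep = "_")) |>
    dplyr::select(sample_id, genotype, cell_line, treatment, aso_sequence,
                  dose) |>
    utils::head(-1)
}

# cached mid-size simulation reused by several test files
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_genes = 2000, n_dosage_up = 60, n_dosage_down = 120)
      cache <<- simulate_dataset(cfg, seed = 101)
    }
    cache
  }
})

# exhaustive hypergeometric upper-tail oracle using log-binomials only
hyper_tail_oracle <- function(N, a, b, s) {
  if (s > min(a, b)) return(0)
  i <- s:min(a, b)
  sum(exp(lchoose(a, i) + lchoose(N - a, b - i) - lchoose(N, b)))
}

# literal BH step-up: sort, scale by n/rank, enforce monotonicity from the top
bh_oracle <- function(p) {
  ok <- !is.na(p)
  q <- p[ok]
  n <- length(q)
  o <- order(q)
  adj <- q[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- rep(NA_real_, length(p))
  out[ok][o] <- adj
  out
}

# direct median-of-ratios recomputation (log-scale median so an even gene
# count interpolates geometrically; geometric-mean-1 convention)
size_factor_oracle <- function(m) {
  ref <- apply(m, 1, function(x) exp(mean(log(x))))
  keep <- is.finite(log(ref))
  sf <- vapply(seq_len(ncol(m)),
               function(j) exp(stats::median(log(m[keep, j] / ref[keep]))),
               numeric(1))
  sf / exp(mean(log(sf)))
}

# draw one element of a vector (sample() misreads length-1 integer vectors)
pick1 <- function(v) v[sample.int(length(v), 1)]

# adjusted Rand index for two label vectors
adjusted_rand <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  idx <- sum(choose(tab, 2))
  exp_idx <- a * b / choose(n, 2)
  max_idx <- (a + b) / 2
  (idx - exp_idx) / (max_idx - exp_idx)
}
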