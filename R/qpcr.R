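#' Relative expression by the delta-delta-Ct method
#'
#' Classic relative qPCR quantification at fixed amplification efficiency 2.
#' Technical replicates are averaged per (sample, gene); the per-sample
#' delta Ct is the target Ct minus the housekeeping Ct; the delta-delta Ct
#' subtracts the arithmetic mean delta Ct of the reference group; the
#' fold-change is `2^(-ddCt)`. By construction the reference group's mean
#' fold-change on the delta-Ct scale is exactly 1, and a constant plate
#' offset added to every Ct cancels.
#'
#' @param ct_table Tibble with columns `sample_id`, `group`, `gene`, `ct`
#'   (an optional `replicate` column marks technical replicates).
#' @param target Target gene symbol.
#' @param housekeeping Housekeeping gene symbol.
#' @param reference_group Level of `group` to normalize against.
#' @return A tibble with per-sample `delta_ct`, `delta_delta_ct`,
#'   `fold_change`.
#' @export
#' @examples
#' ct <- tibble::tibble(
#'   sample_id = rep(c("c1", "c2", "t1"), each = 2),
#'   group = rep(c("ctrl", "ctrl", "treated"), each = 2),
#'   gene = rep(c("GOI", "HK"), 3),
#'   ct = c(24, 20, 25, 21, 23, 20))
#' ddct(ct, "GOI", "HK", "ctrl")
ddct <- function(ct_table, target, housekeeping, reference_group) {
  req <- c("sample_id", "group", "gene", "ct")
  if (!all(req %in% names(ct_table))) {
    abort(sprintf("`ct_table` must have columns: %s",
                  paste(req, collapse = ", ")))
  }
  if (any(!is.finite(ct_table$ct) | ct_table$ct <= 0)) {
    abort("all Ct values must be positive numbers.")
  }
  avg <- ct_table |>
    filter(.data$gene %in% c(target, housekeeping)) |>
    group_by(.data$sample_id, .data$group, .data$gene) |>
    summarise(ct = mean(.data$ct), .groups = "drop")
  wide <- avg |>
    tidyr::pivot_wider(names_from = "gene", values_from = "ct")
  for (g in c(target, housekeeping)) {
    if (!g %in% names(wide) || any(is.na(wide[[g]]))) {
      miss <- if (!g %in% names(wide)) wide$sample_id else
        wide$sample_id[is.na(wide[[g]])]
      abort(sprintf("missing Ct for gene '%s' in sample(s): %s", g,
                    paste(miss, collapse = ", ")))
    }
  }
  wide$delta_ct <- wide[[target]] - wide[[housekeeping]]
  ref <- wide$delta_ct[wide$group == reference_group]
  if (length(ref) == 0) {
    abort(sprintf("reference group '%s' has no samples.", reference_group))
  }
  wide |>
    mutate(delta_delta_ct = .data$delta_ct - mean(ref),
           fold_change = 2^(-.data$delta_delta_ct)) |>
    select("sample_id", "group", "delta_ct", "delta_delta_ct",
           "fold_change")
}
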