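#' Compare HSR calls against known truth blocks
#'
#' Block-level precision/recall for origin-A calls against the generator's
#' truth. A truth block counts as recovered when same-haplotype A calls
#' cover at least `min_overlap` of it; a call counts as correct when at
#' least `min_overlap` of its bases fall inside the haplotype's truth
#' blocks. Recall is computed over truth blocks of at least `min_truth_bp`
#' (the scan cannot resolve sub-window blocks); precision over all A calls.
#'
#' @param calls HSR call tibble.
#' @param truth Truth block tibble from [simulate_admixed_haplotypes()].
#' @param chrom_lengths Named chromosome lengths (for the recovered
#'   admixture fraction).
#' @param min_truth_bp Minimum truth-block size entering recall (default
#'   40 kb = two scan windows).
#' @param min_overlap Reciprocal overlap fraction (default 0.5).
#' @param n_query_haps Number of query haplotypes (defaults to the distinct
#'   haplotypes in `truth`).
#' @return One-row tibble: `n_truth`, `n_calls`, `precision`, `recall`,
#'   `f1`, `admix_called` (mean per-haplotype A-call fraction of the
#'   genome), `admix_true` (same from the truth blocks).
#' @export
evaluate_calls <- function(calls, truth, chrom_lengths,
                           min_truth_bp = 40000, min_overlap = 0.5,
                           n_query_haps = length(unique(truth$hap_id))) {
  a_calls <- filter(calls, .data$origin == "A")
  big_truth <- filter(truth, .data$end - .data$start >= min_truth_bp)
  total <- sum(chrom_lengths)
  hap_overlap <- function(x_row, y) {
    yv <- y[y$hap_id == x_row$hap_id & y$chrom == x_row$chrom, ]
    if (nrow(yv) == 0) return(0)
    sum(pmax(0, pmin(x_row$end, yv$end) - pmax(x_row$start, yv$start)))
  }
  recall <- if (nrow(big_truth) == 0) NA_real_ else {
    hits <- vapply(seq_len(nrow(big_truth)), function(i) {
      tb <- big_truth[i, ]
      hap_overlap(tb, a_calls) >= min_overlap * (tb$end - tb$start)
    }, logical(1))
    mean(hits)
  }
  precision <- if (nrow(a_calls) == 0) NA_real_ else {
    hits <- vapply(seq_len(nrow(a_calls)), function(i) {
      cl <- a_calls[i, ]
      hap_overlap(cl, truth) >= min_overlap * (cl$end - cl$start)
    }, logical(1))
    mean(hits)
  }
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else 2 * precision * recall / (precision + recall)
  n_query_haps <- max(1, n_query_haps)
  tibble(
    n_truth = nrow(big_truth),
    n_calls = nrow(a_calls),
    precision = precision,
    recall = recall,
    f1 = f1,
    admix_called = sum(a_calls$end - a_calls$start) / (total * n_query_haps),
    admix_true = sum(truth$end - truth$start) / (total * n_query_haps)
  )
}
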