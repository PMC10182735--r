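#' Scan configuration
#'
#' Tuning parameters of the windowed distance-ratio scan.
#'
#' @param window_size_bp Window size in bp (default 20 kb, chosen so a window
#'   holds about 100 SNPs at typical densities).
#' @param min_max_distance Low-diversity filter: a (haplotype, window) pair is
#'   dropped when the larger of its two panel distances is below this count
#'   (default 20).
#' @param fold_threshold Call threshold as fold deviation from the
#'   genome-wide mean ratio (default 8).
#' @param merge_gap_bp Called regions closer than this are combined
#'   (default 50 kb, strict inequality).
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(window_size_bp = 20000,
                        min_max_distance = 20,
                        fold_threshold = 8,
                        merge_gap_bp = 50000) {
  check_scalar(window_size_bp, "window_size_bp", min = 0, strict_min = TRUE)
  check_scalar(min_max_distance, "min_max_distance", min = 0,
               strict_min = TRUE)
  check_scalar(fold_threshold, "fold_threshold", min = 1, strict_min = TRUE)
  check_scalar(merge_gap_bp, "merge_gap_bp", min = 0)
  structure(list(window_size_bp = window_size_bp,
                 min_max_distance = min_max_distance,
                 fold_threshold = fold_threshold,
                 merge_gap_bp = merge_gap_bp),
            class = "scan_config")
}

#' Tile chromosomes into non-overlapping windows
#'
#' Windows start at position 0; a trailing partial window is retained.
#'
#' @param chrom_lengths Named vector of chromosome lengths in bp, or a
#'   [phased_panel()] (its `chrom_lengths` are used).
#' @param window_size_bp Window size in bp.
#' @return Tibble with `chrom`, `start`, `end`.
#' @export
build_windows <- function(chrom_lengths, window_size_bp = 20000) {
  if (inherits(chrom_lengths, "phased_panel")) {
    chrom_lengths <- chrom_lengths$chrom_lengths
  }
  out <- lapply(names(chrom_lengths), function(cn) {
    L <- unname(chrom_lengths[[cn]])
    starts <- seq(0, L - 1, by = window_size_bp)
    tibble(chrom = cn, start = starts, end = pmin(starts + window_size_bp, L))
  })
  bind_rows(out)
}

#' Minimum Hamming distance from one haplotype to a panel
#'
#' @param hap 0/1 vector for the query haplotype over the window's sites.
#' @param panel 0/1 matrix of reference haplotypes (rows) over the same
#'   sites.
#' @return Integer: the smallest count of mismatching sites over panel
#'   members. A window with zero sites gives 0.
#' @export
min_hamming <- function(hap, panel) {
  panel <- as.matrix(panel)
  abort_if(nrow(panel) == 0, "empty reference panel")
  if (length(hap) == 0) return(0L)
  abort_if(ncol(panel) != length(hap),
           "haplotype and panel cover different site counts")
  as.integer(min(colSums(abs(t(panel) - hap))))
}

# all-window minimum distances query x {ref_A, ref_B}, vectorised per window
window_min_distances <- function(query_m, ref_m, site_win) {
  nq <- nrow(query_m)
  wins <- sort(unique(site_win))
  out <- matrix(NA_integer_, nq, length(wins),
                dimnames = list(rownames(query_m), wins))
  rs_ref <- NULL
  for (wi in seq_along(wins)) {
    idx <- which(site_win == wins[wi])
    q <- query_m[, idx, drop = FALSE]
    r <- ref_m[, idx, drop = FALSE]
    d <- matrix(rowSums(q), nq, nrow(r)) +
      matrix(rowSums(r), nq, nrow(r), byrow = TRUE) -
      2 * tcrossprod(q, r)
    out[, wi] <- as.integer(round(apply(d, 1, min)))
  }
  out
}

#' Score query haplotypes in windows against two reference panels
#'
#' For every (query haplotype, window) pair, computes the minimum Hamming
#' distance to each reference panel, their ratio `d_A / d_B`, and the
#' low-diversity filter flag (`max(d_A, d_B) < min_max_distance`). A ratio of
#' `Inf` (d_B = 0, d_A > 0) is permitted; 0/0 windows are always filtered.
#'
#' @param query,ref_a,ref_b [phased_panel()]s over the same site set.
#' @param config A [scan_config()].
#' @return Tibble with `hap_id`, `chrom`, `start`, `end`, `n_sites`, `d_a`,
#'   `d_b`, `ratio`, `filtered`.
#' @export
score_windows <- function(query, ref_a, ref_b, config = scan_config()) {
  abort_if(nrow(query$geno) == 0, "empty query panel")
  abort_if(!identical(query$sites$pos, ref_a$sites$pos) ||
             !identical(query$sites$pos, ref_b$sites$pos),
           "query and reference panels must share one site set")
  windows <- build_windows(query, config$window_size_bp)
  ws <- config$window_size_bp
  out <- lapply(unique(windows$chrom), function(cn) {
    sidx <- which(query$sites$chrom == cn)
    win_tbl <- windows[windows$chrom == cn, ]
    pos <- query$sites$pos[sidx]
    site_win <- pos %/% ws
    qm <- query$geno[, sidx, drop = FALSE]
    am <- panel_matrix(ref_a)[, sidx, drop = FALSE]
    bm <- panel_matrix(ref_b)[, sidx, drop = FALSE]
    da <- window_min_distances(qm, am, site_win)
    db <- window_min_distances(qm, bm, site_win)
    occupied <- as.integer(colnames(da))
    n_sites <- as.integer(table(site_win))
    grid <- tibble(
      win = rep(win_tbl$start %/% ws, each = nrow(qm)),
      hap_id = rep(rownames(query$geno), times = nrow(win_tbl)),
      chrom = cn,
      start = rep(win_tbl$start, each = nrow(qm)),
      end = rep(win_tbl$end, each = nrow(qm))
    )
    wcol <- match(grid$win, occupied)
    take_win <- function(m) {
      v <- rep(0L, nrow(grid))
      has <- !is.na(wcol)
      v[has] <- m[cbind(match(grid$hap_id[has], rownames(m)), wcol[has])]
      v
    }
    d_a_v <- take_win(da)
    d_b_v <- take_win(db)
    grid %>%
      mutate(
        n_sites = if_else(is.na(wcol), 0L, n_sites[wcol]),
        d_a = d_a_v,
        d_b = d_b_v,
        ratio = if_else(.data$d_a == 0 & .data$d_b == 0, NA_real_,
                        .data$d_a / .data$d_b),
        filtered = pmax(.data$d_a, .data$d_b) < config$min_max_distance
      ) %>%
      select(-"win")
  })
  bind_rows(out) %>% arrange(.data$hap_id, .data$chrom, .data$start)
}

#' Genome-wide mean distance ratio
#'
#' For each query haplotype, the mean of its unfiltered `d_A` values divided
#' by the mean of its unfiltered `d_B` values; the scan's reference point is
#' the mean of these per-haplotype ratios (not the mean of window ratios).
#'
#' @param scores Window score tibble from [score_windows()].
#' @return Scalar mean ratio.
#' @export
genomewide_mean_ratio <- function(scores) {
  per_hap <- scores %>%
    filter(!.data$filtered) %>%
    group_by(.data$hap_id) %>%
    summarise(r = mean(.data$d_a) / mean(.data$d_b), n = n())
  missing <- setdiff(unique(scores$hap_id), per_hap$hap_id)
  abort_if(length(missing) > 0,
           sprintf("haplotype(s) with no unfiltered windows: %s",
                   paste(missing, collapse = ", ")))
  mean(per_hap$r)
}

#' Call high-similarity regions (HSRs) from window scores
#'
#' Unfiltered windows with `ratio <= mean_ratio / fold` are called origin
#' `A`; `ratio >= mean_ratio * fold` origin `B` (equality counts as called).
#' Same-origin called windows of one haplotype closer than `merge_gap_bp`
#' (strict) are combined into contiguous regions.
#'
#' @param scores Window score tibble from [score_windows()].
#' @param mean_ratio Genome-wide mean ratio (see [genomewide_mean_ratio()]).
#' @param config A [scan_config()].
#' @return Tibble with `hap_id`, `chrom`, `start`, `end`, `origin`,
#'   `n_windows`, `size_bp`.
#' @export
call_hsrs <- function(scores, mean_ratio, config = scan_config()) {
  abort_if(!is.finite(mean_ratio) || mean_ratio <= 0,
           "`mean_ratio` must be a positive finite number")
  thr <- hsr_thresholds(mean_ratio, config$fold_threshold)
  called <- scores %>%
    filter(!.data$filtered, !is.na(.data$ratio)) %>%
    mutate(origin = dplyr::case_when(
      .data$ratio <= thr[["low"]] ~ "A",
      .data$ratio >= thr[["high"]] ~ "B",
      TRUE ~ NA_character_
    )) %>%
    filter(!is.na(.data$origin))
  if (nrow(called) == 0) {
    return(tibble(hap_id = character(), chrom = character(),
                  start = numeric(), end = numeric(), origin = character(),
                  n_windows = integer(), size_bp = numeric()))
  }
  called %>%
    select("hap_id", "chrom", "origin", "start", "end") %>%
    group_by(.data$hap_id, .data$chrom) %>%
    group_split() %>%
    purrr::map(merge_called_windows, max_gap = config$merge_gap_bp) %>%
    bind_rows() %>%
    mutate(size_bp = .data$end - .data$start) %>%
    select("hap_id", "chrom", "start", "end", "origin", "n_windows",
           "size_bp") %>%
    arrange(.data$hap_id, .data$chrom, .data$start)
}

# Merge same-origin called windows of one haplotype/chromosome when their
# gap is strictly below max_gap AND no opposite-origin called window lies in
# the gap: an intervening call of the other origin breaks contiguity, which
# also guarantees A and B regions never overlap.
merge_called_windows <- function(d, max_gap) {
  d <- arrange(d, .data$start)
  out <- list()
  for (or in unique(d$origin)) {
    own <- d[d$origin == or, ]
    other_starts <- d$start[d$origin != or]
    if (nrow(own) == 1) {
      runs <- rep(1L, 1)
    } else {
      gap_lo <- own$end[-nrow(own)]
      gap_hi <- own$start[-1]
      blocked <- vapply(seq_along(gap_lo), function(i) {
        any(other_starts >= gap_lo[i] & other_starts < gap_hi[i])
      }, logical(1))
      new_run <- c(TRUE, gap_hi - gap_lo >= max_gap | blocked)
      runs <- cumsum(new_run)
    }
    out[[or]] <- own %>%
      mutate(run = runs) %>%
      group_by(.data$hap_id, .data$chrom, .data$origin, .data$run) %>%
      summarise(start = min(.data$start), end = max(.data$end),
                n_windows = n(), .groups = "drop") %>%
      select(-"run")
  }
  bind_rows(out)
}

#' Call thresholds implied by a mean ratio and fold deviation
#'
#' @param mean_ratio Genome-wide mean distance ratio.
#' @param fold Fold deviation (default 8).
#' @return Named vector with `low` (`mean_ratio / fold`) and `high`
#'   (`mean_ratio * fold`).
#' @export
hsr_thresholds <- function(mean_ratio, fold = 8) {
  c(low = mean_ratio / fold, high = mean_ratio * fold)
}

#' Run the full window scan on a combined panel
#'
#' Splits `panel` into its `query`, `ref_A` and `ref_B` groups, scores all
#' windows, computes the genome-wide mean ratio and calls HSRs.
#'
#' @param panel A [phased_panel()] containing all three groups.
#' @param config A [scan_config()].
#' @return An object of class `hsr_scan`: list with `scores`, `mean_ratio`,
#'   `thresholds`, `calls`, `config`. Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @export
hsr_scan <- function(panel, config = scan_config()) {
  query <- panel_subset(panel, "query")
  ref_a <- panel_subset(panel, "ref_A")
  ref_b <- panel_subset(panel, "ref_B")
  scores <- score_windows(query, ref_a, ref_b, config)
  mean_ratio <- genomewide_mean_ratio(scores)
  calls <- call_hsrs(scores, mean_ratio, config)
  structure(
    list(scores = scores, mean_ratio = mean_ratio,
         thresholds = hsr_thresholds(mean_ratio, config$fold_threshold),
         calls = calls, config = config,
         chrom_lengths = panel$chrom_lengths,
         query_haps = rownames(query$geno)),
    class = "hsr_scan"
  )
}

#' @export
print.hsr_scan <- function(x, ...) {
  cat(sprintf("<hsr_scan> mean ratio %.3f (call thresholds %.3f / %.3f)\n",
              x$mean_ratio, x$thresholds[["low"]], x$thresholds[["high"]]))
  cat(sprintf("  %d window scores (%d filtered), %d HSR calls (A: %d, B: %d)\n",
              nrow(x$scores), sum(x$scores$filtered), nrow(x$calls),
              sum(x$calls$origin == "A"), sum(x$calls$origin == "B")))
  invisible(x)
}

#' Pairwise Hamming distance matrix over an interval
#'
#' @param panel A [phased_panel()].
#' @param chrom,start,end Interval (0-based half-open) that must contain at
#'   least one site.
#' @param normalize Divide by the largest distance (max cell becomes 1).
#' @return Symmetric numeric matrix with haplotype ids as dimnames.
#' @export
pairwise_hamming_matrix <- function(panel, chrom, start, end,
                                    normalize = FALSE) {
  idx <- which(panel$sites$chrom == chrom & panel$sites$pos >= start &
                 panel$sites$pos < end)
  abort_if(length(idx) == 0, "interval contains no sites")
  m <- panel$geno[, idx, drop = FALSE]
  rs <- rowSums(m)
  d <- matrix(rs, nrow(m), nrow(m)) + matrix(rs, nrow(m), nrow(m),
                                             byrow = TRUE) -
    2 * tcrossprod(m)
  dimnames(d) <- list(rownames(m), rownames(m))
  if (normalize && max(d) > 0) d <- d / max(d)
  d
}
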