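#' Merge half-open intervals closer than a gap threshold
#'
#' Two intervals are merged iff the gap between them (`next.start - prev.end`)
#' is strictly less than `max_gap`; overlapping intervals are always merged.
#' Merging is applied separately within every combination of the
#' non-coordinate columns (chromosome, labels, haplotype ids, ...), is
#' idempotent and order-invariant.
#'
#' @param intervals Tibble with `start`, `end` (0-based half-open) and any
#'   number of grouping columns (at least `chrom`).
#' @param max_gap Merge gap threshold in bp (`>= 0`). With the default 0 only
#'   overlapping intervals are unioned; intervals that merely touch are kept.
#' @return Tibble with the grouping columns, `start`, `end` and `n_merged`
#'   (how many input intervals each output interval absorbed).
#' @export
merge_intervals <- function(intervals, max_gap = 0) {
  abort_if(!is.numeric(max_gap) || length(max_gap) != 1 || max_gap < 0,
           "`max_gap` must be a single non-negative number")
  intervals <- as_tibble(intervals)
  abort_if(!all(c("start", "end") %in% names(intervals)),
           "`intervals` needs start and end columns")
  abort_if(any(intervals$start >= intervals$end),
           "intervals must satisfy start < end")
  key_cols <- setdiff(names(intervals), c("start", "end"))
  if (nrow(intervals) == 0) {
    return(mutate(intervals, n_merged = integer()))
  }
  intervals %>%
    group_by(across(all_of(key_cols))) %>%
    arrange(.data$start, .data$end, .by_group = TRUE) %>%
    mutate(
      run_end = cummax(.data$end),
      new_run = .data$start - lag(.data$run_end,
                                  default = -Inf) >= max_gap,
      run_id = cumsum(.data$new_run)
    ) %>%
    group_by(.data$run_id, .add = TRUE) %>%
    summarise(start = min(.data$start), end = max(.data$end),
              n_merged = n(), .groups = "drop") %>%
    select(all_of(key_cols), "start", "end", "n_merged") %>%
    arrange(across(all_of(c(key_cols, "start"))))
}

#' Total bases covered by an interval set
#'
#' Overlaps within the same chromosome are counted once.
#'
#' @param intervals Tibble with `chrom`, `start`, `end`.
#' @return Total covered bases (numeric scalar).
#' @export
interval_size <- function(intervals) {
  if (nrow(intervals) == 0) return(0)
  m <- merge_intervals(select(intervals, "chrom", "start", "end"),
                       max_gap = 0)
  sum(m$end - m$start)
}

#' Bases shared between two interval sets
#'
#' @param x,y Interval tibbles with `chrom`, `start`, `end`. Each set is
#'   unioned internally before intersection.
#' @return Total intersected bases.
#' @export
intersect_size <- function(x, y) {
  if (nrow(x) == 0 || nrow(y) == 0) return(0)
  xm <- merge_intervals(select(as_tibble(x), "chrom", "start", "end"), 0)
  ym <- merge_intervals(select(as_tibble(y), "chrom", "start", "end"), 0)
  total <- 0
  for (cn in intersect(unique(xm$chrom), unique(ym$chrom))) {
    xs <- xm[xm$chrom == cn, ]
    ys <- ym[ym$chrom == cn, ]
    for (i in seq_len(nrow(xs))) {
      total <- total + sum(pmax(0, pmin(xs$end[i], ys$end) -
                                  pmax(xs$start[i], ys$start)))
    }
  }
  total
}

#' Per-base coverage count of an interval set, run-length encoded
#'
#' @param intervals Tibble with `chrom`, `start`, `end`; one unit of coverage
#'   per row (callers wanting per-haplotype counts must pass intervals that
#'   are non-overlapping within a haplotype).
#' @param chrom_lengths Named vector of chromosome lengths; zero-coverage
#'   segments are emitted so that segment lengths sum to each chromosome
#'   length exactly.
#' @return Tibble with `chrom`, `start`, `end`, `count`.
#' @export
coverage_track <- function(intervals, chrom_lengths) {
  out <- lapply(names(chrom_lengths), function(cn) {
    L <- unname(chrom_lengths[[cn]])
    iv <- intervals[intervals$chrom == cn, , drop = FALSE]
    if (nrow(iv) == 0) {
      return(tibble(chrom = cn, start = 0, end = L, count = 0L))
    }
    abort_if(any(iv$start < 0) || any(iv$end > L),
             sprintf("interval outside chromosome bounds on %s", cn))
    bp <- sort(unique(c(0, L, iv$start, iv$end)))
    delta <- rep(0L, length(bp))
    tab_s <- table(factor(iv$start, levels = bp))
    tab_e <- table(factor(iv$end, levels = bp))
    delta <- as.integer(tab_s) - as.integer(tab_e)
    counts <- cumsum(delta)
    seg <- tibble(chrom = cn, start = bp[-length(bp)], end = bp[-1],
                  count = counts[-length(bp)])
    # collapse consecutive segments with equal count
    seg %>%
      mutate(run = cumsum(c(1L, diff(.data$count) != 0))) %>%
      group_by(.data$chrom, .data$run) %>%
      summarise(start = min(.data$start), end = max(.data$end),
                count = first(.data$count), .groups = "drop") %>%
      select("chrom", "start", "end", "count")
  })
  bind_rows(out) %>% arrange(.data$chrom, .data$start)
}
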