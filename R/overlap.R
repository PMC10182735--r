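#' Per-base HSR recurrence track
#'
#' Run-length encoded count of query haplotypes whose same-origin HSRs cover
#' each base, one track per origin, including zero-count segments so that
#' segment lengths sum to the genome length.
#'
#' @param calls HSR call tibble (from [call_hsrs()] or [hsr_scan()]`$calls`).
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param n_query_haps Number of query haplotypes (bounds check).
#' @return Tibble with `origin`, `chrom`, `start`, `end`, `count`.
#' @export
overlap_track <- function(calls, chrom_lengths, n_query_haps) {
  check_scalar(n_query_haps, "n_query_haps", min = 1, integerish = TRUE)
  origins <- if (nrow(calls) > 0) sort(unique(calls$origin)) else character()
  out <- lapply(origins, function(or) {
    iv <- calls %>%
      filter(.data$origin == or) %>%
      # one unit of coverage per haplotype: union within haplotype first
      select("hap_id", "chrom", "start", "end") %>%
      merge_intervals(max_gap = 0) %>%
      select("chrom", "start", "end")
    coverage_track(iv, chrom_lengths) %>%
      mutate(origin = or)
  })
  track <- bind_rows(out)
  if (nrow(track) > 0) {
    abort_if(max(track$count) > n_query_haps,
             "per-base count exceeds the number of query haplotypes")
  }
  select(track, "origin", "chrom", "start", "end", "count")
}

#' Regions recurring in exactly (or at least) k haplotypes
#'
#' @param track Recurrence track from [overlap_track()].
#' @param k Overlap count of interest.
#' @param at_least Use `count >= k` instead of the default exact `count == k`.
#' @param origin Optional origin filter (`"A"` or `"B"`).
#' @param n_haps Optional number of query haplotypes; requesting `k` above it
#'   is an error.
#' @return Interval tibble `origin`, `chrom`, `start`, `end` of maximal runs.
#' @export
recurrent_regions <- function(track, k, at_least = FALSE, origin = NULL,
                              n_haps = NULL) {
  check_scalar(k, "k", min = 0, integerish = TRUE)
  if (!is.null(n_haps)) {
    abort_if(k > n_haps, "k exceeds the number of query haplotypes")
  }
  if (!is.null(origin)) track <- filter(track, .data$origin %in% !!origin)
  seg <- if (at_least) filter(track, .data$count >= k)
         else filter(track, .data$count == k)
  if (nrow(seg) == 0) {
    return(tibble(origin = character(), chrom = character(),
                  start = numeric(), end = numeric()))
  }
  # adjacent qualifying segments (gap 0 at shared breakpoints) become one run
  seg %>%
    select("origin", "chrom", "start", "end") %>%
    merge_intervals(max_gap = 1) %>%
    select("origin", "chrom", "start", "end")
}

#' Per-haplotype HSR fraction of the callable genome
#'
#' `f_i` is the share of the callable genome covered by haplotype `i`'s
#' same-origin HSRs (intersected with the callable mask), the ingredient of
#' the random-placement expectation.
#'
#' @param calls HSR call tibble.
#' @param callable Interval tibble of callable regions (see
#'   [callable_mask()]), or `NULL` to use whole chromosomes.
#' @param chrom_lengths Named chromosome lengths (used when `callable` is
#'   `NULL` and for the denominator check).
#' @param hap_ids Full set of query haplotype ids (zero-call haplotypes get
#'   `f = 0`).
#' @return Tibble with `origin`, `hap_id`, `f`.
#' @export
haplotype_fractions <- function(calls, callable = NULL, chrom_lengths = NULL,
                                hap_ids = NULL) {
  if (is.null(callable)) {
    abort_if(is.null(chrom_lengths),
             "supply `callable` intervals or `chrom_lengths`")
    callable <- tibble(chrom = names(chrom_lengths), start = 0,
                       end = as.numeric(chrom_lengths))
  }
  s_callable <- interval_size(callable)
  abort_if(s_callable <= 0, "callable genome size must be positive")
  hap_ids <- hap_ids %||% unique(calls$hap_id)
  unknown <- setdiff(unique(calls$hap_id), hap_ids)
  abort_if(length(unknown) > 0,
           sprintf("calls reference unknown haplotype(s): %s",
                   paste(unknown, collapse = ", ")))
  origins <- if (nrow(calls) > 0) sort(unique(calls$origin)) else "A"
  grid <- tidyr::expand_grid(origin = origins, hap_id = hap_ids)
  grid$f <- purrr::map2_dbl(grid$origin, grid$hap_id, function(or, h) {
    iv <- filter(calls, .data$origin == or, .data$hap_id == h)
    intersect_size(iv, callable) / s_callable
  })
  attr(grid, "s_callable") <- s_callable
  grid
}

#' Expected bases where every haplotype carries an HSR
#'
#' Random-placement null: the chance that one base lies in an HSR in all n
#' haplotypes is the product of the per-haplotype fractions; multiplied by
#' the callable genome size it gives the expected count of fully recurrent
#' bases.
#'
#' @param f Vector of per-haplotype HSR fractions, one entry per query
#'   haplotype.
#' @param s_callable Callable genome size in bp.
#' @return Expected number of bases (numeric scalar).
#' @export
expected_full_overlap <- function(f, s_callable) {
  abort_if(any(f < 0 | f > 1), "fractions must lie in [0, 1]")
  check_scalar(s_callable, "s_callable", min = 0, strict_min = TRUE)
  prod(f) * s_callable
}

#' Expected bases at overlap count k under a binomial null
#'
#' Uses a single fraction `f` for every haplotype:
#' `choose(n, k) f^k (1-f)^(n-k) * s_callable`.
#'
#' @param f HSR fraction (by convention the highest of the per-haplotype
#'   fractions, a conservative choice).
#' @param s_callable Callable genome size in bp.
#' @param k Overlap count (vectorised), `0 <= k <= n_haps`.
#' @param n_haps Number of query haplotypes (default 8).
#' @return Expected bases at each `k`.
#' @export
expected_overlap_binomial <- function(f, s_callable, k, n_haps = 8) {
  check_scalar(f, "f", min = 0, max = 1)
  check_scalar(s_callable, "s_callable", min = 0, strict_min = TRUE)
  abort_if(any(k < 0 | k > n_haps), "k out of range")
  choose(n_haps, k) * f^k * (1 - f)^(n_haps - k) * s_callable
}

#' Log2 observed/expected overrepresentation score
#'
#' @param observed,expected Positive base counts.
#' @return `log2(observed / expected)`; display convention is one decimal.
#' @export
m_value <- function(observed, expected) {
  abort_if(any(observed <= 0) || any(expected <= 0),
           "observed and expected must be positive")
  log2(observed / expected)
}

#' Callable-genome mask from windowed F_ST
#'
#' Windows where the parent species are differentiated enough to assign
#' ancestry: inter-species F_ST strictly above `threshold`. Windows with
#' missing F_ST are non-callable (counted in attribute `"n_missing"`).
#'
#' @param fst_windows Tibble with `chrom`, `start`, `end`, `fst` (see
#'   [diversity_windows()]).
#' @param threshold F_ST cutoff (default 0.15).
#' @return Interval tibble of callable windows (adjacent windows merged).
#' @export
callable_mask <- function(fst_windows, threshold = 0.15) {
  n_missing <- sum(is.na(fst_windows$fst))
  keep <- fst_windows %>%
    filter(!is.na(.data$fst), .data$fst > threshold) %>%
    select("chrom", "start", "end")
  out <- if (nrow(keep) > 0) {
    merge_intervals(keep, max_gap = 1) %>% select("chrom", "start", "end")
  } else keep
  attr(out, "n_missing") <- n_missing
  out
}

#' @rdname callable_mask
#' @return `callable_genome_size()`: total callable bases.
#' @export
callable_genome_size <- function(fst_windows, threshold = 0.15) {
  interval_size(callable_mask(fst_windows, threshold))
}

#' Observed versus expected recurrence, per overlap count
#'
#' Restricts the recurrence track to the callable mask, tabulates observed
#' bases at each overlap count k, and compares with the binomial null (using
#' the highest per-haplotype fraction) via M-values. At `k = n` the
#' product-form expectation over the individual fractions is also reported.
#'
#' @param track Recurrence track from [overlap_track()].
#' @param fractions Output of [haplotype_fractions()] (carries the callable
#'   size as an attribute).
#' @param callable Callable interval tibble (same mask used for
#'   `fractions`), or `NULL` for whole chromosomes.
#' @param n_haps Number of query haplotypes.
#' @return Tibble with `origin`, `k`, `observed_bases`, `expected_bases`,
#'   `m` (`NA` where a side is zero); attribute `"expected_full"` holds the
#'   product-form n_k = n expectation per origin.
#' @export
overlap_summary <- function(track, fractions, callable = NULL, n_haps = 8) {
  s_callable <- attr(fractions, "s_callable")
  abort_if(is.null(s_callable), "`fractions` must come from haplotype_fractions()")
  origins <- sort(unique(track$origin))
  rows <- list()
  full <- list()
  for (or in origins) {
    f_or <- filter(fractions, .data$origin == or)
    f_max <- max(f_or$f)
    obs <- vapply(0:n_haps, function(k) {
      seg <- filter(track, .data$origin == or, .data$count == k) %>%
        select("chrom", "start", "end")
      if (nrow(seg) == 0) return(0)
      if (is.null(callable)) sum(seg$end - seg$start)
      else intersect_size(seg, callable)
    }, numeric(1))
    expd <- expected_overlap_binomial(f_max, s_callable, 0:n_haps, n_haps)
    rows[[or]] <- tibble(
      origin = or, k = 0:n_haps,
      observed_bases = obs, expected_bases = expd,
      m = if_else(obs > 0 & expd > 0, log2(obs / expd), NA_real_)
    )
    full[[or]] <- expected_full_overlap(f_or$f, s_callable)
  }
  out <- bind_rows(rows)
  attr(out, "expected_full") <- unlist(full)
  attr(out, "s_callable") <- s_callable
  out
}
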