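#' High-F_ST enrichment of recurrent HSR bins
#'
#' Bins the diversity windows by the number of same-origin HSR haplotypes
#' covering their midpoint, then asks whether high-F_ST windows (window
#' average above `high_fst`, by construction a small top slice of the
#' genome) are overrepresented in the high-recurrence bins: per bin an
#' M-value against the genome-wide high-F_ST fraction and an exact binomial
#' tail p-value (trials = windows in the bin, success probability =
#' genome-wide fraction).
#'
#' @param track Recurrence track from [overlap_track()].
#' @param fst_windows Windowed F_ST tibble (see [diversity_windows()]);
#'   windows with missing F_ST are ignored.
#' @param high_fst High-differentiation cutoff (default 0.6).
#' @return Tibble with `origin`, `k`, `n_windows`, `n_high`, `frac_high`,
#'   `m`, `p_binomial`; the genome-wide high fraction is attached as
#'   attribute `"genome_frac"`.
#' @export
hsr_fst_enrichment <- function(track, fst_windows, high_fst = 0.6) {
  fw <- filter(fst_windows, !is.na(.data$fst))
  abort_if(nrow(fw) == 0, "no windows with defined F_ST")
  genome_frac <- mean(fw$fst > high_fst)
  rows <- list()
  for (or in sort(unique(track$origin))) {
    tr <- track %>%
      filter(.data$origin == or) %>%
      arrange(.data$chrom, .data$start)
    k_at <- integer(nrow(fw))
    for (cn in unique(fw$chrom)) {
      widx <- which(fw$chrom == cn)
      seg <- tr[tr$chrom == cn, ]
      if (nrow(seg) == 0) { k_at[widx] <- 0L; next }
      mid <- (fw$start[widx] + fw$end[widx]) / 2
      si <- findInterval(mid, seg$start)
      k_at[widx] <- if_else(si >= 1 & mid < seg$end[pmax(si, 1)],
                            as.integer(seg$count[pmax(si, 1)]), 0L)
    }
    rows[[or]] <- tibble(origin = or, k = k_at, high = fw$fst > high_fst) %>%
      group_by(.data$origin, .data$k) %>%
      summarise(n_windows = n(), n_high = sum(.data$high),
                .groups = "drop") %>%
      mutate(
        frac_high = .data$n_high / .data$n_windows,
        m = if_else(.data$frac_high > 0 & genome_frac > 0,
                    log2(.data$frac_high / genome_frac), NA_real_),
        p_binomial = pbinom(.data$n_high - 1, .data$n_windows, genome_frac,
                            lower.tail = FALSE)
      )
  }
  out <- bind_rows(rows)
  attr(out, "genome_frac") <- genome_frac
  out
}

#' Exon density of a region set
#'
#' Fraction of region bases covered by exons; exons extending past a region
#' boundary are clipped to it, so the value is an exact base fraction.
#'
#' @param regions Interval tibble (`chrom`, `start`, `end`); must be
#'   non-empty.
#' @param exons Exon interval tibble (overlaps are unioned internally).
#' @return Covered fraction in `[0, 1]`.
#' @export
exon_density <- function(regions, exons) {
  abort_if(nrow(regions) == 0, "`regions` is empty")
  denom <- interval_size(regions)
  intersect_size(regions, exons) / denom
}

#' Recombination-rate contrast between regions and background
#'
#' Length-weighted mean map rate (cM/Mb) inside the regions and inside the
#' background set, plus a two-sided Welch t-test over the rates of the map
#' windows each set touches.
#'
#' @param regions,background Interval tibbles.
#' @param map Recombination map tibble (`chrom`, `start`, `end`,
#'   `rate_cM_per_Mb`); must cover the regions.
#' @return One-row tibble: `mean_regions`, `mean_background`, `n_regions`,
#'   `n_background` (map windows touched), `t_stat`, `p_value`.
#' @export
rate_contrast <- function(regions, map, background) {
  w_reg <- map_window_overlaps(regions, map)
  w_bg <- map_window_overlaps(background, map)
  abort_if(nrow(w_reg) == 0, "regions do not overlap the map")
  abort_if(nrow(w_bg) == 0, "background does not overlap the map")
  wm <- function(d) sum(d$rate_cM_per_Mb * d$overlap) / sum(d$overlap)
  tt <- if (nrow(w_reg) > 1 && nrow(w_bg) > 1) {
    # constant rates (e.g. a uniform map) leave the contrast undefined
    tryCatch(t.test(w_reg$rate_cM_per_Mb, w_bg$rate_cM_per_Mb),
             error = function(e) NULL)
  } else NULL
  tibble(
    mean_regions = wm(w_reg),
    mean_background = wm(w_bg),
    n_regions = nrow(w_reg),
    n_background = nrow(w_bg),
    t_stat = if (is.null(tt)) NA_real_ else unname(tt$statistic),
    p_value = if (is.null(tt)) NA_real_ else tt$p.value
  )
}

# map windows with their overlap (bp) against an interval set
map_window_overlaps <- function(regions, map) {
  rm_ <- merge_intervals(select(as_tibble(regions), "chrom", "start", "end"),
                         0)
  out <- list()
  for (cn in unique(rm_$chrom)) {
    mw <- map[map$chrom == cn, ]
    rg <- rm_[rm_$chrom == cn, ]
    if (nrow(mw) == 0) {
      abort_if(nrow(rg) > 0, sprintf("region outside map coverage: %s", cn))
      next
    }
    ov <- vapply(seq_len(nrow(mw)), function(i) {
      sum(pmax(0, pmin(mw$end[i], rg$end) - pmax(mw$start[i], rg$start)))
    }, numeric(1))
    keep <- ov > 0
    out[[cn]] <- mutate(mw[keep, ], overlap = ov[keep])
  }
  bind_rows(out)
}

#' Mean per-SNP allele-frequency distance between pools
#'
#' For pooled population samples sharing a SNP set, the pairwise distance is
#' the mean absolute allele-frequency difference per SNP.
#'
#' @param freq Data frame of per-pool allele frequencies over shared SNPs:
#'   numeric columns are pools (any non-numeric columns, e.g. SNP ids, are
#'   ignored). Missing frequencies are an error.
#' @return Symmetric distance matrix with pool names as dimnames.
#' @export
pool_frequency_distance <- function(freq) {
  freq <- as_tibble(freq)
  num <- freq[vapply(freq, is.numeric, logical(1))]
  abort_if(ncol(num) < 2, "need at least two pools")
  abort_if(anyNA(num), "missing allele frequencies")
  m <- as.matrix(num)
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- mean(abs(m[, i] - m[, j]))
    }
  }
  d
}
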