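#' Windowed nucleotide diversity (pi)
#'
#' Average pairwise difference per accessible site within a group:
#' per window, the sum over sites of `k(n-k) / choose(n, 2)` divided by the
#' accessible bases, so monomorphic accessible sites dilute the estimate as
#' they should.
#'
#' @param panel A [phased_panel()].
#' @param group Panel group to use (needs >= 2 haplotypes).
#' @param windows Window tibble from [build_windows()].
#' @param accessible_bases Accessible bases per window: a single number, a
#'   vector matching `windows`, or `NULL` for the full window width.
#' @return `windows` with columns `n_sites` and `pi`.
#' @export
windowed_pi <- function(panel, group, windows, accessible_bases = NULL) {
  m <- panel_matrix(panel, group)
  abort_if(nrow(m) < 2, "pi needs at least 2 haplotypes in the group")
  acc <- resolve_accessible(windows, accessible_bases)
  per_site <- function(k, n) k * (n - k) / (n * (n - 1) / 2)
  agg <- window_site_sums(panel, windows,
                          per_site(colSums(m), nrow(m)))
  windows %>%
    mutate(n_sites = agg$n_sites, pi = agg$sum / acc)
}

#' Windowed between-group divergence (d_xy)
#'
#' Average cross-group pairwise difference per accessible site.
#'
#' @param panel A [phased_panel()].
#' @param group_a,group_b The two panel groups.
#' @inheritParams windowed_pi
#' @return `windows` with columns `n_sites` and `dxy`.
#' @export
windowed_dxy <- function(panel, group_a, group_b, windows,
                         accessible_bases = NULL) {
  ma <- panel_matrix(panel, group_a)
  mb <- panel_matrix(panel, group_b)
  acc <- resolve_accessible(windows, accessible_bases)
  ka <- colSums(ma); kb <- colSums(mb)
  na <- nrow(ma); nb <- nrow(mb)
  per_site <- (ka * (nb - kb) + kb * (na - ka)) / (na * nb)
  agg <- window_site_sums(panel, windows, per_site)
  windows %>%
    mutate(n_sites = agg$n_sites, dxy = agg$sum / acc)
}

#' Windowed Hudson F_ST (ratio of sums)
#'
#' Per site, numerator `(p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and
#' denominator `p1(1-p2) + p2(1-p1)`; the window estimate is the ratio of
#' the two sums over the window's sites. Windows with no usable site (or
#' zero denominator) get `NA`. Small negative estimates are legitimate for
#' this unbiased estimator and are not clamped.
#'
#' @param panel A [phased_panel()].
#' @param group_a,group_b The two panel groups (>= 2 haplotypes each).
#' @param windows Window tibble from [build_windows()].
#' @param maf Pooled minor-allele-frequency filter applied before the sums
#'   (default 0.05; set 0 to disable).
#' @return `windows` with columns `n_sites` and `fst`.
#' @export
windowed_fst <- function(panel, group_a, group_b, windows, maf = 0.05) {
  ma <- panel_matrix(panel, group_a)
  mb <- panel_matrix(panel, group_b)
  abort_if(nrow(ma) < 2 || nrow(mb) < 2,
           "Hudson F_ST needs >= 2 haplotypes per group")
  n1 <- nrow(ma); n2 <- nrow(mb)
  p1 <- colSums(ma) / n1
  p2 <- colSums(mb) / n2
  pooled <- (colSums(ma) + colSums(mb)) / (n1 + n2)
  use <- pooled >= maf & pooled <= 1 - maf
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  num[!use] <- 0; den[!use] <- 0
  agg_n <- window_site_sums(panel, windows, num)
  agg_d <- window_site_sums(panel, windows, den)
  used <- window_site_sums(panel, windows, as.numeric(use))
  windows %>%
    mutate(
      n_sites = as.integer(used$sum),
      fst = if_else(agg_d$sum > 0, agg_n$sum / agg_d$sum, NA_real_)
    )
}

# sum an arbitrary per-site quantity within each window
window_site_sums <- function(panel, windows, per_site) {
  sums <- numeric(nrow(windows))
  n_sites <- integer(nrow(windows))
  for (cn in unique(windows$chrom)) {
    widx <- which(windows$chrom == cn)
    sidx <- which(panel$sites$chrom == cn)
    if (length(sidx) == 0) next
    pos <- panel$sites$pos[sidx]
    bin <- findInterval(pos, windows$start[widx])
    ok <- bin >= 1 & pos < windows$end[widx][pmax(bin, 1)]
    t_sum <- tapply(per_site[sidx][ok], bin[ok], sum)
    t_n <- tapply(rep(1L, sum(ok)), bin[ok], sum)
    at <- as.integer(names(t_sum))
    sums[widx[at]] <- as.numeric(t_sum)
    n_sites[widx[at]] <- as.integer(t_n)
  }
  list(sum = sums, n_sites = n_sites)
}

resolve_accessible <- function(windows, accessible_bases) {
  if (is.null(accessible_bases)) return(windows$end - windows$start)
  abort_if(any(accessible_bases <= 0), "accessible bases must be positive")
  if (length(accessible_bases) == 1) {
    rep(accessible_bases, nrow(windows))
  } else {
    abort_if(length(accessible_bases) != nrow(windows),
             "accessible_bases must match the number of windows")
    accessible_bases
  }
}

#' All windowed diversity statistics between the two reference panels
#'
#' Convenience wrapper computing per-window pi (both groups), d_xy and
#' Hudson F_ST in non-overlapping windows (default 5 kb).
#'
#' @param panel A [phased_panel()] with `ref_A` and `ref_B` groups.
#' @param window_size_bp Window size (default 5000).
#' @param maf MAF filter for F_ST only (pi / d_xy denominators are never
#'   filtered).
#' @param accessible_bases See [windowed_pi()].
#' @return Tibble with `chrom`, `start`, `end`, `n_sites`, `pi_ref_A`,
#'   `pi_ref_B`, `dxy`, `fst`.
#' @export
diversity_windows <- function(panel, window_size_bp = 5000, maf = 0.05,
                              accessible_bases = NULL) {
  windows <- build_windows(panel, window_size_bp)
  pa <- windowed_pi(panel, "ref_A", windows, accessible_bases)
  pb <- windowed_pi(panel, "ref_B", windows, accessible_bases)
  dx <- windowed_dxy(panel, "ref_A", "ref_B", windows, accessible_bases)
  fs <- windowed_fst(panel, "ref_A", "ref_B", windows, maf)
  windows %>%
    mutate(n_sites = dx$n_sites, pi_ref_A = pa$pi, pi_ref_B = pb$pi,
           dxy = dx$dxy, fst = fs$fst)
}
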