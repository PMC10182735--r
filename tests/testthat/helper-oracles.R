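# Brute-force reference implementations and tiny fixture builders.
# These stay deliberately naive (explicit loops, per-base counting) so they
# are independent of the package's vectorised code paths.

bf_min_hamming <- function(hap, panel) {
  best <- Inf
  for (i in seq_len(nrow(panel))) {
    d <- 0
    for (j in seq_along(hap)) if (panel[i, j] != hap[j]) d <- d + 1
    if (d < best) best <- d
  }
  as.integer(best)
}

# iterative pairwise merging until no pair qualifies
bf_merge <- function(iv, max_gap) {
  iv <- iv[order(iv$start, iv$end), , drop = FALSE]
  repeat {
    merged <- FALSE
    i <- 1
    while (i < nrow(iv)) {
      gap <- iv$start[i + 1] - iv$end[i]
      if (gap < max_gap || iv$start[i + 1] < iv$end[i]) {
        iv$end[i] <- max(iv$end[i], iv$end[i + 1])
        iv <- iv[-(i + 1), , drop = FALSE]
        merged <- TRUE
      } else {
        i <- i + 1
      }
    }
    if (!merged) break
  }
  iv
}

# per-base coverage counting on a small chromosome
bf_coverage_counts <- function(iv, L) {
  cov <- integer(L)
  for (i in seq_len(nrow(iv))) {
    idx <- seq(iv$start[i] + 1, iv$end[i])
    cov[idx] <- cov[idx] + 1L
  }
  cov
}

bf_pi <- function(m, accessible) {
  n <- nrow(m)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) tot <- tot + sum(m[i, ] != m[j, ])
  }
  tot / (n * (n - 1) / 2) / accessible
}

bf_dxy <- function(ma, mb, accessible) {
  tot <- 0
  for (i in seq_len(nrow(ma))) {
    for (j in seq_len(nrow(mb))) tot <- tot + sum(ma[i, ] != mb[j, ])
  }
  tot / (nrow(ma) * nrow(mb)) / accessible
}

bf_hudson_fst <- function(ma, mb, maf = 0) {
  n1 <- nrow(ma); n2 <- nrow(mb)
  num <- den <- 0
  for (s in seq_len(ncol(ma))) {
    p1 <- sum(ma[, s]) / n1
    p2 <- sum(mb[, s]) / n2
    pooled <- (sum(ma[, s]) + sum(mb[, s])) / (n1 + n2)
    if (pooled < maf || pooled > 1 - maf) next
    num <- num + (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) -
      p2 * (1 - p2) / (n2 - 1)
    den <- den + p1 * (1 - p2) + p2 * (1 - p1)
  }
  if (den > 0) num / den else NA_real_
}

bf_exon_density <- function(regions, exons, L) {
  in_region <- logical(L)
  in_exon <- logical(L)
  for (i in seq_len(nrow(regions))) {
    in_region[seq(regions$start[i] + 1, regions$end[i])] <- TRUE
  }
  for (i in seq_len(nrow(exons))) {
    in_exon[seq(exons$start[i] + 1, exons$end[i])] <- TRUE
  }
  sum(in_region & in_exon) / sum(in_region)
}

# a panel built directly from a 0/1 matrix; positions default to 1 bp apart
toy_panel <- function(geno, groups, pos = NULL, chrom_len = NULL,
                      chrom = "chr1") {
  geno <- as.matrix(geno)
  if (is.null(pos)) pos <- seq_len(ncol(geno)) - 1L
  n <- nrow(geno)
  haps <- tibble::tibble(
    hap_id = sprintf("h%02d", seq_len(n)),
    sample = sprintf("s%02d", ceiling(seq_len(n) / 2)),
    phase = 2L - (seq_len(n) %% 2L),
    group = groups
  )
  cl <- stats::setNames(chrom_len %||% (max(pos) + 1), chrom)
  phased_panel(geno, tibble::tibble(chrom = chrom, pos = as.integer(pos),
                                    ref = "A", alt = "C"),
               haps, chrom_lengths = cl)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

random_intervals <- function(n, L, max_len = L / 4) {
  start <- floor(runif(n, 0, L - 1))
  len <- pmax(1, floor(runif(n, 1, max_len)))
  tibble::tibble(chrom = "chr1", start = start,
                 end = pmin(L, start + len))
}

uniform_test_map <- function(L = 1e7, total_cM = 20, res = 1e5) {
  starts <- seq(0, L - 1, by = res)
  tibble::tibble(chrom = "chr1", start = starts, end = pmin(starts + res, L),
                 rate_cM_per_Mb = total_cM / (L / 1e6))
}
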