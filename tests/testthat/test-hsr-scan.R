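test_that("windows tile from zero, keep the trailing partial, and are half-open", {
  w <- build_windows(c(chr1 = 45000), 20000)
  expect_equal(w$start, c(0, 20000, 40000))
  expect_equal(w$end, c(20000, 40000, 45000))

  # a site at exactly 20000 belongs to the second window
  geno <- rbind(q = c(0, 1), a = c(1, 1), a2 = c(1, 1),
                b = c(0, 0), b2 = c(0, 0))
  p <- toy_panel(geno, c("query", "ref_A", "ref_A", "ref_B", "ref_B"),
                 pos = c(19999, 20000), chrom_len = 45000)
  sc <- score_windows(panel_subset(p, "query"), panel_subset(p, "ref_A"),
                      panel_subset(p, "ref_B"))
  expect_equal(sc$n_sites, c(1L, 1L, 0L))
})

test_that("minimum Hamming distance matches identity, direct count and brute force", {
  panel <- matrix(c(0, 1, 0, 1), nrow = 1)
  expect_equal(min_hamming(c(0, 1, 0, 1), panel), 0L)

  set.seed(2)
  hap100 <- rbinom(100, 1, 0.5)
  other <- hap100
  other[c(3, 50, 97)] <- 1 - other[c(3, 50, 97)]
  expect_equal(min_hamming(hap100, matrix(other, nrow = 1)), 3L)

  for (rep in 1:200) {
    s <- sample(3:40, 1)
    hap <- rbinom(s, 1, 0.5)
    pn <- matrix(rbinom(20 * s, 1, runif(1, 0.2, 0.8)), nrow = 20)
    expect_equal(min_hamming(hap, pn), bf_min_hamming(hap, pn))
  }
  expect_error(min_hamming(c(0, 1), matrix(0, 2, 3)), "site counts")
  expect_error(min_hamming(c(0, 1), matrix(numeric(0), 0, 2)), "empty")
})

test_that("window scores apply the low-diversity filter and ratio conventions", {
  # one 100-site window; construct exact distances d_A = 5, d_B = 12
  set.seed(9)
  q <- rbinom(100, 1, 0.5)
  a1 <- q; a1[1:5] <- 1 - a1[1:5]
  b1 <- q; b1[1:12] <- 1 - b1[1:12]
  p <- toy_panel(rbind(q, a1, a1, b1, b1),
                 c("query", "ref_A", "ref_A", "ref_B", "ref_B"),
                 chrom_len = 20000)
  sc <- score_windows(panel_subset(p, "query"), panel_subset(p, "ref_A"),
                      panel_subset(p, "ref_B"))
  expect_equal(sc$d_a, 5L)
  expect_equal(sc$d_b, 12L)
  expect_true(sc$filtered)            # max(5, 12) < 20

  # d_A = d_B = 50: ratio exactly 1, unfiltered
  a2 <- q; a2[1:50] <- 1 - a2[1:50]
  b2 <- q; b2[51:100] <- 1 - b2[51:100]
  p2 <- toy_panel(rbind(q, a2, a2, b2, b2),
                  c("query", "ref_A", "ref_A", "ref_B", "ref_B"),
                  chrom_len = 20000)
  sc2 <- score_windows(panel_subset(p2, "query"), panel_subset(p2, "ref_A"),
                       panel_subset(p2, "ref_B"))
  expect_equal(sc2$ratio, 1)
  expect_false(sc2$filtered)

  # query identical to a ref_A member with divergent panels: ratio 0
  p3 <- toy_panel(rbind(q, q, a2, b2, b2),
                  c("query", "ref_A", "ref_A", "ref_B", "ref_B"),
                  chrom_len = 20000)
  sc3 <- score_windows(panel_subset(p3, "query"), panel_subset(p3, "ref_A"),
                       panel_subset(p3, "ref_B"))
  expect_equal(sc3$d_a, 0L)
  expect_equal(sc3$ratio, 0)
  # and the mirrored case gives an infinite ratio (d_B = 0)
  p4 <- toy_panel(rbind(q, a2, a2, q, b2),
                  c("query", "ref_A", "ref_A", "ref_B", "ref_B"),
                  chrom_len = 20000)
  sc4 <- score_windows(panel_subset(p4, "query"), panel_subset(p4, "ref_A"),
                       panel_subset(p4, "ref_B"))
  expect_equal(sc4$ratio, Inf)
})

test_that("the genome-wide mean ratio is the mean of per-haplotype ratios", {
  mk <- function(d_a, d_b, hap) {
    tibble::tibble(hap_id = hap, chrom = "chr1",
                   start = seq(0, by = 20000, length.out = length(d_a)),
                   end = start + 20000, n_sites = 100L,
                   d_a = d_a, d_b = d_b, ratio = d_a / d_b,
                   filtered = FALSE)
  }
  # every window d_A = 29, d_B = 20 for every haplotype: mean ratio 1.45
  sc <- dplyr::bind_rows(lapply(sprintf("h%d", 1:8), function(h) {
    mk(rep(29, 50), rep(20, 50), h)
  }))
  expect_equal(genomewide_mean_ratio(sc), 1.45)

  # d_A == d_B everywhere: exactly 1
  sc1 <- mk(rep(7, 10), rep(7, 10), "h1")
  expect_equal(genomewide_mean_ratio(sc1), 1)

  # two haplotypes with per-haplotype ratios 1.2 and 1.8: mean 1.5
  sc2 <- dplyr::bind_rows(mk(rep(12, 5), rep(10, 5), "h1"),
                          mk(rep(18, 5), rep(10, 5), "h2"))
  expect_equal(genomewide_mean_ratio(sc2), 1.5)

  # a haplotype with zero unfiltered windows is an error
  sc3 <- dplyr::bind_rows(sc1, dplyr::mutate(mk(rep(3, 4), rep(3, 4), "h2"),
                                             filtered = TRUE))
  expect_error(genomewide_mean_ratio(sc3), "h2")
})

test_that("call thresholds and boundary handling follow the 8-fold rule", {
  thr <- hsr_thresholds(1.45, 8)
  expect_equal(unname(thr["high"]), 11.6)
  expect_equal(unname(thr["low"]), 0.18125)
  expect_equal(round(unname(thr["high"])), 12)
  expect_equal(round(unname(thr["low"]), 2), 0.18)

  base <- tibble::tibble(
    hap_id = "h1", chrom = "chr1",
    start = c(0, 20000, 40000, 60000, 80000),
    end = start + 20000, n_sites = 100L,
    d_a = c(29, 232, 29, 2, 29),
    d_b = c(20, 20, 20, 160, 20),
    filtered = FALSE
  )
  base$ratio <- base$d_a / base$d_b
  # per-window ratios: 1.45, 11.6, 1.45, 0.0125, 1.45 with mean ratio 1.45
  calls <- call_hsrs(base, mean_ratio = 1.45)
  # window at exactly the mean ratio: never called; equality at the
  # threshold (11.6 = 1.45 * 8) IS called, as is the deep-A window
  expect_equal(sort(calls$origin), c("A", "B"))
  expect_equal(calls$start[calls$origin == "B"], 20000)
  expect_equal(calls$start[calls$origin == "A"], 60000)

  # adjacent same-origin windows concatenate, <50 kb gaps merge
  two <- base
  two$d_a <- c(2, 2, 29, 2, 29)
  two$d_b <- c(160, 160, 20, 160, 20)
  two$ratio <- two$d_a / two$d_b
  calls2 <- call_hsrs(two, mean_ratio = 1.45)
  expect_equal(nrow(calls2), 1L)      # windows 1,2 adjacent; window 4 is
  expect_equal(calls2$start, 0)       # 20 kb away: all one region
  expect_equal(calls2$end, 80000)
  expect_equal(calls2$n_windows, 3L)
  expect_equal(calls2$size_bp, 80000)
})

test_that("swapping the reference panels inverts ratios and exchanges labels", {
  cfg <- sim_config(chrom_length_bp = 2e6, seed = 23)
  ds <- simulate_hybrid_dataset(cfg)
  q <- panel_subset(ds$panel, "query")
  a <- panel_subset(ds$panel, "ref_A")
  b <- panel_subset(ds$panel, "ref_B")
  sc <- score_windows(q, a, b)
  sw <- score_windows(q, b, a)
  expect_equal(sw$d_a, sc$d_b)
  expect_equal(sw$ratio, 1 / sc$ratio)
  expect_equal(sw$filtered, sc$filtered)
  r <- genomewide_mean_ratio(sc)
  calls <- call_hsrs(sc, r)
  calls_sw <- call_hsrs(sw, 1 / r)
  flip <- dplyr::mutate(calls_sw, origin = ifelse(origin == "A", "B", "A"))
  expect_equal(dplyr::arrange(calls, hap_id, chrom, start, origin),
               dplyr::arrange(flip, hap_id, chrom, start, origin))
})

test_that("calls of either origin never overlap within a haplotype", {
  cfg <- sim_config(chrom_length_bp = 4e6, seed = 29)
  ds <- simulate_hybrid_dataset(cfg)
  scan <- hsr_scan(ds$panel)
  for (h in unique(scan$calls$hap_id)) {
    cl <- dplyr::arrange(scan$calls[scan$calls$hap_id == h, ], start)
    if (nrow(cl) > 1) {
      expect_true(all(cl$start[-1] >= cl$end[-nrow(cl)]))
    }
  }
})

test_that("pairwise Hamming matrices match brute force and normalise to 1", {
  p <- toy_panel(rbind(c(0, 0, 0, 0), c(0, 0, 0, 0), c(1, 1, 0, 0)),
                 c("query", "ref_A", "ref_B"))
  d0 <- pairwise_hamming_matrix(toy_panel(rbind(c(0, 1), c(0, 1)),
                                          c("query", "query")),
                                "chr1", 0, 2)
  expect_true(all(d0 == 0))

  set.seed(5)
  g <- matrix(rbinom(3 * 30, 1, 0.5), nrow = 3)
  pp <- toy_panel(g, rep("query", 3))
  d <- pairwise_hamming_matrix(pp, "chr1", 0, 30)
  for (i in 1:3) for (j in 1:3) {
    expect_equal(unname(d[i, j]), sum(g[i, ] != g[j, ]))
  }
  dn <- pairwise_hamming_matrix(pp, "chr1", 0, 30, normalize = TRUE)
  expect_equal(max(dn), 1)
  expect_error(pairwise_hamming_matrix(pp, "chr1", 500, 600), "no sites")
})
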