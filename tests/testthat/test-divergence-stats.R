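test_that("windowed pi matches hand arithmetic and brute force", {
  # identical haplotypes: zero diversity
  g0 <- matrix(0L, 4, 10)
  p0 <- toy_panel(g0, rep("ref_A", 4), chrom_len = 1000)
  w <- build_windows(c(chr1 = 1000), 1000)
  expect_equal(windowed_pi(p0, "ref_A", w)$pi, 0)

  # 2 haplotypes, 1 difference, 1000 accessible bases: 0.001
  g1 <- rbind(rep(0L, 5), c(1L, rep(0L, 4)))
  p1 <- toy_panel(g1, rep("ref_A", 2), chrom_len = 1000)
  expect_equal(windowed_pi(p1, "ref_A", w)$pi, 0.001)
  expect_error(windowed_pi(toy_panel(matrix(0L, 1, 3), "ref_A"), "ref_A", w),
               "2 haplotypes")

  set.seed(41)
  for (rep in 1:100) {
    n <- sample(3:8, 1); s <- sample(5:30, 1)
    g <- matrix(rbinom(n * s, 1, runif(1, 0.1, 0.9)), nrow = n)
    p <- toy_panel(g, rep("ref_A", n), chrom_len = 500)
    w1 <- build_windows(c(chr1 = 500), 500)
    expect_equal(windowed_pi(p, "ref_A", w1)$pi, bf_pi(g, 500))
  }
})

test_that("windowed d_xy matches hand arithmetic, symmetry and brute force", {
  w <- build_windows(c(chr1 = 1000), 1000)
  # one fixed difference out of 1000 accessible bases: 0.001
  g <- rbind(rep(0L, 3), rep(0L, 3), c(1L, 0L, 0L), c(1L, 0L, 0L))
  p <- toy_panel(g, c("ref_A", "ref_A", "ref_B", "ref_B"), chrom_len = 1000)
  expect_equal(windowed_dxy(p, "ref_A", "ref_B", w)$dxy, 0.001)
  expect_equal(windowed_dxy(p, "ref_B", "ref_A", w)$dxy,
               windowed_dxy(p, "ref_A", "ref_B", w)$dxy)

  set.seed(43)
  for (rep in 1:100) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1); s <- sample(5:30, 1)
    ga <- matrix(rbinom(na * s, 1, 0.4), nrow = na)
    gb <- matrix(rbinom(nb * s, 1, 0.6), nrow = nb)
    p2 <- toy_panel(rbind(ga, gb), c(rep("ref_A", na), rep("ref_B", nb)),
                    chrom_len = 300)
    w1 <- build_windows(c(chr1 = 300), 300)
    expect_equal(windowed_dxy(p2, "ref_A", "ref_B", w1)$dxy,
                 bf_dxy(ga, gb, 300))
  }
})

test_that("Hudson F_ST handles fixation, no differentiation, and hand values", {
  w <- build_windows(c(chr1 = 100), 100)
  # fully fixed difference: exactly 1 regardless of sample sizes >= 2
  for (n in c(2, 4, 16)) {
    g <- rbind(matrix(1L, n, 2), matrix(0L, n, 2))
    p <- toy_panel(g, c(rep("ref_A", n), rep("ref_B", n)), chrom_len = 100)
    expect_equal(windowed_fst(p, "ref_A", "ref_B", w)$fst, 1)
  }

  # p1 = p2 at every site: near zero (unbiased, can be slightly negative)
  set.seed(47)
  g <- matrix(rbinom(32 * 400, 1, 0.5), nrow = 32)
  p <- toy_panel(g, rep(c("ref_A", "ref_B"), each = 16), chrom_len = 400)
  w4 <- build_windows(c(chr1 = 400), 400)
  expect_lt(abs(windowed_fst(p, "ref_A", "ref_B", w4)$fst), 0.05)

  # single site, p1 = 0.2, p2 = 0.8, n1 = n2 = 5:
  # num = 0.36 - 0.16/4 - 0.16/4 = 0.28; den = 0.68
  g5 <- rbind(matrix(c(1L, 0L, 0L, 0L, 0L), 5, 1),
              matrix(c(1L, 1L, 1L, 1L, 0L), 5, 1))
  p5 <- toy_panel(g5, rep(c("ref_A", "ref_B"), each = 5), chrom_len = 100)
  expect_equal(windowed_fst(p5, "ref_A", "ref_B", w, maf = 0)$fst,
               0.28 / 0.68)

  # monomorphic window: undefined
  gm <- matrix(0L, 8, 1)
  pm <- toy_panel(gm, rep(c("ref_A", "ref_B"), each = 4), chrom_len = 100)
  expect_true(is.na(windowed_fst(pm, "ref_A", "ref_B", w)$fst))

  # the pooled MAF filter removes rare sites from the sums
  gr <- cbind(rbind(matrix(1L, 4, 1), matrix(0L, 4, 1)),   # fixed diff
              c(1L, rep(0L, 7)))                            # pooled maf 1/8
  pr <- toy_panel(gr, rep(c("ref_A", "ref_B"), each = 4), chrom_len = 100)
  with_filter <- windowed_fst(pr, "ref_A", "ref_B", w, maf = 0.2)$fst
  expect_equal(with_filter, 1)   # only the fixed site remains

  set.seed(53)
  for (rep in 1:100) {
    na <- sample(2:8, 1); nb <- sample(2:8, 1); s <- sample(5:30, 1)
    g <- rbind(matrix(rbinom(na * s, 1, 0.3), nrow = na),
               matrix(rbinom(nb * s, 1, 0.7), nrow = nb))
    p <- toy_panel(g, c(rep("ref_A", na), rep("ref_B", nb)), chrom_len = 200)
    wr <- build_windows(c(chr1 = 200), 200)
    got <- windowed_fst(p, "ref_A", "ref_B", wr, maf = 0.05)$fst
    ref <- bf_hudson_fst(g[1:na, , drop = FALSE],
                         g[-(1:na), , drop = FALSE], maf = 0.05)
    expect_equal(got, ref)
  }
})

test_that("high-F_ST enrichment per recurrence bin matches hand-computed tails", {
  # 40 windows of 5 kb; 10 fall in a k=1 region; genome-wide high fraction
  # is 0.1 (4 high windows), 3 of them inside the region
  fst <- rep(0.2, 40)
  fst[c(1, 2, 3, 15)] <- 0.9
  fw <- tibble::tibble(chrom = "chr1", start = seq(0, by = 5000,
                                                   length.out = 40),
                       end = start + 5000, fst = fst)
  track <- tibble::tibble(origin = "A", chrom = "chr1",
                          start = c(0, 50000), end = c(50000, 200000),
                          count = c(1L, 0L))
  enr <- hsr_fst_enrichment(track, fw, high_fst = 0.6)
  k1 <- enr[enr$k == 1, ]
  expect_equal(k1$n_windows, 10L)
  expect_equal(k1$n_high, 3L)
  expect_equal(k1$frac_high, 0.3)
  expect_equal(k1$m, log2(0.3 / 0.1))
  # exact binomial tail: sum_{j>=3} C(10,j) 0.1^j 0.9^(10-j)
  tail_p <- sum(sapply(3:10, function(j) {
    choose(10, j) * 0.1^j * 0.9^(10 - j)
  }))
  expect_equal(k1$p_binomial, tail_p)

  # a bin matching the genome fraction is unremarkable
  fst2 <- rep(c(0.9, rep(0.2, 9)), 4)
  fw2 <- dplyr::mutate(fw, fst = fst2)
  enr2 <- hsr_fst_enrichment(track, fw2, high_fst = 0.6)
  expect_equal(enr2$m[enr2$k == 1], 0)
  expect_gte(enr2$p_binomial[enr2$k == 1], 0.3)

  # no high-F_ST windows anywhere: all bin fractions zero
  enr3 <- hsr_fst_enrichment(track, dplyr::mutate(fw, fst = 0.2), 0.6)
  expect_true(all(enr3$frac_high == 0))
})

test_that("enrichment p-values are calibrated under random placement", {
  # regions placed uniformly at random: the exact binomial tail should
  # reject at 0.05 no more often than ~5% (discrete tails are conservative)
  set.seed(59)
  n_w <- 400
  fw <- tibble::tibble(chrom = "chr1",
                       start = seq(0, by = 5000, length.out = n_w),
                       end = start + 5000,
                       fst = runif(n_w, 0, 1))
  L <- n_w * 5000
  rejections <- logical(200)
  for (rep in 1:200) {
    s0 <- floor(runif(1, 0, L - 250000))
    track <- tibble::tibble(origin = "A", chrom = "chr1",
                            start = c(0, s0, s0 + 250000),
                            end = c(s0, s0 + 250000, L),
                            count = c(0L, 1L, 0L))
    enr <- hsr_fst_enrichment(track, fw, high_fst = 0.6)
    rejections[rep] <- enr$p_binomial[enr$k == 1] < 0.05
  }
  expect_lt(mean(rejections), 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("exon density clips edge exons and matches per-base counting", {
  exons <- tibble::tibble(chrom = "chr1", start = c(100, 400),
                          end = c(200, 450))
  inside <- tibble::tibble(chrom = "chr1", start = 120, end = 180)
  expect_equal(exon_density(inside, exons), 1)
  away <- tibble::tibble(chrom = "chr1", start = 700, end = 900)
  expect_equal(exon_density(away, exons), 0)
  expect_error(exon_density(away[0, ], exons), "empty")

  set.seed(61)
  for (rep in 1:50) {
    L <- 1000
    regions <- merge_intervals(random_intervals(3, L, 300), 0)
    exn <- merge_intervals(random_intervals(4, L, 200), 0)
    expect_equal(exon_density(regions, exn),
                 bf_exon_density(regions, exn, L))
  }
})

test_that("recombination-rate contrasts recover means and the Welch test", {
  map <- uniform_test_map(L = 1e6, total_cM = 2, res = 1e5)
  map$rate_cM_per_Mb <- c(1, 2, 3, 1, 1, 5, 6, 7, 5, 5)
  regions <- tibble::tibble(chrom = "chr1", start = 0, end = 3e5)
  background <- tibble::tibble(chrom = "chr1", start = 5e5, end = 1e6)
  rc <- rate_contrast(regions, map, background)
  expect_equal(rc$mean_regions, 2)
  expect_equal(rc$mean_background, 5.6)
  # textbook Welch on the touched window rates
  tt <- stats::t.test(c(1, 2, 3), c(5, 6, 7, 5, 5))
  expect_equal(rc$t_stat, unname(tt$statistic))
  expect_equal(rc$p_value, tt$p.value)

  # identical region and background sets: zero difference
  rc2 <- rate_contrast(regions, map, regions)
  expect_equal(rc2$mean_regions, rc2$mean_background)

  # uniform map: all means equal
  mapu <- uniform_test_map(L = 1e6, total_cM = 2, res = 1e5)
  rc3 <- rate_contrast(regions, mapu, background)
  expect_equal(rc3$mean_regions, rc3$mean_background)
  expect_error(rate_contrast(tibble::tibble(chrom = "chr9", start = 0,
                                            end = 100), map, background),
               "map")
})

test_that("pool frequency distances are mean absolute differences per SNP", {
  freq <- tibble::tibble(snp = sprintf("s%d", 1:4),
                         p1 = c(0.1, 0.2, 0.3, 0.4),
                         p2 = c(0.1, 0.2, 0.3, 0.4),
                         p3 = c(0.6, 0.7, 0.8, 0.9))
  d <- pool_frequency_distance(freq)
  expect_equal(d["p1", "p2"], 0)
  expect_equal(d["p1", "p3"], 0.5)
  expect_true(isSymmetric(d))

  set.seed(67)
  m <- matrix(runif(5 * 20), ncol = 5,
              dimnames = list(NULL, sprintf("pool%d", 1:5)))
  d2 <- pool_frequency_distance(tibble::as_tibble(m))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(unname(d2[i, j]), mean(abs(m[, i] - m[, j])))
  }
  freq$p2[1] <- NA
  expect_error(pool_frequency_distance(freq), "missing")
})
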