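test_that("invalid generator configs are rejected with named reasons", {
  expect_error(sim_config(admix_prop = 1.5), "admix_prop")
  expect_error(sim_config(admix_prop = -0.1), "admix_prop")
  expect_error(sim_config(snp_density = 0), "snp_density")
  expect_error(sim_config(n_ref_a_haps = 0), "n_ref_a_haps")
  expect_error(sim_config(map_total_cM = 0), "map_total_cM")
  expect_error(sim_config(target_dxy = 1), "target_dxy")
})

test_that("identical seed and config give bit-identical output", {
  cfg <- sim_config(chrom_length_bp = 5e5, seed = 42)
  a <- simulate_hybrid_dataset(cfg)
  b <- simulate_hybrid_dataset(cfg)
  expect_identical(a$panel$geno, b$panel$geno)
  expect_identical(a$truth, b$truth)
  expect_identical(a$map, b$map)
  expect_identical(a$exons, b$exons)
  c <- simulate_hybrid_dataset(sim_config(chrom_length_bp = 5e5, seed = 43))
  expect_false(identical(a$panel$geno, c$panel$geno))
})

test_that("no divergence and no fixed class give near-zero windowed F_ST", {
  cfg <- sim_config(chrom_length_bp = 2.1e7, divergence_fst = 0,
                    target_dxy = NULL, admix_prop = 0, seed = 8)
  panel <- simulate_reference_panels(cfg)
  expect_gte(ncol(panel$geno), 1e5)
  fst <- windowed_fst(panel, "ref_A", "ref_B", build_windows(panel, 20000))
  expect_lt(abs(mean(fst$fst, na.rm = TRUE)), 0.02)
})

test_that("realized d_xy matches the target, against a per-site frequency oracle", {
  cfg <- sim_config(seed = 21)
  panel <- simulate_reference_panels(cfg)
  fr <- attr(panel, "species_freqs")
  # oracle: expected divergence from the realized per-site frequencies
  dxy_freq <- sum(fr$p_a * (1 - fr$p_b) + fr$p_b * (1 - fr$p_a)) /
    sum(panel$chrom_lengths)
  expect_lt(abs(dxy_freq - cfg$target_dxy) / cfg$target_dxy, 0.15)
  # and the sample-based value agrees with the frequency-based one
  dxy_obs <- hsrscan:::panel_divergence(panel)$dxy
  expect_lt(abs(dxy_obs - dxy_freq) / dxy_freq, 0.05)
})

test_that("admixture extremes behave as specified", {
  cfg0 <- sim_config(chrom_length_bp = 5e5, admix_prop = 0, seed = 5)
  refs0 <- simulate_reference_panels(cfg0)
  adm0 <- simulate_admixed_haplotypes(cfg0, refs0)
  expect_equal(nrow(adm0$blocks), 0)

  cfg1 <- sim_config(chrom_length_bp = 5e5, admix_prop = 1, seed = 5)
  refs1 <- simulate_reference_panels(cfg1)
  adm1 <- simulate_admixed_haplotypes(cfg1, refs1)
  expect_equal(nrow(adm1$blocks), cfg1$n_query_haps)
  expect_true(all(adm1$blocks$start == 0 & adm1$blocks$end == 5e5))

  # mismatched site sets rejected
  other <- simulate_reference_panels(sim_config(chrom_length_bp = 5e5,
                                                seed = 99))
  attr(other, "species_freqs") <- NULL
  expect_error(simulate_admixed_haplotypes(cfg1, other), "site set")
})

test_that("default config recovers ~25% species-A ancestry in the truth", {
  cfg <- sim_config(seed = 7)  # 8 haplotypes x 10 Mb
  refs <- simulate_reference_panels(cfg)
  adm <- simulate_admixed_haplotypes(cfg, refs)
  fr <- truth_fractions(adm$blocks, refs$chrom_lengths,
                        adm$panel$haplotypes$hap_id)
  # oracle: fraction = summed truth-block lengths / genome size
  manual <- sapply(adm$panel$haplotypes$hap_id, function(h) {
    b <- adm$blocks[adm$blocks$hap_id == h, ]
    sum(b$end - b$start) / sum(refs$chrom_lengths)
  })
  expect_equal(fr$fraction, unname(manual))
  expect_lt(abs(mean(fr$fraction) - cfg$admix_prop), 0.05)
  # intervals non-overlapping and sorted within haplotype
  by_hap <- split(adm$blocks, adm$blocks$hap_id)
  for (b in by_hap) {
    expect_true(all(diff(b$start) > 0))
    expect_true(all(b$start[-1] >= b$end[-nrow(b)]))
  }
})

test_that("recombination map is normalized, reproducible, and optionally uniform", {
  cfg <- sim_config(chrom_length_bp = 1.05e6, map_total_cM = 3.3, seed = 12)
  m <- simulate_recombination_map(cfg)
  expect_true(all(m$rate_cM_per_Mb >= 0))
  tot <- sum(m$rate_cM_per_Mb * (m$end - m$start) / 1e6)
  expect_lt(abs(tot - 3.3) / 3.3, 1e-9)

  m2 <- simulate_recombination_map(cfg)
  expect_identical(m, m2)

  cfgu <- sim_config(chrom_length_bp = 1e6, map_total_cM = 5,
                     map_profile = "uniform", seed = 12)
  mu <- simulate_recombination_map(cfgu)
  expect_true(all(abs(mu$rate_cM_per_Mb - 5 / 1) < 1e-12))
})

test_that("pi and d_xy respond monotonically to their controlling knobs", {
  pis <- sapply(c(0.1, 0.3, 0.5), function(f) {
    p <- simulate_reference_panels(sim_config(chrom_length_bp = 2e6,
                                              divergence_fst = f, seed = 31))
    hsrscan:::panel_divergence(p)$pi_ref_A
  })
  expect_true(all(diff(pis) < 0))
  dxys <- sapply(c(0.003, 0.0038, 0.0046), function(d) {
    p <- simulate_reference_panels(sim_config(chrom_length_bp = 2e6,
                                              target_dxy = d, seed = 31))
    hsrscan:::panel_divergence(p)$dxy
  })
  expect_true(all(diff(dxys) > 0))
  fsts <- sapply(c(0.1, 0.3, 0.5), function(f) {
    p <- simulate_reference_panels(sim_config(chrom_length_bp = 2e6,
                                              divergence_fst = f, seed = 31))
    mean(windowed_fst(p, "ref_A", "ref_B", build_windows(p, 5000))$fst,
         na.rm = TRUE)
  })
  expect_true(all(diff(fsts) > 0))
})

test_that("nearly all windows clear the low-diversity filter under defaults", {
  cfg <- sim_config(chrom_length_bp = 4e6, seed = 17)
  ds <- simulate_hybrid_dataset(cfg)
  scores <- score_windows(panel_subset(ds$panel, "query"),
                          panel_subset(ds$panel, "ref_A"),
                          panel_subset(ds$panel, "ref_B"))
  expect_gt(mean(!scores$filtered), 0.95)
})

test_that("generate_dataset round-trips through the standard formats", {
  out <- withr::local_tempdir()
  cfg <- sim_config(chrom_length_bp = 4e5, seed = 3)
  man <- generate_dataset(cfg, out)
  ds <- simulate_hybrid_dataset(cfg)

  groups <- dplyr::distinct(ds$panel$haplotypes, sample, group)
  back <- read_phased_vcf(file.path(out, "panel.vcf"), groups)
  expect_identical(unname(back$geno[rownames(ds$panel$geno), ]),
                   unname(ds$panel$geno))
  expect_equal(unname(back$chrom_lengths["chr1"]), 4e5)

  bed <- read_bed(file.path(out, "truth_blocks.bed"), c("origin", "hap_id"))
  expect_true(all(bed$start >= 0 & bed$end <= 4e5))

  # manifest admixture fraction equals the recomputation from the BED
  from_bed <- mean(truth_fractions(bed, c(chr1 = 4e5),
                                   unique(ds$panel$haplotypes$hap_id[
                                     ds$panel$haplotypes$group == "query"
                                   ]))$fraction)
  expect_equal(man$realized$admix_fraction_mean, from_bed)

  m <- read_recomb_map(file.path(out, "recomb_map.tsv"))
  expect_equal(max(m$cum_cM_end), cfg$map_total_cM, tolerance = 1e-9)
  ex <- read_gff_exons(file.path(out, "exons.gff3"))
  expect_true(nrow(ex) > 0)
})
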