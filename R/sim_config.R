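#' Configuration for the synthetic hybrid-population generator
#'
#' Defines the study conditions the generator emulates: two reference panels
#' from divergent sister species (A and B), plus admixed query haplotypes that
#' are species-B mosaics carrying species-A blocks.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length_bp Length of each chromosome in bp.
#' @param snp_density Expected segregating sites per bp across the combined
#'   panels (default `5e-3`, i.e. an expected 100 SNPs per 20 kb window).
#' @param divergence_fst Balding-Nichols differentiation parameter for the
#'   shared-polymorphism site class.
#' @param target_dxy Expected between-species divergence per bp. The
#'   generator adds a species-fixed-difference site class sized analytically
#'   so the expected d_xy hits this value; `NULL` disables the fixed class.
#' @param ancestral_beta_shape Shape of the symmetric Beta distribution for
#'   ancestral allele frequencies at shared-polymorphism sites.
#' @param n_ref_a_haps,n_ref_b_haps,n_query_haps Panel sizes in haploid
#'   genomes (defaults 16, 8, 8: two haplotypes per diploid individual for
#'   8 species-A and 4 species-B reference individuals, 4 admixed queries).
#' @param admix_prop Expected fraction of each query haplotype that is
#'   species-A material (default 0.25).
#' @param block_length_mean_bp Mean introgressed block length (exponential).
#' @param copy_error Per-site probability that a copied donor allele is
#'   flipped inside an introgressed block, emulating post-introgression
#'   mutation/gene-conversion decay.
#' @param map_total_cM Genetic length of each chromosome in cM.
#' @param map_resolution_bp Recombination-map window size (default 100 kb).
#' @param map_profile `"gamma"` (heterogeneous) or `"uniform"`.
#' @param map_gamma_shape Shape of the gamma rate profile when heterogeneous.
#' @param exon_fraction,exon_length_mean_bp Toy exon annotation targets:
#'   genome fraction covered and mean exon length.
#' @param seed RNG seed; identical seed and config give bit-identical output.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 1L,
                       chrom_length_bp = 1e7,
                       snp_density = 5e-3,
                       divergence_fst = 0.4,
                       target_dxy = 0.0043,
                       ancestral_beta_shape = 5,
                       n_ref_a_haps = 16L,
                       n_ref_b_haps = 8L,
                       n_query_haps = 8L,
                       admix_prop = 0.25,
                       block_length_mean_bp = 1e5,
                       copy_error = 1e-4,
                       map_total_cM = 20,
                       map_resolution_bp = 1e5,
                       map_profile = c("gamma", "uniform"),
                       map_gamma_shape = 0.7,
                       exon_fraction = 0.089,
                       exon_length_mean_bp = 247,
                       seed = 1L) {
  map_profile <- match.arg(map_profile)
  check_scalar(n_chrom, "n_chrom", min = 1, integerish = TRUE)
  check_scalar(chrom_length_bp, "chrom_length_bp", min = 1)
  check_scalar(snp_density, "snp_density", min = 0, strict_min = TRUE)
  check_scalar(divergence_fst, "divergence_fst", min = 0, max = 1)
  if (!is.null(target_dxy)) {
    check_scalar(target_dxy, "target_dxy", min = 0, strict_min = TRUE)
    abort_if(target_dxy > snp_density,
             "`target_dxy` must not exceed `snp_density` (per-site divergence cannot exceed 1)")
  }
  check_scalar(ancestral_beta_shape, "ancestral_beta_shape",
               min = 0, strict_min = TRUE)
  check_scalar(n_ref_a_haps, "n_ref_a_haps", min = 1, integerish = TRUE)
  check_scalar(n_ref_b_haps, "n_ref_b_haps", min = 1, integerish = TRUE)
  check_scalar(n_query_haps, "n_query_haps", min = 1, integerish = TRUE)
  check_scalar(admix_prop, "admix_prop", min = 0, max = 1)
  check_scalar(block_length_mean_bp, "block_length_mean_bp",
               min = 0, strict_min = TRUE)
  check_scalar(copy_error, "copy_error", min = 0, max = 1)
  check_scalar(map_total_cM, "map_total_cM", min = 0, strict_min = TRUE)
  check_scalar(map_resolution_bp, "map_resolution_bp",
               min = 1, strict_min = FALSE)
  check_scalar(exon_fraction, "exon_fraction", min = 0, max = 1)
  check_scalar(exon_length_mean_bp, "exon_length_mean_bp",
               min = 1)
  check_scalar(seed, "seed", integerish = TRUE)
  structure(
    list(
      n_chrom = as.integer(n_chrom),
      chrom_length_bp = chrom_length_bp,
      snp_density = snp_density,
      divergence_fst = divergence_fst,
      target_dxy = target_dxy,
      ancestral_beta_shape = ancestral_beta_shape,
      n_ref_a_haps = as.integer(n_ref_a_haps),
      n_ref_b_haps = as.integer(n_ref_b_haps),
      n_query_haps = as.integer(n_query_haps),
      admix_prop = admix_prop,
      block_length_mean_bp = block_length_mean_bp,
      copy_error = copy_error,
      map_total_cM = map_total_cM,
      map_resolution_bp = map_resolution_bp,
      map_profile = map_profile,
      map_gamma_shape = map_gamma_shape,
      exon_fraction = exon_fraction,
      exon_length_mean_bp = exon_length_mean_bp,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Expected heterozygosity 2p(1-p) under Beta(a, a) ancestral frequencies.
beta_mean_het <- function(a) a / (2 * a + 1)

# Fraction of sites that must be species-fixed differences so that the
# expected per-bp d_xy equals target_dxy given the SNP density. Cross-species
# expected difference per shared-polymorphism site is E[2p(1-p)], independent
# of the Balding-Nichols F; per fixed-difference site it is 1.
fixed_diff_fraction <- function(config) {
  if (is.null(config$target_dxy)) return(0)
  e_het <- beta_mean_het(config$ancestral_beta_shape)
  d <- config$target_dxy / config$snp_density
  abort_if(d > 1, "target_dxy exceeds snp_density: unreachable divergence")
  max(0, (d - e_het) / (1 - e_het))
}
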