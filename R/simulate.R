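#' Simulate two divergent species reference panels
#'
#' Sites are placed by a Poisson process at `snp_density`. Each site is either
#' a species-fixed difference (class sized analytically so expected d_xy hits
#' `target_dxy`) or a shared polymorphism whose ancestral frequency is drawn
#' from a symmetric Beta and whose per-species frequencies follow the
#' Balding-Nichols construction with `divergence_fst`. Haplotypes are
#' independent Bernoulli draws from their species frequency.
#'
#' @param config A [sim_config()].
#' @return A [phased_panel()] with groups `ref_A` and `ref_B`. The realized
#'   per-species allele frequencies are attached as attribute
#'   `"species_freqs"` (used by [simulate_admixed_haplotypes()]).
#' @export
simulate_reference_panels <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  phi <- fixed_diff_fraction(config)
  a <- config$ancestral_beta_shape
  f <- config$divergence_fst
  with_seed(derive_seed(config$seed, 1L), {
    per_chrom <- lapply(seq_len(config$n_chrom), function(ci) {
      L <- config$chrom_length_bp
      n_sites <- rpois(1L, L * config$snp_density)
      n_sites <- min(n_sites, L)
      pos <- sort(sample.int(L, n_sites)) - 1L
      fixed <- runif(n_sites) < phi
      orient <- runif(n_sites) < 0.5
      p_anc <- rbeta(n_sites, a, a)
      if (f > 0) {
        s1 <- p_anc * (1 - f) / f
        s2 <- (1 - p_anc) * (1 - f) / f
        p_a <- rbeta(n_sites, s1, s2)
        p_b <- rbeta(n_sites, s1, s2)
      } else {
        p_a <- p_anc
        p_b <- p_anc
      }
      p_a[fixed] <- ifelse(orient[fixed], 1, 0)
      p_b[fixed] <- ifelse(orient[fixed], 0, 1)
      list(chrom = paste0("chr", ci), pos = pos, p_a = p_a, p_b = p_b)
    })
    chrom <- unlist(lapply(per_chrom, function(x) rep(x$chrom, length(x$pos))))
    pos <- unlist(lapply(per_chrom, `[[`, "pos"))
    p_a <- unlist(lapply(per_chrom, `[[`, "p_a"))
    p_b <- unlist(lapply(per_chrom, `[[`, "p_b"))
    s <- length(pos)
    alleles <- random_alleles(s)
    geno_a <- matrix(rbinom(config$n_ref_a_haps * s, 1L,
                            rep(p_a, each = config$n_ref_a_haps)),
                     nrow = config$n_ref_a_haps)
    geno_b <- matrix(rbinom(config$n_ref_b_haps * s, 1L,
                            rep(p_b, each = config$n_ref_b_haps)),
                     nrow = config$n_ref_b_haps)
    sites <- tibble(chrom = chrom, pos = as.integer(pos),
                    ref = alleles$ref, alt = alleles$alt)
    haps <- bind_rows(
      hap_table("ATL", config$n_ref_a_haps, "ref_A"),
      hap_table("PAC", config$n_ref_b_haps, "ref_B")
    )
    panel <- phased_panel(
      rbind(geno_a, geno_b), sites, haps,
      chrom_lengths = setNames(rep(config$chrom_length_bp, config$n_chrom),
                               paste0("chr", seq_len(config$n_chrom)))
    )
    attr(panel, "species_freqs") <- tibble(chrom = chrom,
                                           pos = as.integer(pos),
                                           p_a = p_a, p_b = p_b)
    panel
  })
}

random_alleles <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  list(ref = ref, alt = unname(alt))
}

hap_table <- function(prefix, n_haps, group) {
  i <- seq_len(n_haps)
  tibble(
    hap_id = sprintf("%s%02d_h%d", prefix, ceiling(i / 2), 2L - (i %% 2L)),
    sample = sprintf("%s%02d", prefix, ceiling(i / 2)),
    phase = 2L - (i %% 2L),
    group = group
  )
}

#' Simulate admixed query haplotypes with known introgressed blocks
#'
#' Each query haplotype is an independent species-B draw into which
#' species-A blocks are inserted: block starts follow a Poisson process whose
#' rate is set so expected coverage equals `admix_prop`, lengths are
#' exponential with mean `block_length_mean_bp`, and inside a block the
#' haplotype copies one randomly chosen species-A panel haplotype with a
#' small per-site copy error.
#'
#' @param config A [sim_config()].
#' @param panels The output of [simulate_reference_panels()] for the same
#'   config (site sets must match).
#' @return A list with elements `panel` (a `phased_panel` of group `query`)
#'   and `blocks` (truth tibble: `hap_id`, `chrom`, `start`, `end`, `origin`),
#'   intervals 0-based half-open, non-overlapping and sorted per haplotype.
#' @export
simulate_admixed_haplotypes <- function(config, panels) {
  stopifnot(inherits(config, "sim_config"), inherits(panels, "phased_panel"))
  freqs <- attr(panels, "species_freqs")
  abort_if(is.null(freqs) ||
             !identical(freqs$pos, panels$sites$pos) ||
             !identical(freqs$chrom, panels$sites$chrom),
           "`panels` lacks matching species frequencies for this site set")
  geno_a <- panel_matrix(panels, "ref_A")
  s <- nrow(panels$sites)
  n_q <- config$n_query_haps
  with_seed(derive_seed(config$seed, 2L), {
    geno_q <- matrix(rbinom(n_q * s, 1L, rep(freqs$p_b, each = n_q)),
                     nrow = n_q)
    hap_ids <- hap_table("BAL", n_q, "query")$hap_id
    blocks_all <- list()
    for (h in seq_len(n_q)) {
      for (ci in seq_len(config$n_chrom)) {
        cn <- paste0("chr", ci)
        L <- config$chrom_length_bp
        blocks <- draw_blocks(config, L)
        if (nrow(blocks) == 0) next
        site_in_chrom <- which(panels$sites$chrom == cn)
        pos <- panels$sites$pos[site_in_chrom]
        for (bi in seq_len(nrow(blocks))) {
          idx <- site_in_chrom[pos >= blocks$start[bi] & pos < blocks$end[bi]]
          if (length(idx) > 0) {
            donor <- sample.int(nrow(geno_a), 1L)
            copied <- geno_a[donor, idx]
            flip <- runif(length(idx)) < config$copy_error
            geno_q[h, idx] <- ifelse(flip, 1L - copied, copied)
          }
        }
        blocks_all[[length(blocks_all) + 1L]] <-
          mutate(blocks, hap_id = hap_ids[h], chrom = cn)
      }
    }
    blocks <- if (length(blocks_all)) {
      bind_rows(blocks_all) %>%
        mutate(origin = "A") %>%
        select("hap_id", "chrom", "start", "end", "origin") %>%
        arrange(.data$hap_id, .data$chrom, .data$start)
    } else {
      tibble(hap_id = character(), chrom = character(),
             start = numeric(), end = numeric(), origin = character())
    }
    panel <- phased_panel(geno_q, panels$sites,
                          hap_table("BAL", n_q, "query"),
                          panels$chrom_lengths)
    list(panel = panel, blocks = blocks)
  })
}

# Poisson block starts (extended left of the origin to avoid edge deficit),
# exponential lengths, overlaps unioned. Rate chosen so stationary coverage
# is admix_prop: 1 - exp(-lambda * mean_len) = admix_prop.
draw_blocks <- function(config, L) {
  q <- config$admix_prop
  mu <- config$block_length_mean_bp
  if (q == 0) return(tibble(start = numeric(), end = numeric()))
  if (q == 1) return(tibble(start = 0, end = L))
  lambda <- -log(1 - q) / mu
  pad <- 10 * mu
  n <- rpois(1L, lambda * (L + pad))
  if (n == 0) return(tibble(start = numeric(), end = numeric()))
  start <- runif(n, -pad, L)
  len <- rexp(n, 1 / mu)
  d <- tibble(start = pmax(0, floor(start)),
              end = pmin(L, ceiling(start + len))) %>%
    filter(.data$end > .data$start)
  if (nrow(d) == 0) return(d)
  merge_intervals(mutate(d, chrom = "."), max_gap = 0) %>%
    select("start", "end")
}

#' Per-haplotype introgressed fraction from truth blocks
#'
#' @param blocks Truth tibble from [simulate_admixed_haplotypes()].
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param hap_ids Optional full set of haplotype ids (so haplotypes with no
#'   blocks report fraction 0).
#' @return Tibble with `hap_id` and `fraction`.
#' @export
truth_fractions <- function(blocks, chrom_lengths, hap_ids = NULL) {
  total <- sum(chrom_lengths)
  out <- blocks %>%
    group_by(.data$hap_id) %>%
    summarise(fraction = sum(.data$end - .data$start) / total)
  if (!is.null(hap_ids)) {
    out <- tibble(hap_id = hap_ids) %>%
      left_join(out, by = "hap_id") %>%
      mutate(fraction = if_else(is.na(.data$fraction), 0, .data$fraction))
  }
  out
}

#' Simulate a windowed recombination map
#'
#' Per-window rates (cM/Mb) at `map_resolution_bp` resolution, either uniform
#' or gamma-heterogeneous, rescaled so each chromosome's genetic length
#' equals `map_total_cM` exactly.
#'
#' @param config A [sim_config()].
#' @return Tibble with `chrom`, `start`, `end`, `rate_cM_per_Mb`.
#' @export
simulate_recombination_map <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  abort_if(config$map_total_cM <= 0, "map_total_cM must be positive")
  with_seed(derive_seed(config$seed, 3L), {
    res <- config$map_resolution_bp
    out <- lapply(seq_len(config$n_chrom), function(ci) {
      L <- config$chrom_length_bp
      starts <- seq(0, L - 1, by = res)
      ends <- pmin(starts + res, L)
      width_mb <- (ends - starts) / 1e6
      w <- switch(config$map_profile,
        uniform = width_mb,
        gamma = rgamma(length(starts), shape = config$map_gamma_shape,
                       rate = 1) * width_mb
      )
      if (all(w == 0)) w <- width_mb
      g <- config$map_total_cM * w / sum(w)
      tibble(chrom = paste0("chr", ci), start = starts, end = ends,
             rate_cM_per_Mb = g / width_mb)
    })
    bind_rows(out)
  })
}

#' Simulate a toy exon annotation
#'
#' Poisson-placed exons with exponential lengths (mean
#' `exon_length_mean_bp`), unioned, covering about `exon_fraction` of the
#' genome.
#'
#' @param config A [sim_config()].
#' @return Interval tibble `chrom`, `start`, `end`, `label`.
#' @export
simulate_exons <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 4L), {
    mu <- config$exon_length_mean_bp
    lambda <- -log(1 - config$exon_fraction) / mu
    out <- lapply(seq_len(config$n_chrom), function(ci) {
      L <- config$chrom_length_bp
      n <- rpois(1L, lambda * L)
      if (n == 0) return(tibble(chrom = character(), start = numeric(),
                                end = numeric()))
      start <- sort(floor(runif(n, 0, L)))
      len <- pmax(1, round(rexp(n, 1 / mu)))
      merge_intervals(
        tibble(chrom = paste0("chr", ci), start = start,
               end = pmin(L, start + len)),
        max_gap = 0
      )
    })
    bind_rows(out) %>%
      select("chrom", "start", "end") %>%
      mutate(label = "exon")
  })
}

#' Simulate a complete hybrid-population dataset in memory
#'
#' Convenience wrapper chaining [simulate_reference_panels()],
#' [simulate_admixed_haplotypes()], [simulate_recombination_map()] and
#' [simulate_exons()].
#'
#' @param config A [sim_config()].
#' @return List with `panel` (combined query + ref_A + ref_B
#'   [phased_panel()]), `truth` (block tibble), `map`, `exons`, `config`.
#' @export
simulate_hybrid_dataset <- function(config) {
  refs <- simulate_reference_panels(config)
  adm <- simulate_admixed_haplotypes(config, refs)
  panel <- panel_bind(adm$panel, refs)
  attr(panel, "species_freqs") <- attr(refs, "species_freqs")
  list(panel = panel,
       truth = adm$blocks,
       map = simulate_recombination_map(config),
       exons = simulate_exons(config),
       config = config)
}
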