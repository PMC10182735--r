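#' End-to-end pipeline configuration
#'
#' Bundles the stage configs with a global seed; the global seed overrides
#' the stage seeds so one number reproduces the whole run.
#'
#' @param sim A [sim_config()].
#' @param scan A [scan_config()].
#' @param clock A [clock_config()].
#' @param diversity_window_bp Window size for pi / d_xy / F_ST (default 5 kb).
#' @param callable_fst Callable-mask F_ST threshold (default 0.15).
#' @param high_fst High-differentiation threshold (default 0.6).
#' @param date_hsrs Run the recombination clock stage (can be disabled for
#'   quick runs).
#' @param seed Global seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       scan = scan_config(),
                       clock = clock_config(),
                       diversity_window_bp = 5000,
                       callable_fst = 0.15,
                       high_fst = 0.6,
                       date_hsrs = TRUE,
                       seed = 1L) {
  check_scalar(seed, "seed", integerish = TRUE)
  sim$seed <- as.integer(seed)
  clock$seed <- derive_seed(seed, 1000L)
  structure(list(sim = sim, scan = scan, clock = clock,
                 diversity_window_bp = diversity_window_bp,
                 callable_fst = callable_fst, high_fst = high_fst,
                 date_hsrs = isTRUE(date_hsrs), seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full introgression analysis on a synthetic dataset
#'
#' Chains simulate, scan, recurrence/overlap, diversity/enrichment and
#' tract-dating stages; optionally writes per-stage tables and a
#' machine-readable metrics file.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory; when given, writes the score
#'   table, HSR BED, overlap and enrichment tables, age table and
#'   `metrics.yaml`. Reruns with the same config and seed are byte-identical.
#' @return List of class `hsr_run` with elements `dataset`, `scan`, `track`,
#'   `fractions`, `overlap`, `diversity`, `callable`, `enrichment`,
#'   `exon_density`, `rates`, `ages`, `evaluation`, `metrics`.
#' @export
run_hsr_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  ds <- simulate_hybrid_dataset(config$sim)
  scan <- hsr_scan(ds$panel, config$scan)
  n_q <- config$sim$n_query_haps
  div <- diversity_windows(ds$panel, config$diversity_window_bp)
  callable <- callable_mask(div, config$callable_fst)
  track <- overlap_track(scan$calls, ds$panel$chrom_lengths, n_q)
  fractions <- haplotype_fractions(scan$calls, callable,
                                   hap_ids = scan$query_haps)
  overlap <- overlap_summary(track, fractions, callable, n_haps = n_q)
  enr <- hsr_fst_enrichment(track, div, config$high_fst)
  full_a <- recurrent_regions(track, n_q, origin = "A", n_haps = n_q)
  exon_d <- if (nrow(full_a) > 0) {
    exon_density(full_a, ds$exons)
  } else NA_real_
  exon_genome <- exon_density(
    tibble(chrom = names(ds$panel$chrom_lengths), start = 0,
           end = as.numeric(ds$panel$chrom_lengths)), ds$exons)
  rates <- if (nrow(full_a) > 0) {
    rate_contrast(full_a, ds$map,
                  tibble(chrom = names(ds$panel$chrom_lengths), start = 0,
                         end = as.numeric(ds$panel$chrom_lengths)))
  } else NULL
  ages <- if (config$date_hsrs && nrow(scan$calls) > 0) {
    estimate_age(scan$calls, ds$map, config$clock)
  } else NULL
  evaluation <- evaluate_calls(scan$calls, ds$truth,
                               ds$panel$chrom_lengths,
                               min_truth_bp = 2 * config$scan$window_size_bp,
                               n_query_haps = n_q)
  age_sum <- if (!is.null(ages)) summarize_ages(ages) else NULL
  metrics <- list(
    seed = config$seed,
    mean_ratio = scan$mean_ratio,
    threshold_low = unname(scan$thresholds[["low"]]),
    threshold_high = unname(scan$thresholds[["high"]]),
    n_windows = nrow(scan$scores) / max(1, length(scan$query_haps)),
    n_filtered_pairs = sum(scan$scores$filtered),
    n_hsr_a = sum(scan$calls$origin == "A"),
    n_hsr_b = sum(scan$calls$origin == "B"),
    bases_hsr_a = sum(scan$calls$size_bp[scan$calls$origin == "A"]),
    bases_hsr_b = sum(scan$calls$size_bp[scan$calls$origin == "B"]),
    s_callable = attr(overlap, "s_callable"),
    full_overlap_regions_a = nrow(full_a),
    full_overlap_bases_a = sum(full_a$end - full_a$start),
    exon_density_full_a = exon_d,
    exon_density_genome = exon_genome,
    precision = evaluation$precision,
    recall = evaluation$recall,
    f1 = evaluation$f1,
    admix_called = evaluation$admix_called,
    admix_true = evaluation$admix_true
  )
  if (!is.null(age_sum)) {
    a_row <- age_sum[age_sum$origin %in% "A", ]
    if (nrow(a_row) == 1) {
      metrics$age_median_gen_a <- a_row$median_gen
      metrics$age_median_kya_a <- a_row$median_kya
    }
  }
  out <- structure(
    list(dataset = ds, scan = scan, track = track, fractions = fractions,
         overlap = overlap, diversity = div, callable = callable,
         enrichment = enr, exon_density = exon_d,
         exon_density_genome = exon_genome, rates = rates, ages = ages,
         evaluation = evaluation, metrics = metrics, config = config),
    class = "hsr_run"
  )
  if (!is.null(out_dir)) write_run_outputs(out, out_dir)
  out
}

#' @export
print.hsr_run <- function(x, ...) {
  m <- x$metrics
  cat("<hsr_run>\n")
  cat(sprintf("  mean ratio %.3f; HSRs: %d A (%.2f Mb), %d B (%.2f Mb)\n",
              m$mean_ratio, m$n_hsr_a, m$bases_hsr_a / 1e6, m$n_hsr_b,
              m$bases_hsr_b / 1e6))
  cat(sprintf("  block F1 %.3f (precision %.3f, recall %.3f)\n",
              m$f1, m$precision, m$recall))
  invisible(x)
}

write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(run$scan$scores, file.path(out_dir, "window_scores.tsv"))
  write_bed(select(run$scan$calls, "chrom", "start", "end", "origin",
                   "hap_id"),
            file.path(out_dir, "hsr_calls.bed"))
  readr::write_tsv(run$overlap, file.path(out_dir, "overlap_expectation.tsv"))
  readr::write_tsv(run$enrichment, file.path(out_dir, "fst_enrichment.tsv"))
  readr::write_tsv(run$diversity, file.path(out_dir, "diversity_windows.tsv"))
  if (!is.null(run$ages)) {
    readr::write_tsv(run$ages$summary, file.path(out_dir, "hsr_ages.tsv"))
  }
  yaml::write_yaml(run$metrics, file.path(out_dir, "metrics.yaml"))
  invisible(out_dir)
}
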