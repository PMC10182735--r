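#' Configuration for the recombination-clock tract dating
#'
#' @param n_replicates Decay simulations per HSR (default 100).
#' @param max_generations Generation cap; replicates that reach it are
#'   censored (default 5e5, comfortably above the 1e5 reporting range).
#' @param generation_time_years Years per generation (default 2.4).
#' @param seed Global seed; per-HSR replicate streams are derived from it.
#' @return A list of class `clock_config`.
#' @export
clock_config <- function(n_replicates = 100,
                         max_generations = 5e5,
                         generation_time_years = 2.4,
                         seed = 1L) {
  check_scalar(n_replicates, "n_replicates", min = 1, integerish = TRUE)
  check_scalar(max_generations, "max_generations", min = 1,
               integerish = TRUE)
  check_scalar(generation_time_years, "generation_time_years", min = 0,
               strict_min = TRUE)
  check_scalar(seed, "seed", integerish = TRUE)
  structure(list(n_replicates = as.integer(n_replicates),
                 max_generations = max_generations,
                 generation_time_years = generation_time_years,
                 seed = as.integer(seed)),
            class = "clock_config")
}

# chromosome map slice -> list(L, total_cM, cum breakpoints) for fast
# genetic <-> physical conversion
chrom_map_fun <- function(map, chrom) {
  mw <- map_cumulative(map[map$chrom == chrom, ])
  abort_if(nrow(mw) == 0, sprintf("chromosome %s not in map", chrom))
  list(
    L = max(mw$end),
    total_cM = max(mw$cum_cM_end),
    win_start = mw$start, win_end = mw$end,
    cum_start = mw$cum_cM_start, cum_end = mw$cum_cM_end
  )
}

# genetic position (cM) -> physical bp, linear within map windows
genetic_to_physical <- function(cm, u) {
  i <- findInterval(u, cm$cum_start, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(cm$cum_start))
  span_g <- cm$cum_end[i] - cm$cum_start[i]
  frac <- ifelse(span_g > 0, (u - cm$cum_start[i]) / span_g, 0)
  cm$win_start[i] + frac * (cm$win_end[i] - cm$win_start[i])
}

#' Simulate recombination-driven decay of an introgressed tract
#'
#' The tract starts as the whole chromosome. Each generation at most one
#' crossover occurs, with probability `p = min(1, genetic length in
#' Morgans)`; its position is drawn with per-base probability proportional
#' to the local recombination rate. A crossover inside the current tract
#' truncates it on the side away from the focal point. The replicate's value
#' is the first generation at which the surviving tract is shorter than
#' `observed_size_bp` (censored at the cap when never reached, e.g. on a
#' zero-rate chromosome).
#'
#' @param map Recombination map tibble.
#' @param chrom Chromosome of the tract.
#' @param focal_bp Focal position (bp) retained inside the tract.
#' @param observed_size_bp Observed tract size (bp), `0 < size <= L`.
#' @param config A [clock_config()].
#' @param n Number of replicates (defaults to `config$n_replicates`).
#' @param seed Seed for this call (defaults to `config$seed`).
#' @return Tibble with `replicate`, `generation`, `censored`.
#' @export
simulate_tract_decay <- function(map, chrom, focal_bp, observed_size_bp,
                                 config = clock_config(),
                                 n = config$n_replicates,
                                 seed = config$seed) {
  cm <- chrom_map_fun(map, chrom)
  abort_if(focal_bp < 0 || focal_bp > cm$L, "focal point outside chromosome")
  abort_if(observed_size_bp <= 0 || observed_size_bp > cm$L,
           "observed size must be in (0, chromosome length]")
  p <- min(1, cm$total_cM / 100)
  cap <- config$max_generations
  with_seed(seed, {
    gens <- numeric(n)
    cens <- logical(n)
    for (r in seq_len(n)) {
      res <- decay_one(cm, focal_bp, observed_size_bp, p, cap)
      gens[r] <- res$generation
      cens[r] <- res$censored
    }
    tibble(replicate = seq_len(n), generation = gens, censored = cens)
  })
}

# One replicate. Crossovers are an ordered event stream; the surviving tract
# after n events is [max(breaks <= focal), min(breaks > focal)] clamped to
# the chromosome, so running cummax/cummin give the whole trajectory at once.
decay_one <- function(cm, focal_bp, observed_size_bp, p, cap) {
  if (p <= 0) return(list(generation = cap, censored = TRUE))
  lo <- 0; hi <- cm$L; gen <- 0
  batch <- 512L
  repeat {
    gaps <- if (p >= 1) rep(1, batch) else rgeom(batch, p) + 1
    gens <- gen + cumsum(gaps)
    u <- runif(batch, 0, cm$total_cM)
    x <- genetic_to_physical(cm, u)
    lo_run <- cummax(c(lo, ifelse(x <= focal_bp, x, -Inf))[-1])
    lo_run <- pmax(lo_run, lo)
    hi_run <- cummin(c(hi, ifelse(x > focal_bp, x, Inf))[-1])
    hi_run <- pmin(hi_run, hi)
    size <- hi_run - lo_run
    hit <- which(size < observed_size_bp & gens <= cap)
    if (length(hit) > 0) {
      return(list(generation = gens[hit[1]], censored = FALSE))
    }
    if (gens[batch] > cap) return(list(generation = cap, censored = TRUE))
    lo <- lo_run[batch]; hi <- hi_run[batch]; gen <- gens[batch]
  }
}

#' Surviving tract size after a fixed number of generations
#'
#' Forward companion of [simulate_tract_decay()]: run the same decay process
#' for exactly `generations` generations and report the surviving tract
#' length. Useful for self-consistency checks (generate tracts of known age,
#' then date them).
#'
#' @inheritParams simulate_tract_decay
#' @param generations Number of generations to simulate.
#' @return Numeric vector of `n` tract sizes in bp.
#' @export
tract_size_after <- function(map, chrom, focal_bp, generations,
                             n = 1, seed = 1L) {
  cm <- chrom_map_fun(map, chrom)
  p <- min(1, cm$total_cM / 100)
  with_seed(seed, {
    vapply(seq_len(n), function(r) {
      if (p <= 0) return(cm$L)
      n_events <- rbinom(1, generations, p)
      if (n_events == 0) return(cm$L)
      x <- genetic_to_physical(cm, runif(n_events, 0, cm$total_cM))
      lo <- max(0, x[x <= focal_bp])
      hi <- min(cm$L, x[x > focal_bp])
      hi - lo
    }, numeric(1))
  })
}

#' Date HSR calls with the recombination clock
#'
#' For each call, runs `n_replicates` independent decay simulations with the
#' focal point at the call midpoint and summarises the first-passage
#' generations.
#'
#' @param calls HSR call tibble (needs `chrom`, `start`, `end`; `hap_id`
#'   and `origin` are carried through if present).
#' @param map Recombination map covering the calls' chromosomes.
#' @param config A [clock_config()].
#' @return Object of class `hsr_ages`: list with `summary` (per-call median,
#'   quartiles, censored count, years) and `config`.
#' @export
estimate_age <- function(calls, map, config = clock_config()) {
  abort_if(nrow(calls) == 0, "no calls to date")
  rows <- purrr::map(seq_len(nrow(calls)), function(i) {
    cl <- calls[i, ]
    reps <- simulate_tract_decay(
      map, cl$chrom, focal_bp = (cl$start + cl$end) / 2,
      observed_size_bp = cl$end - cl$start, config = config,
      seed = derive_seed(config$seed, i)
    )
    tibble(
      hsr_id = i,
      hap_id = if ("hap_id" %in% names(cl)) cl$hap_id else NA_character_,
      origin = if ("origin" %in% names(cl)) cl$origin else NA_character_,
      chrom = cl$chrom, start = cl$start, end = cl$end,
      size_bp = cl$end - cl$start,
      median_gen = median(reps$generation),
      q25_gen = unname(quantile(reps$generation, 0.25)),
      q75_gen = unname(quantile(reps$generation, 0.75)),
      n_censored = sum(reps$censored),
      censored = all(reps$censored)
    )
  })
  summary <- bind_rows(rows) %>%
    mutate(median_years = generations_to_years(
      .data$median_gen, config$generation_time_years))
  structure(list(summary = summary, config = config), class = "hsr_ages")
}

#' @export
print.hsr_ages <- function(x, ...) {
  cat(sprintf("<hsr_ages> %d dated regions; cohort median %.3g generations\n",
              nrow(x$summary), median(x$summary$median_gen)))
  invisible(x)
}

#' Cohort summary of age estimates
#'
#' Medians are taken over all loci including those whose estimates exceed
#' the reporting range; the count beyond the range is reported separately.
#'
#' @param ages An `hsr_ages` object or its `summary` tibble.
#' @param range_cap Reporting range in generations (default 1e5).
#' @param generation_time_years Years per generation for the kYA column.
#' @return Tibble per origin: `n`, `median_gen`, `n_beyond_range`,
#'   `median_years`, `median_kya` (nearest integer).
#' @export
summarize_ages <- function(ages, range_cap = 1e5,
                           generation_time_years = 2.4) {
  s <- if (inherits(ages, "hsr_ages")) {
    generation_time_years <- ages$config$generation_time_years
    ages$summary
  } else as_tibble(ages)
  abort_if(nrow(s) == 0, "no estimates to summarise")
  if (!"origin" %in% names(s)) s$origin <- NA_character_
  s %>%
    group_by(.data$origin) %>%
    summarise(
      n = n(),
      n_beyond_range = sum(.data$median_gen > range_cap),
      median_gen = median(.data$median_gen),
      .groups = "drop"
    ) %>%
    mutate(
      median_years = generations_to_years(.data$median_gen,
                                          generation_time_years),
      median_kya = round(.data$median_years / 1000)
    )
}

#' Convert generations to years
#'
#' @param generations Generations since introgression (`>= 0`).
#' @param generation_time_years Years per generation (default 2.4).
#' @return Years; the conventional kYA display is `round(years / 1000)`.
#' @export
generations_to_years <- function(generations, generation_time_years = 2.4) {
  abort_if(any(generations < 0), "generations must be non-negative")
  generations * generation_time_years
}
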