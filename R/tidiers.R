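#' Tidy and glance methods
#'
#' `tidy()` returns the per-record result table of a fitted object (HSR
#' calls for a scan, per-region ages for a dating run); `glance()` returns a
#' one-row summary.
#'
#' @param x An `hsr_scan`, `hsr_ages` or `hsr_run` object.
#' @param ... Unused.
#' @return A tibble.
#' @name hsrscan-tidiers
NULL

#' @rdname hsrscan-tidiers
#' @method tidy hsr_scan
#' @export
tidy.hsr_scan <- function(x, ...) x$calls

#' @rdname hsrscan-tidiers
#' @method glance hsr_scan
#' @export
glance.hsr_scan <- function(x, ...) {
  tibble(
    mean_ratio = x$mean_ratio,
    threshold_low = unname(x$thresholds[["low"]]),
    threshold_high = unname(x$thresholds[["high"]]),
    n_windows = nrow(x$scores),
    n_filtered = sum(x$scores$filtered),
    n_hsr_a = sum(x$calls$origin == "A"),
    n_hsr_b = sum(x$calls$origin == "B"),
    bases_hsr_a = sum(x$calls$size_bp[x$calls$origin == "A"]),
    bases_hsr_b = sum(x$calls$size_bp[x$calls$origin == "B"])
  )
}

#' @rdname hsrscan-tidiers
#' @method tidy hsr_ages
#' @export
tidy.hsr_ages <- function(x, ...) x$summary

#' @rdname hsrscan-tidiers
#' @method glance hsr_ages
#' @export
glance.hsr_ages <- function(x, ...) {
  summarize_ages(x) %>%
    tidyr::pivot_wider(names_from = "origin",
                       values_from = c("n", "median_gen", "n_beyond_range",
                                       "median_years", "median_kya"))
}

#' @rdname hsrscan-tidiers
#' @method tidy hsr_run
#' @export
tidy.hsr_run <- function(x, ...) x$scan$calls

#' @rdname hsrscan-tidiers
#' @method glance hsr_run
#' @export
glance.hsr_run <- function(x, ...) {
  as_tibble(x$metrics[!vapply(x$metrics, is.null, logical(1))])
}
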