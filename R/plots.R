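#' Plot window distance ratios along the genome
#'
#' Log-scaled ratio per window and haplotype with the two call thresholds;
#' called windows fall outside the dashed band.
#'
#' @param object An `hsr_scan` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hsr_scan
#' @export
autoplot.hsr_scan <- function(object, ...) {
  d <- object$scores %>%
    filter(!.data$filtered, is.finite(.data$ratio), .data$ratio > 0)
  ggplot2::ggplot(d, ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                  y = .data$ratio)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4) +
    ggplot2::geom_hline(yintercept = object$thresholds,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::geom_hline(yintercept = object$mean_ratio,
                        colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::facet_grid(hap_id ~ chrom) +
    ggplot2::labs(x = "position (Mb)", y = "d_A / d_B",
                  title = "Window distance ratios") +
    ggplot2::theme_minimal(base_size = 9)
}

#' Plot HSR sizes ranked from largest to smallest, by origin
#'
#' @param calls HSR call tibble.
#' @return A ggplot object.
#' @export
plot_hsr_sizes <- function(calls) {
  d <- calls %>%
    group_by(.data$origin) %>%
    arrange(dplyr::desc(.data$size_bp), .by_group = TRUE) %>%
    mutate(rank = row_number()) %>%
    ungroup()
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$size_bp / 1e3,
                                  colour = .data$origin)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "size rank", y = "HSR size (kb)",
                  colour = "origin") +
    ggplot2::theme_minimal()
}

#' Plot observed versus expected recurrence by overlap count
#'
#' @param overlap Output of [overlap_summary()].
#' @return A ggplot object.
#' @export
plot_overlap_counts <- function(overlap) {
  d <- overlap %>%
    tidyr::pivot_longer(c("observed_bases", "expected_bases"),
                        names_to = "kind", values_to = "bases") %>%
    filter(.data$bases > 0)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$k), y = .data$bases,
                                  fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~origin) +
    ggplot2::labs(x = "haplotypes sharing an HSR (k)", y = "bases",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the distribution of estimated ages
#'
#' @param object An `hsr_ages` object.
#' @param range_cap Upper display limit in generations (default 1e5);
#'   medians (vertical lines) still use all loci.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hsr_ages
#' @export
autoplot.hsr_ages <- function(object, range_cap = 1e5, ...) {
  s <- object$summary
  med <- s %>%
    group_by(.data$origin) %>%
    summarise(med = median(.data$median_gen))
  ggplot2::ggplot(filter(s, .data$median_gen <= range_cap),
                  ggplot2::aes(x = .data$median_gen, fill = .data$origin)) +
    ggplot2::geom_histogram(bins = 40, alpha = 0.6,
                            position = "identity") +
    ggplot2::geom_vline(data = med,
                        ggplot2::aes(xintercept = .data$med,
                                     colour = .data$origin)) +
    ggplot2::labs(x = "estimated age (generations)", y = "regions") +
    ggplot2::theme_minimal()
}
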