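# ggplot2 displays for the main result types.

#' Plot an SBS96 spectrum
#'
#' Bar plot over the 96 channels, faceted by substitution type in the
#' conventional catalog layout.
#'
#' @param spectrum An `sbs_spectrum` (see [build_spectrum()]).
#' @return A ggplot object.
#' @export
plot_spectrum <- function(spectrum) {
  ggplot2::ggplot(spectrum,
                  ggplot2::aes(x = .data$channel, y = .data$count,
                               fill = .data$substitution)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_grid(~substitution, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "sSNV count") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())
}

#' @export
autoplot.sbs_spectrum <- function(object, ...) plot_spectrum(object)

#' Plot per-cell burden against donor age
#'
#' @param burdens Tibble with age, burden_per_gb and condition columns.
#' @return A ggplot object with per-condition linear trends.
#' @export
plot_burden_age <- function(burdens) {
  ggplot2::ggplot(burdens,
                  ggplot2::aes(x = .data$age, y = .data$burden_per_gb,
                               colour = .data$condition)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "Age (years)", y = "sSNVs per GB",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot observed/expected enrichment ratios across groups
#'
#' @param x An `enrichment_result`.
#' @return A ggplot object: ratio with permutation SD error bars and the
#'   fitted linear trend, annotated with R and P.
#' @export
plot_enrichment <- function(x) {
  df <- x$groups
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$ratio)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ratio - .data$ratio_sd,
                   ymax = .data$ratio + .data$ratio_sd), width = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::labs(x = "Group (low → high)",
                  y = "Observed / expected sSNV density",
                  subtitle = sprintf("R = %.2f, P = %.3g", x$R, x$p.value)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.enrichment_result <- function(object, ...) plot_enrichment(object)

#' Plot NMF rank-selection diagnostics
#'
#' @param x An `nmf_result`.
#' @return A ggplot of the cophenetic coefficient and scaled RSS per rank.
#' @export
plot_rank_selection <- function(x) {
  d <- x$diagnostics |>
    dplyr::mutate(rss_scaled = .data$rss / max(.data$rss)) |>
    tidyr::pivot_longer(c("cophenetic", "rss_scaled"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$value,
                                  colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = x$rank, linetype = 2) +
    ggplot2::labs(x = "Rank", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.nmf_result <- function(object, ...) plot_rank_selection(object)
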