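# ggplot2 views of the main result types.

#' Plot cumulative distributions of the modified relative difference
#'
#' One step curve per nutrient, in the style of a nutrient-concordance
#' CDF panel.
#'
#' @param comparisons Tibble from [compare_nutrients()].
#' @param weighting `"unique"` or `"volume"`.
#' @return A ggplot object.
#' @export
plot_rel_diff_cdf <- function(comparisons,
                              weighting = c("unique", "volume")) {
  weighting <- match.arg(weighting)
  cdfs <- purrr::map_dfr(
    unique(comparisons$nutrient),
    function(nut) {
      dplyr::mutate(rel_diff_cdf(comparisons, nut, weighting),
                    nutrient = nut)
    })
  ggplot2::ggplot(cdfs, ggplot2::aes(.data$rel_diff, .data$cum_fraction,
                                     colour = .data$nutrient)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "modified relative difference",
                  y = "cumulative fraction of products",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot dispersion of profile differences by number of retailers
#'
#' Pooled standard deviation of the percentage-point differences for
#' retailers used individually (squares) and cumulatively combined
#' (circles).
#'
#' @param dispersion Tibble from [dispersion_summary()].
#' @param max_individual How many individual retailers to show.
#' @return A ggplot object.
#' @export
plot_coverage_dispersion <- function(dispersion, max_individual = 10) {
  pooled <- dispersion |>
    dplyr::filter(.data$group == "(pooled)") |>
    dplyr::mutate(
      rank_num = suppressWarnings(
        as.integer(sub("individual_", "", .data$subset_id))),
      x = ifelse(.data$subset_type == "individual" & !is.na(.data$rank_num),
                 .data$rank_num, .data$subset_size)) |>
    dplyr::filter(.data$subset_type == "cumulative" |
                    .data$x <= max_individual)
  ggplot2::ggplot(pooled, ggplot2::aes(.data$x, .data$sd_pp,
                                       shape = .data$subset_type)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_line(data = ~ dplyr::filter(.x, .data$subset_type ==
                                                "cumulative")) +
    ggplot2::scale_shape_manual(values = c(individual = 15,
                                           cumulative = 16)) +
    ggplot2::labs(x = "retailer rank / number of retailers combined",
                  y = "SD of percentage-point difference",
                  shape = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cpd_coverage <- function(object, ...) {
  plot_coverage_dispersion(dispersion_summary(object), ...)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
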