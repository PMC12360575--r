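#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a decision curve
#'
#' Net benefit against threshold for every strategy in the curve, clipped
#' below at slightly under 0 so the 'none' reference stays visible.
#'
#' @param object A `nb_curve` tibble from [decision_curve()].
#' @param ymin Lower display limit (default -0.02).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nb_curve <- function(object, ymin = -0.02, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$threshold, y = .data$net_benefit,
                               colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(ymin, NA)) +
    ggplot2::labs(x = "risk threshold t", y = "net benefit b(t)",
                  colour = NULL,
                  title = paste0("Decision curve (", object$subgroup[1],
                                 " subgroup, n = ", object$n[1], ")")) +
    ggplot2::theme_minimal()
}

#' Scatter of single-variable AUC: comorbid vs non-comorbid
#'
#' Each point is one variable, positioned by its single-variable model AUC in
#' the comorbid (x) and non-comorbid (y) subgroups; the diagonal marks equal
#' predictive ability. Points below the diagonal are more informative in the
#' comorbid subgroup.
#'
#' @param table A driver tibble from [single_variable_models()].
#' @return A ggplot object.
#' @export
plot_single_variable_auc <- function(table) {
  wide <- table |>
    dplyr::select("feature", "category", "subgroup", "score") |>
    tidyr::pivot_wider(names_from = "subgroup", values_from = "score")
  ggplot2::ggplot(wide,
                  ggplot2::aes(x = .data$comorbid, y = .data$non_comorbid,
                               colour = .data$category == "ELF")) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "red"),
                                 labels = c("other", "ELF"), name = NULL) +
    ggplot2::labs(x = "AUC, comorbid subgroup",
                  y = "AUC, non-comorbid subgroup") +
    ggplot2::theme_minimal()
}

#' Bar chart of the top driver variables
#'
#' @param table A driver tibble (one subgroup) with `feature`, `score`,
#'   `category`.
#' @param top_k How many variables to show (default 30).
#' @return A ggplot object.
#' @export
plot_top_drivers <- function(table, top_k = 30) {
  top <- table |>
    dplyr::arrange(dplyr::desc(.data$score)) |>
    utils::head(top_k)
  ggplot2::ggplot(top,
                  ggplot2::aes(x = .data$score,
                               y = stats::reorder(.data$feature, .data$score),
                               fill = .data$category == "ELF")) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "forestgreen"),
                               labels = c("other", "ELF"), name = NULL) +
    ggplot2::labs(x = unique(table$metric), y = NULL) +
    ggplot2::theme_minimal()
}

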