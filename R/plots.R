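#' Plot methods
#'
#' ggplot2 `autoplot()` methods for the main result types: an MA plot for
#' contrast results (mean normalized count vs log2 fold change, significant
#' genes highlighted), stacked category bars for classifications, and a
#' per-replicate calibration dot plot with the nominal band for null
#' calibrations.
#'
#' @param object A result object.
#' @param alpha Adjusted-p highlight threshold for the MA plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name plots
NULL

#' @rdname plots
#' @method autoplot contrast_result
#' @export
autoplot.contrast_result <- function(object, alpha = 0.05, ...) {
  df <- tidy(object) |>
    dplyr::filter(.data$tested) |>
    dplyr::mutate(
      significant = !is.na(.data$padj) & .data$padj < alpha
    )
  ggplot2::ggplot(
    df, ggplot2::aes(.data$base_mean, .data$log2fc, colour = .data$significant)
  ) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
      name = paste0("padj < ", alpha)
    ) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "mean normalized count", y = "log2 fold change")
}

#' @rdname plots
#' @method autoplot reversal_classification
#' @export
autoplot.reversal_classification <- function(object, ...) {
  df <- summarize_categories(object) |>
    dplyr::mutate(
      category = factor(.data$category, levels = reversal_category_levels)
    )
  ggplot2::ggplot(
    df, ggplot2::aes(.data$direction, .data$n, fill = .data$category)
  ) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(
      x = "direction of age effect", y = "genes",
      fill = "repopulation outcome"
    )
}

#' @rdname plots
#' @method autoplot lps_classification
#' @export
autoplot.lps_classification <- function(object, ...) {
  df <- summarize_categories(object) |>
    dplyr::mutate(
      category = factor(.data$category, levels = lps_category_levels)
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$category, .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_col(
      ggplot2::aes(y = .data$n_prevented), fill = "navy"
    ) +
    ggplot2::labs(
      x = NULL, y = "genes",
      subtitle = "dark: LPS induction prevented by repopulation"
    ) +
    ggplot2::theme(
      axis.text.x = ggplot2::element_text(angle = 30, hjust = 1)
    )
}

#' @rdname plots
#' @method autoplot null_calibration
#' @export
autoplot.null_calibration <- function(object, ...) {
  alpha <- attr(object, "alpha") %||% 0.05
  ggplot2::ggplot(
    tidy(object),
    ggplot2::aes(.data$contrast, .data$frac_p_below)
  ) +
    ggplot2::geom_hline(yintercept = alpha, linetype = 2) +
    ggplot2::geom_point(position = ggplot2::position_jitter(width = 0.1)) +
    ggplot2::labs(
      x = NULL, y = paste0("fraction of raw p < ", alpha),
      subtitle = "all-null simulation, one point per replicate"
    )
}
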