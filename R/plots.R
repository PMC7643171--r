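# ggplot2 methods for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Violin plot of per-OCR variance fractions
#'
#' One violin per covariate (plus residual), with the median fraction
#' annotated — the usual way to show how much accessibility variation each
#' biological or technical covariate explains.
#'
#' @param object An `ocr_varfrac` tibble from [variance_fractions()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ocr_varfrac <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"ocr_id",
                              names_to = "covariate", values_to = "fraction")
  med <- dplyr::summarise(dplyr::group_by(long, .data$covariate),
                          fraction = stats::median(.data$fraction,
                                                   na.rm = TRUE),
                          .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = stats::reorder(.data$covariate,
                                                        -.data$fraction,
                                                        stats::median),
                                     y = .data$fraction)) +
    ggplot2::geom_violin(scale = "width", fill = "grey85") +
    ggplot2::geom_point(data = med, colour = "red", size = 2) +
    ggplot2::labs(x = NULL, y = "fraction of variance explained") +
    ggplot2::theme_minimal()
}

#' Heatmap of the pairwise pi1 matrix
#'
#' @param object An `ocr_pi1_matrix` tibble from [pairwise_pi1()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ocr_pi1_matrix <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$group_a, y = .data$group_b,
                               fill = .data$pi1)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "pi1") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Stacked-bar plot of estimated cell-type proportions
#'
#' @param object An `ocr_mixing` tibble from [estimate_proportions()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ocr_mixing <- function(object, ...) {
  cells <- setdiff(names(object), c("sample_id", "residual_norm"))
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              dplyr::all_of(cells),
                              names_to = "cell_type",
                              values_to = "proportion")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id,
                                     y = .data$proportion,
                                     fill = .data$cell_type)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "estimated proportion", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Mean-variance trend plot of the precision-weight fit
#'
#' @param object An `ocr_voom` object from [voom_weights()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ocr_voom <- function(object, ...) {
  ggplot2::ggplot(object$trend, ggplot2::aes(x = .data$mean_logcount,
                                             y = .data$sqrt_sd)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.4) +
    ggplot2::geom_smooth(formula = y ~ x, method = "loess", se = FALSE,
                         colour = "red") +
    ggplot2::labs(x = "mean log2 count", y = "sqrt(residual sd)") +
    ggplot2::theme_minimal()
}
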