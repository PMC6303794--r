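# ggplot2 displays for the main result types. These are deliberately plain:
# one panel per call, no styling beyond labels.

#' @method autoplot pbb_kcurve
#' @export
autoplot.pbb_kcurve <- function(object,
                                quantity = c("mean_block_size", "max_block_size",
                                             "reusability_entropy", "mean_reusability",
                                             "total_reusability"),
                                ...) {
  quantity <- match.arg(quantity)
  df <- object[object$feasible, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data[[quantity]])) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "number of building blocks (k)", y = quantity)
}

#' @method autoplot pbb_comparison
#' @export
autoplot.pbb_comparison <- function(object, ...) {
  ggplot2::ggplot(object$members, ggplot2::aes(x = .data$auc_ratio)) +
    ggplot2::geom_histogram(bins = 20) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = sprintf("AUC ratio (ensemble/real), %s", object$quantity),
                  y = "members")
}

#' Element-usage histogram with its binomial expectation
#'
#' Bars show the observed usage (expression-breadth) histogram; the line
#' shows the expected counts if presences were scattered binomially at the
#' matrix density. A U-shaped departure (excess at both extremes) is the
#' usage signature of biological systems.
#'
#' @param matrix a [condition_matrix()].
#' @return a ggplot object.
#' @export
plot_usage_distribution <- function(matrix) {
  obs <- element_usage(matrix, include_zero = TRUE)
  expd <- binomial_usage_expectation(matrix)
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$usage, y = .data$n_elements)) +
    ggplot2::geom_col() +
    ggplot2::geom_line(data = expd,
                       ggplot2::aes(x = .data$usage, y = .data$expected),
                       color = "red") +
    ggplot2::labs(x = "element usage (conditions)", y = "elements")
}

#' Block size vs reusability scatter for a decomposition
#'
#' @param decomposition a `pbb_decomposition`.
#' @return a ggplot object.
#' @export
plot_size_reusability <- function(decomposition) {
  ggplot2::ggplot(tidy(decomposition),
                  ggplot2::aes(x = .data$size, y = .data$reusability)) +
    ggplot2::geom_count() +
    ggplot2::labs(x = "block size (elements)", y = "reusability (conditions)")
}
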