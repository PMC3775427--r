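#' Plot metric-versus-sparsity curves
#'
#' One panel per metric, one line per network (including the random
#' reference when it was computed).
#'
#' @param object A `sparsity_curve` tibble from [sparsity_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sparsity_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$sparsity, y = .data$value, colour = .data$network
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "sparsity", y = "metric value", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot permutation-test differences across sparsity
#'
#' Observed between-network differences per metric, with significant
#' sparsity levels (p below the sweep's alpha) highlighted.
#'
#' @param object A `perm_sweep` tibble from [sweep_tests()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.perm_sweep <- function(object, ...) {
  alpha <- attr(object, "alpha") %||% 0.001
  ggplot2::ggplot(object, ggplot2::aes(x = .data$sparsity, y = .data$observed_diff)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant), size = 1) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey40", `TRUE` = "red3"),
      labels = c(`FALSE` = "n.s.", `TRUE` = sprintf("p < %g", alpha))
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "sparsity", y = "observed difference (network A - B)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the sorted degree-difference envelope
#'
#' Observed sorted degree differences against the permutation null band
#' (min/max over scrambled pairs); ranks outside the band are highlighted.
#'
#' @param object A `degree_envelope` tibble from [degree_envelope()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.degree_envelope <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rank)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$null_min, ymax = .data$null_max),
      fill = "grey80"
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed)) +
    ggplot2::geom_point(
      data = function(d) d[d$exceeds, , drop = FALSE],
      ggplot2::aes(y = .data$observed), colour = "red3", size = 1.2
    ) +
    ggplot2::labs(
      x = "rank (sorted)", y = "degree difference (A - B)",
      title = sprintf("Sorted degree differences, sparsity %.2f",
                      attr(object, "sparsity") %||% NA)
    ) +
    ggplot2::theme_minimal()
}
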