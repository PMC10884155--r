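# ggplot2 views of the main result types.

#' Scatter plot of openness calls
#'
#' Per-peak condition A vs condition B RP10M signal (log10 with a
#' pseudocount), coloured by openness label, with the background threshold
#' drawn on both axes.
#'
#' @param calls an `openness_calls` tibble.
#' @return A ggplot object.
#' @export
plot_openness <- function(calls) {
  thr <- attr(calls, "threshold")
  ggplot2::ggplot(tidy(calls),
                  ggplot2::aes(x = log10(.data$signal_a + 1),
                               y = log10(.data$signal_b + 1),
                               colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = log10(thr + 1), linetype = "dashed") +
    ggplot2::geom_hline(yintercept = log10(thr + 1), linetype = "dashed") +
    ggplot2::labs(x = "condition A signal, log10(RP10M + 1)",
                  y = "condition B signal, log10(RP10M + 1)",
                  colour = "cluster",
                  title = "Chromatin openness dichotomization") +
    ggplot2::theme_minimal()
}

#' @rdname plot_openness
#' @param object an `openness_calls` tibble.
#' @param ... unused.
#' @export
autoplot.openness_calls <- function(object, ...) plot_openness(object)

#' ABC score vs element-TSS distance
#'
#' @param pairs pair tibble from [abc_scores()].
#' @param threshold score threshold to draw (default 0.02).
#' @return A ggplot object.
#' @export
plot_abc_pairs <- function(pairs, threshold = 0.02) {
  ggplot2::ggplot(pairs,
                  ggplot2::aes(x = .data$distance / 1000, y = .data$abc_score,
                               colour = .data$is_promoter)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "element-TSS distance (kb)", y = "ABC score",
                  colour = "promoter element",
                  title = "Activity-by-Contact enhancer-gene scores") +
    ggplot2::theme_minimal()
}

#' Knockdown vs wild-type differentiation response
#'
#' Per-gene KD log2 change against WT log2 change, coloured by cluster,
#' with the identity and attenuation-cutoff lines.
#'
#' @param calls a `kd_response_calls` tibble.
#' @return A ggplot object.
#' @export
plot_kd_response <- function(calls) {
  cutoff <- attr(calls, "attenuation_cutoff")
  ggplot2::ggplot(tidy(calls),
                  ggplot2::aes(x = .data$wt_delta, y = .data$kd_delta,
                               colour = .data$cluster)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_abline(slope = cutoff, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "WT log2(NPC/ESC)", y = "KD log2(NPC/ESC)",
                  colour = "cluster",
                  title = "Knockdown-response classification") +
    ggplot2::theme_minimal()
}

#' @rdname plot_kd_response
#' @param object a `kd_response_calls` tibble.
#' @param ... unused.
#' @export
autoplot.kd_response_calls <- function(object, ...) plot_kd_response(object)
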