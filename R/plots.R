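# ggplot2 displays. Parameter estimation always happens in untransformed
# space; reciprocal space is used for display because intersection families
# are what the eye (and the classifier) reads there.

#' Double-reciprocal (Lineweaver-Burk) plot of an initial-velocity dataset
#'
#' @param data Data frame with the varied substrate, co-substrate and `v`.
#' @param varied,fixed Column names (defaults `"a"`, `"b"`).
#' @return A ggplot: 1/v against 1/\[varied\], one line per co-substrate
#'   level.
#' @export
plot_double_reciprocal <- function(data, varied = "a", fixed = "b") {
  data <- dplyr::mutate(data,
    inv_s = 1 / .data[[varied]], inv_v = 1 / .data$v,
    series = factor(.data[[fixed]]))
  ggplot2::ggplot(data, ggplot2::aes(.data$inv_s, .data$inv_v,
                                     colour = .data$series)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, fullrange = TRUE) +
    ggplot2::labs(x = paste0("1/[", varied, "] (mM^-1)"), y = "1/v",
                  colour = paste0("[", fixed, "] (mM)")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pk_fit <- function(object, ...) {
  d <- augment(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$.fitted, .data$v)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "fitted velocity", y = "observed velocity",
                  title = paste("model:", object$model)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pk_qseries <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$q)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.7, linetype = 2, colour = "grey50") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "time (frames)", y = "Q (fraction of native contacts)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pk_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(factor(.data$position), .data$frequency,
                               fill = .data$residue)) +
    ggplot2::geom_col(colour = "grey30", linewidth = 0.2) +
    ggplot2::labs(x = "reference position", y = "relative frequency") +
    ggplot2::theme_minimal()
}
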