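# ggplot2 displays of consensus assignments and evaluation reports.

#' Plot a consensus assignment
#'
#' Per-residue assignment support, colored by reliability class; one
#' facet per nucleus.
#'
#' @param object A `consensus_assignment` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot consensus_assignment
#' @export
autoplot.consensus_assignment <- function(object, ...) {
  df <- object[object$class != "unassigned", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$residue_number,
                                   y = .data$support,
                                   colour = .data$class)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.7, size = 1) +
    ggplot2::geom_hline(yintercept = 0.8, linetype = 2, colour = "grey40") +
    ggplot2::facet_wrap(~nucleus, ncol = 1) +
    ggplot2::scale_colour_manual(values = c(strong = "#1b7837",
                                            weak = "#d6604d")) +
    ggplot2::labs(x = "residue", y = "consensus support",
                  colour = "class",
                  title = "Multi-run assignment consensus") +
    ggplot2::theme_minimal()
}

#' Plot an evaluation report
#'
#' Histogram of assignment deviations from the reference per nucleus,
#' with the tolerance marked.
#'
#' @param object An `eval_report` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  df <- object$detail[!is.na(object$detail$reference), ]
  df$deviation <- df$shift - df$reference
  tol <- tibble::tibble(nucleus = c("1H", "13C", "15N"),
                        tol = c(0.03, 0.4, 0.4))
  tol <- tol[tol$nucleus %in% df$nucleus, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$deviation,
                                   fill = .data$correct)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::geom_vline(data = tol, ggplot2::aes(xintercept = .data$tol),
                        linetype = 2) +
    ggplot2::geom_vline(data = tol, ggplot2::aes(xintercept = -.data$tol),
                        linetype = 2) +
    ggplot2::facet_wrap(~nucleus, scales = "free") +
    ggplot2::labs(x = "assigned - reference (ppm)", fill = "correct",
                  title = "Assignment deviations vs reference") +
    ggplot2::theme_minimal()
}

#' Strong-fraction accuracy estimate curve
#'
#' The two empirical linear estimators of assignment accuracy as a
#' function of the strong percentage, with a marker at the supplied
#' value.
#'
#' @param S Optional strong percentage to mark.
#' @return A ggplot object.
#' @export
plot_accuracy_estimate <- function(S = NULL) {
  grid <- estimate_accuracy(seq(0, 100, by = 1))
  long <- tidyr::pivot_longer(grid, c("A", "A_strong"),
                              names_to = "estimator", values_to = "accuracy")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$S, y = .data$accuracy,
                                          colour = .data$estimator)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "strong assignments S (%)",
                  y = "estimated accuracy (%)") +
    ggplot2::theme_minimal()
  if (!is.null(S)) {
    pt <- estimate_accuracy(S)
    p <- p + ggplot2::geom_point(data = tibble::tibble(
      S = c(S, S), accuracy = c(pt$A, pt$A_strong),
      estimator = c("A", "A_strong")), size = 2)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
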