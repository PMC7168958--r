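#' Plot per-fold AUROCs of a LOPO evaluation
#'
#' @param object A `wp_lopo` object.
#' @param ... Unused.
#' @return A ggplot: one point per left-out participant with the fold mean
#'   and its 95% t-interval.
#' @export
autoplot.wp_lopo <- function(object, ...) {
  df <- tidy(object)
  g <- glance(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$left_out, y = .data$auroc)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted", colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = g$mean_auroc, colour = "steelblue") +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf, ymin = g$ci_lo,
                      ymax = g$ci_hi, alpha = 0.15, fill = "steelblue") +
    ggplot2::labs(x = "left-out participant", y = "AUROC",
                  title = sprintf("%s (%s): mean AUROC %.2f",
                                  attr(object, "symptom"),
                                  attr(object, "mode"), g$mean_auroc)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a condition comparison
#'
#' @param object A `wp_comparison` object.
#' @param ... Unused.
#' @return A ggplot: per-fold AUROC lines across conditions (the paired
#'   structure the rmANOVA exploits) with condition means.
#' @export
autoplot.wp_comparison <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::bind_cols(tibble::tibble(left_out = rownames(object$auroc)),
                     tibble::as_tibble(object$auroc)),
    -"left_out", names_to = "condition", values_to = "auroc")
  df$condition <- factor(df$condition, levels = object$conditions)
  means <- tibble::tibble(
    condition = factor(object$conditions, levels = object$conditions),
    auroc = colMeans(object$auroc))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$auroc)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$left_out),
                       colour = "grey70", alpha = 0.7) +
    ggplot2::geom_point(colour = "grey40", alpha = 0.7) +
    ggplot2::geom_point(data = means, colour = "firebrick", size = 3) +
    ggplot2::geom_line(data = means, ggplot2::aes(group = 1),
                       colour = "firebrick") +
    ggplot2::labs(x = object$factor, y = "AUROC",
                  subtitle = sprintf("rmANOVA F(%d, %d) = %.2f, p = %.3g",
                                     object$anova$df1, object$anova$df2,
                                     object$anova$F, object$anova$p)) +
    ggplot2::theme_minimal()
}

#' Plot a computation-time versus AUROC Pareto frontier
#'
#' @param object A `wp_pareto` object from [pareto_filter()].
#' @param ... Unused.
#' @return A ggplot: all feature-set entries (discarded in grey) with the
#'   retained frontier drawn as a step line, log-scaled time axis.
#' @export
autoplot.wp_pareto <- function(object, ...) {
  df <- tibble::as_tibble(object)
  front <- df[df$retained, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_time_ms,
                                   y = .data$mean_auroc)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$retained)) +
    ggplot2::geom_step(data = front, colour = "firebrick") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), vjust = -0.8,
                       size = 2.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey60")) +
    ggplot2::labs(x = "computation time (ms, log scale)", y = "mean AUROC",
                  colour = "retained") +
    ggplot2::theme_minimal()
}
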