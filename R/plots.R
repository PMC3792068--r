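#' Plot a Kaplan-Meier curve
#'
#' Step-function survival curves per group, with censoring marks.
#'
#' @param object A `km_curve` from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot km_curve
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- as_tibble(object)
  # prepend S(0) = 1 for each group so the step starts at the origin
  origins <- df %>%
    group_by(.data$group) %>%
    summarise(time = 0, surv = 1, n_censor = 0L, .groups = "drop")
  steps <- bind_rows(origins, df[, c("group", "time", "surv", "n_censor")]) %>%
    arrange(.data$group, .data$time)
  ggplot2::ggplot(steps, ggplot2::aes(x = .data$time, y = .data$surv,
                                      colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = dplyr::filter(steps, .data$n_censor > 0),
                        shape = 3) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Surgery-free probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a ratio marker by group
#'
#' @param object A `ratio_marker`.
#' @param ... Unused.
#' @return A ggplot box plot of the per-sample ratio by group.
#' @method autoplot ratio_marker
#' @export
autoplot.ratio_marker <- function(object, ...) {
  lbl <- paste0("Glycan ratio m/z ", object$numerator$label, "/",
                object$denominator$label)
  ggplot2::ggplot(object$ratios,
                  ggplot2::aes(x = .data$group, y = .data$ratio,
                               fill = .data$group)) +
    ggplot2::geom_boxplot(alpha = 0.6, outlier.shape = 1) +
    ggplot2::labs(x = NULL, y = lbl,
                  subtitle = sprintf("AUROC %.3f", object$auroc)) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Volcano-style plot of the differential screen
#'
#' Log2 fold change of group means against -log10 p, with the Bonferroni
#' threshold drawn and significant glycans highlighted.
#'
#' @param results Tibble from [differential_expression()].
#' @return A ggplot object.
#' @export
plot_differential <- function(results) {
  df <- dplyr::mutate(results,
                      log2fc = log2(.data$mean_case / .data$mean_control))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc, y = -log10(.data$p),
                                   colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(df$p_threshold[1]),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2(case mean / control mean)",
                  y = expression(-log[10] ~ p),
                  colour = "Bonferroni\nsignificant") +
    ggplot2::theme_minimal()
}
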