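#' Angle-versus-setting chart
#'
#' Measured indicator angles per true setting with mean +/- SD error bars and
#' the 45-degree zone cutoffs as horizontal reference lines.
#'
#' @param records Data frame with `truth_setting` and `angle_deg`.
#' @return A ggplot object.
#' @export
plot_angle_summary <- function(records) {
  summ <- angle_summary(records)
  pts <- dplyr::filter(records, !is.na(.data$angle_deg))
  ggplot2::ggplot(pts, ggplot2::aes(x = factor(.data$truth_setting,
                                               levels = 1:8),
                                    y = .data$angle_deg)) +
    ggplot2::geom_hline(yintercept = seq(-90, 270, by = 45),
                        linetype = "dotted", colour = "grey60") +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.4, colour = "grey40") +
    ggplot2::geom_pointrange(data = summ,
                             ggplot2::aes(x = factor(.data$setting, levels = 1:8),
                                          y = .data$mean_angle,
                                          ymin = .data$mean_angle - dplyr::coalesce(.data$sd_angle, 0),
                                          ymax = .data$mean_angle + dplyr::coalesce(.data$sd_angle, 0)),
                             shape = 21, fill = "white") +
    ggplot2::labs(x = "valve setting", y = "indicator angle (deg)") +
    ggplot2::theme_minimal()
}

#' Confusion-matrix heatmap
#'
#' @param x A `setting_confusion` (or an `eval_report`, whose confusion
#'   matrix is used).
#' @return A ggplot object.
#' @export
plot_confusion <- function(x) {
  if (inherits(x, "eval_report")) x <- x$confusion
  stopifnot(inherits(x, "setting_confusion"))
  df <- as.data.frame(as.table(x$matrix))
  names(df) <- c("true", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted,
                                   y = factor(.data$true, levels = rev(1:8)),
                                   fill = .data$count)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$count > 0,
                                                   .data$count, "")),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted setting", y = "true setting",
                  fill = "cases") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot an evaluation report
#'
#' @param object An `eval_report`.
#' @param type `"confusion"` (default) or `"angles"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, type = c("confusion", "angles"), ...) {
  type <- match.arg(type)
  if (type == "confusion") return(plot_confusion(object))
  if (is.null(object$angles))
    abort("report was built without angle records")
  summ <- object$angles
  records <- tibble::tibble(truth_setting = rep(summ$setting, summ$n),
                            angle_deg = rep(summ$mean_angle, summ$n))
  plot_angle_summary(records)
}
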