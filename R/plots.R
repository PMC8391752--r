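## ggplot2 views of the main result objects

#' @export
autoplot.fld_selection <- function(object, top = 20, ...) {
  d <- head(object$ranking, top)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$score,
    y = stats::reorder(.data$feature, .data$score)
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = if (object$method == "opr") "single-feature accuracy" else
        "running accuracy",
      y = NULL,
      title = sprintf("%s feature ranking (%s)", toupper(object$method),
                      object$classifier)
    )
}

#' @export
autoplot.fld_sweep <- function(object, ...) {
  d <- tidy(object)
  d$window <- sprintf("%d-%d", d$window_start, d$window_end)
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$window, .data$window_start),
    y = .data$accuracy, group = 1
  )) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$best), size = 3) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "steelblue"),
                                 guide = "none") +
    ggplot2::labs(x = "training window",
                  y = sprintf("accuracy on %d", object$test_year),
                  title = "Training-window sweep")
}

#' @export
autoplot.fld_cohort_summary <- function(object, ...) {
  ggplot2::ggplot(object$yearly_class_ratios, ggplot2::aes(
    x = .data$visit_year, y = .data$ratio, colour = .data$gender
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "visit year", y = "NFLD/FLD class-size ratio",
                  title = "Class balance per year")
}

#' @export
autoplot.fld_seq_model <- function(object, ...) {
  d <- tidyr::pivot_longer(object$history, -"epoch",
                           names_to = "series", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2,
                        colour = "firebrick") +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::labs(title = sprintf("Training history (%s)", object$family),
                  subtitle = sprintf("best epoch %d", object$best_epoch))
}
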