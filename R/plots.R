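#' Plot one pressure frame as a heat map
#'
#' Displays a sensor grid with the lateral axis (columns) horizontal and the
#' front of the seat at the top, the orientation the feature definitions
#' assume.
#'
#' @param seq A [pressure_sequence()].
#' @param t Frame index to display (default 1).
#' @return A ggplot object.
#' @export
plot_pressure_frame <- function(seq, t = 1) {
  fr <- get_frame(seq, t)
  df <- tidyr::expand_grid(row = seq_len(nrow(fr)), col = seq_len(ncol(fr)))
  df$pressure <- fr[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$pressure)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "lateral (column)", y = "longitudinal (row, front up)",
                  fill = "pressure",
                  title = sprintf("Frame %d (%s)", t, seq$meta$label))
}

#' Plot the centre-of-pressure trajectory of a trial
#'
#' @param seq A [pressure_sequence()].
#' @param axis_mode Passed to [frame_series()].
#' @return A ggplot object showing the lateral and longitudinal COP over
#'   time.
#' @export
plot_cop_series <- function(seq, axis_mode = "semantic") {
  fs <- frame_series(seq, axis_mode)
  long <- tidyr::pivot_longer(fs[c("time", "lat_cop", "lon_cop")],
                              -"time", names_to = "axis",
                              values_to = "cop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$cop,
                                     colour = .data$axis)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "centre of pressure (sensor units)",
                  colour = NULL,
                  title = sprintf("COP trajectory (%s)", seq$meta$label))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heat-map display of a confusion matrix
#'
#' @param object A [confusion()] matrix.
#' @param ... Unused.
#' @return A ggplot tile plot with counts annotated.
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(object)))
  names(df) <- c("truth", "predicted", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_y_discrete(limits = rev(rownames(object))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted", y = "truth", fill = "count")
}

#' Per-fold macro-F1 display of a cross-validation result
#'
#' @param object A `cv_result` from [cross_validate()].
#' @param ... Unused.
#' @return A ggplot bar chart of per-class F1 by fold.
#' @export
autoplot.cv_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$fold), y = .data$f1,
                                   fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "fold", y = "F1-score", fill = "class",
                  title = sprintf("%s, subject-grouped CV",
                                  object$classifier))
}

#' Ave-RMS bar chart by side
#'
#' Displays the across-subject mean RMS per muscle and movement, split by
#' body side, with SD error bars — the summary used to contrast affected-
#' and healthy-side trunk-muscle activity.
#'
#' @param ave An [ave_rms()] tibble.
#' @return A ggplot object.
#' @export
plot_ave_rms <- function(ave) {
  ggplot2::ggplot(ave, ggplot2::aes(x = .data$channel, y = .data$ave_rms,
                                    fill = .data$side)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ave_rms - .data$sd_rms,
                   ymax = .data$ave_rms + .data$sd_rms),
      position = ggplot2::position_dodge(width = 0.9), width = 0.3) +
    ggplot2::facet_wrap(~label) +
    ggplot2::labs(x = "muscle", y = "Ave-RMS", fill = "side")
}
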