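#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a stitched environmental series
#'
#' Lines coloured by source installation, with gaps shaded — the classic
#' "temperature as sensed by the plant" figure for an object moved between
#' installations.
#'
#' @param object a `stitched_series` from [stitch()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.stitched_series <- function(object, ...) {
  df <- tibble::as_tibble(object)
  gaps <- attr(object, "gaps")
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$timestamp, y = .data$value,
    colour = .data$location, group = .data$interval_start
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = NULL, y = attr(object, "variable"),
      title = paste("Series sensed by", attr(object, "object")),
      colour = "location"
    ) +
    ggplot2::theme_minimal()
  if (nrow(gaps)) {
    p <- p + ggplot2::geom_rect(
      data = gaps,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "grey40",
      inherit.aes = FALSE
    )
  }
  p
}

#' Plot a thermal-time accumulation
#'
#' @param object a `thermal_time` tibble from [thermal_time()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.thermal_time <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$date, y = .data$thermal_time)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(
      data = df[df$no_data, ],
      ggplot2::aes(y = .data$thermal_time),
      shape = 4, colour = "red"
    ) +
    ggplot2::labs(
      x = NULL, y = "thermal time (degree-days)",
      title = paste(
        "Thermal time for", attr(object, "object"),
        "- base", attr(object, "base_temp")
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot an outlier report
#'
#' Replicate summaries with flagged members highlighted.
#'
#' @param object an `outlier_report` from [flag_outliers()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.outlier_report <- function(object, ...) {
  df <- object$scores
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$member, y = .data$value, colour = .data$flagged
  )) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "red")) +
    ggplot2::labs(
      x = NULL, y = "replicate summary",
      title = paste0(
        "Replicate screen (", object$method,
        ", threshold ", object$threshold, ")"
      )
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
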