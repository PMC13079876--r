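#' Plot a reference cell-cycle curve
#'
#' @param object A `fucci_reference`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fucci_reference <- function(object, ...) {
  chans <- setdiff(names(object), "percentage")
  long <- as_tibble(object) |>
    tidyr::pivot_longer(dplyr::all_of(chans),
                        names_to = "channel", values_to = "intensity")
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$percentage, y = .data$intensity, colour = .data$channel
  )) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(cyan = "#00ced1", magenta = "#d02090"),
      na.value = "grey40"
    ) +
    ggplot2::labs(
      x = "cell-cycle percentage", y = "mean nuclear intensity (a.u.)",
      title = sprintf("Reference curve (%d source track(s))",
                      attr(object, "n_source_tracks"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot pseudotime against frame for an alignment
#'
#' @param object A `fucci_alignment` or `fucci_alignment_set`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fucci_alignment <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$frame, y = .data$pseudotime)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = "frame", y = "cell-cycle percentage (pseudotime)",
      title = sprintf(
        "Track %s/%s: relative time distortion %.2f%s",
        object$track_id, object$branch, object$relative_time_distortion,
        if (isTRUE(object$arrested)) " (arrested)" else ""
      )
    ) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.fucci_alignment
#' @export
autoplot.fucci_alignment_set <- function(object, ...) {
  td <- tidy(object) |>
    mutate(track = paste(.data$track_id, .data$branch, sep = "/"))
  ggplot2::ggplot(td, ggplot2::aes(
    x = .data$frame, y = .data$pseudotime,
    group = .data$track, colour = .data$arrested
  )) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(
      x = "frame", y = "cell-cycle percentage (pseudotime)",
      colour = "arrested"
    ) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Histogram of relative time-distortion values
#'
#' The per-track arrest score with the threshold drawn as a vertical line;
#' a bimodal histogram indicates a mixed cycling/arrested population.
#'
#' @param alignments A `fucci_alignment_set` (or its [glance()] tibble).
#' @param threshold Arrest threshold to draw (default 5).
#' @param bins Histogram bins.
#' @return A ggplot.
#' @export
plot_distortion_histogram <- function(alignments, threshold = 5, bins = 30) {
  gl <- if (inherits(alignments, "fucci_alignment_set")) {
    glance(alignments)
  } else {
    alignments
  }
  ggplot2::ggplot(gl, ggplot2::aes(x = .data$relative_time_distortion)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey60", colour = "grey30") +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed") +
    ggplot2::labs(
      x = "relative time distortion", y = "tracks",
      title = "Arrest score distribution"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
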