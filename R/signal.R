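#' Extract per-track mean nuclear intensities
#'
#' For every spot and channel, averages the image pixels of the spot's mask
#' instance in that frame. A spot's mask is its `label` value if non-zero,
#' otherwise the label found at the spot's rounded `(y, x)` position (spots
#' produced by a tracker sit inside their mask). Interpolated spots (from
#' [close_track_gaps()]) have no mask and yield missing values, which are
#' filled by linear interpolation over time when `fill_gaps = TRUE`.
#'
#' @param labels Label stack, 3-axis integer array `(time, y, x)`.
#' @param images A [image_stack()] with the same `(time, y, x)` shape.
#' @param tracks Spot table (see [read_trackmate_xml()]).
#' @param fill_gaps Fill missing means by linear interpolation per track,
#'   branch and channel (default `TRUE`).
#' @return A tibble with one row per spot: `track_id`, `branch`, `frame`,
#'   `x`, `y`, `label`, `interpolated`, plus one mean-intensity column per
#'   channel of `images`.
#' @export
extract_nuclear_intensities <- function(labels, images, tracks, fill_gaps = TRUE) {
  assert_label_stack(labels)
  stopifnot(inherits(images, "fucci_stack"))
  assert_tracks_tbl(tracks)
  d <- dim(images$data)
  if (!all(dim(labels) == d[c(1, 3, 4)])) {
    stop_fucci("labels and images must share their (time, y, x) shape", "bad_input")
  }
  if (is.null(tracks$interpolated)) tracks$interpolated <- FALSE
  if (is.null(tracks$label)) tracks$label <- 0L

  n_ch <- d[[2]]
  chan_cols <- images$channels
  out <- tracks
  for (ch in chan_cols) out[[ch]] <- NA_real_

  for (t_frame in sort(unique(out$frame))) {
    t_idx <- t_frame + 1L
    if (t_idx < 1 || t_idx > d[[1]]) {
      warn(sprintf("frame %d outside the image stack; intensities left missing", t_frame))
      next
    }
    rows <- which(out$frame == t_frame & !out$interpolated)
    if (length(rows) == 0) next
    lab_frame <- labels[t_idx, , ]
    # resolve unknown labels from the spot position
    lv <- out$label[rows]
    need <- lv == 0L
    if (any(need)) {
      yy <- pmin(pmax(round(out$y[rows[need]]) + 1L, 1L), d[[3]])
      xx <- pmin(pmax(round(out$x[rows[need]]) + 1L, 1L), d[[4]])
      lv[need] <- lab_frame[cbind(yy, xx)]
      out$label[rows] <- lv
    }
    present <- lab_frame[lab_frame > 0]
    idx <- which(lab_frame > 0)
    for (c_idx in seq_len(n_ch)) {
      img <- images$data[t_idx, c_idx, , ]
      means <- tapply(img[idx], present, mean)
      hit <- match(as.character(lv), names(means))
      vals <- as.numeric(means[hit])
      miss <- which(is.na(vals) & lv > 0)
      if (length(miss) > 0 && c_idx == 1) {
        warn(sprintf(
          "frame %d: %d spot label(s) absent from the label image; intensities left missing",
          t_frame, length(miss)
        ))
      }
      out[rows, chan_cols[[c_idx]]] <- vals
    }
  }

  out <- out |>
    select(
      "track_id", "branch", "frame", "x", "y", "label", "interpolated",
      dplyr::all_of(chan_cols)
    ) |>
    arrange(.data$track_id, .data$branch, .data$frame)

  if (fill_gaps) {
    out <- out |>
      group_by(.data$track_id, .data$branch) |>
      mutate(across(
        dplyr::all_of(chan_cols),
        ~ fill_na_linear(.x, .data$frame)
      )) |>
      ungroup()
  }
  out
}

fill_na_linear <- function(v, frames) {
  ok <- !is.na(v)
  if (all(ok) || sum(ok) < 2) {
    return(v)
  }
  stats::approx(frames[ok], v[ok], xout = frames, rule = 2)$y
}

#' Frame-wise percentile normalization
#'
#' Maps each frame and channel affinely so the `p_low` percentile goes to 0
#' and `p_high` to 1, then clips to `[0, 1]`. This is the stand-in intensity
#' normalization used when no flat-field correction has been applied;
#' extracted FUCCI intensities only reflect the cycle when the background is
#' stationary across frames.
#'
#' @param images A [image_stack()].
#' @param p_low,p_high Percentiles in `[0, 100]`, `p_low < p_high`.
#' @return A new [image_stack()] with values in `[0, 1]`.
#' @export
percentile_normalize_frames <- function(images, p_low = 1, p_high = 99) {
  stopifnot(inherits(images, "fucci_stack"))
  if (!(p_low >= 0 && p_low < p_high && p_high <= 100)) {
    stop_fucci("need 0 <= p_low < p_high <= 100", "bad_input")
  }
  d <- dim(images$data)
  out <- images$data
  for (t in seq_len(d[[1]])) {
    for (c in seq_len(d[[2]])) {
      v <- images$data[t, c, , ]
      q <- stats::quantile(v, c(p_low, p_high) / 100, names = FALSE)
      if (q[[2]] <= q[[1]]) {
        warn(sprintf(
          "frame %d channel %s is constant at the chosen percentiles; mapped to zero",
          t - 1L, images$channels[[c]]
        ))
        out[t, c, , ] <- 0
      } else {
        out[t, c, , ] <- pmin(pmax((v - q[[1]]) / (q[[2]] - q[[1]]), 0), 1)
      }
    }
  }
  image_stack(out, images$channels, images$pixel_size, images$frame_interval)
}

#' Signal transforms for DTW preprocessing
#'
#' `smooth_signal()` is a centred moving average whose window shrinks at the
#' boundaries (the first and last points average over the available
#' neighbourhood only). `zscore_signal()` standardizes to mean 0, sd 1 over
#' the track, compensating for intensity differences between individual
#' nuclei. `derivative_signal()` is the first difference (length `n - 1`).
#'
#' @param x Numeric vector.
#' @param window Odd integer window length (1 = identity).
#' @return Numeric vector.
#' @export
smooth_signal <- function(x, window = 5L) {
  if (window %% 2 != 1 || window < 1) {
    stop_fucci("smoothing window must be an odd integer >= 1", "bad_input")
  }
  n <- length(x)
  if (window == 1 || n == 0) {
    return(x)
  }
  h <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}

#' @rdname smooth_signal
#' @export
zscore_signal <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop_fucci(
      paste(
        "zero-variance signal cannot be z-scored;",
        "constant (DARK) tracks should be excluded from alignment"
      ),
      "zero_variance"
    )
  }
  (x - mean(x)) / s
}

#' @rdname smooth_signal
#' @export
derivative_signal <- function(x) {
  if (length(x) < 2) {
    stop_fucci("derivative requires at least 2 samples", "bad_input")
  }
  diff(x)
}

#' Build a DTW feature sequence from an intensity track
#'
#' Applies, in this order: smoothing, per-track z-score normalization, and
#' first differencing, so that the alignment distance is computed on the
#' normalized signal derivative. The same transform must be applied to query
#' tracks and to the reference curve. The order and parameters are recorded
#' in the `provenance` attribute for auditability.
#'
#' @param track Intensity track tibble (one branch) with the channel column.
#' @param channel Channel column name (e.g. `"cyan"`).
#' @param window Smoothing window, odd integer (default 5 frames).
#' @return A `fucci_features` object: numeric matrix (one column per
#'   requested channel, `length(frames) - 1` rows) with a `provenance`
#'   attribute.
#' @export
preprocess_for_dtw <- function(track, channel = "cyan", window = 5L) {
  if (!all(channel %in% names(track))) {
    stop_fucci(
      sprintf("channel column(s) not found: %s",
              paste(setdiff(channel, names(track)), collapse = ", ")),
      "bad_input"
    )
  }
  n <- nrow(track)
  if (n < window + 1) {
    stop_fucci(
      sprintf("track of %d frames is too short for window %d", n, window),
      "bad_input"
    )
  }
  values <- vapply(
    channel,
    function(ch) derivative_signal(zscore_signal(smooth_signal(track[[ch]], window))),
    numeric(n - 1)
  )
  fucci_features(
    matrix(values, ncol = length(channel), dimnames = list(NULL, channel)),
    provenance = c(
      paste0("channel:", paste(channel, collapse = "+")),
      sprintf("smooth(window=%d)", window), "zscore", "derivative"
    )
  )
}

#' @param values Numeric matrix (samples x features).
#' @param provenance Character vector describing applied transforms.
#' @rdname preprocess_for_dtw
#' @export
fucci_features <- function(values, provenance = character()) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) {
    stop_fucci("feature sequences must be finite", "bad_input")
  }
  structure(values, provenance = provenance, class = c("fucci_features", class(values)))
}
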