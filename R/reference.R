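#' Build a reference cell-cycle curve from full-cycle tracks
#'
#' Each input track must span exactly one full cycle (mitosis to mitosis).
#' Tracks are resampled by linear interpolation onto a common cell-cycle
#' percentage grid (0 to 100) and averaged point-wise per channel, giving the
#' average FUCCI dynamics over one cycle against which query tracks are
#' aligned.
#'
#' @param tracks Intensity-track tibble; tracks are identified by
#'   `(track_id, branch)` and must each have at least 10 frames.
#' @param channels Channel columns to average (default cyan + magenta).
#' @param n_points Number of percentage grid points (default 101, i.e. 1%
#'   resolution).
#' @param frame_interval Optional minutes per frame, kept as metadata so
#'   percentages can be converted to absolute time.
#' @return A `fucci_reference` tibble with a `percentage` column and one
#'   column per channel; attributes `n_source_tracks` and `frame_interval`.
#' @export
build_reference_curve <- function(tracks, channels = c("cyan", "magenta"),
                                  n_points = 101L, frame_interval = NULL) {
  if (nrow(tracks) == 0) {
    stop_fucci("at least one full-cycle track is required", "bad_input")
  }
  if (!all(channels %in% names(tracks))) {
    stop_fucci(
      sprintf("channel column(s) not found: %s",
              paste(setdiff(channels, names(tracks)), collapse = ", ")),
      "bad_input"
    )
  }
  if (is.null(tracks$branch)) tracks$branch <- ""
  grid <- seq(0, 100, length.out = n_points)
  pieces <- tracks |>
    dplyr::group_split(.data$track_id, .data$branch)
  resampled <- purrr::map(pieces, function(tt) {
    tt <- tt[order(tt$frame), ]
    n <- nrow(tt)
    if (n < 10) {
      stop_fucci(
        sprintf("track %s has %d frames; full-cycle tracks need at least 10",
                tt$track_id[[1]], n),
        "bad_input"
      )
    }
    pct <- (seq_len(n) - 1) / (n - 1) * 100
    vapply(channels, function(ch) {
      stats::approx(pct, tt[[ch]], xout = grid)$y
    }, numeric(n_points))
  })
  avg <- Reduce(`+`, resampled) / length(resampled)
  out <- tibble(percentage = grid)
  for (i in seq_along(channels)) out[[channels[[i]]]] <- avg[, i]
  new_reference_curve(out, n_source_tracks = length(resampled),
                      frame_interval = frame_interval)
}

new_reference_curve <- function(tbl, n_source_tracks, frame_interval = NULL) {
  stopifnot(is.numeric(tbl$percentage))
  if (abs(tbl$percentage[[1]]) > 1e-9 ||
      abs(tbl$percentage[[nrow(tbl)]] - 100) > 1e-9) {
    stop_fucci("reference percentage must run from 0 to 100", "bad_input")
  }
  structure(
    tbl,
    n_source_tracks = n_source_tracks,
    frame_interval = frame_interval,
    class = c("fucci_reference", class(tibble()))
  )
}

#' Reference-curve CSV input/output
#'
#' The CSV carries a `percentage` column plus one column per channel, and a
#' comment header (`# key: value`) with the number of source tracks and the
#' optional frame interval in minutes.
#'
#' @param reference A `fucci_reference` (see [build_reference_curve()]).
#' @param path CSV file path.
#' @return `read_reference_curve()` returns a `fucci_reference`;
#'   `write_reference_curve()` returns `path` invisibly.
#' @export
write_reference_curve <- function(reference, path) {
  stopifnot(inherits(reference, "fucci_reference"))
  header <- c(
    sprintf("# n_source_tracks: %d", attr(reference, "n_source_tracks")),
    sprintf("# frame_interval: %s",
            if (is.null(attr(reference, "frame_interval"))) "NA"
            else attr(reference, "frame_interval"))
  )
  writeLines(header, path)
  readr::write_csv(as_tibble(reference), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_reference_curve
#' @export
read_reference_curve <- function(path) {
  lines <- readLines(path, n = 10)
  meta <- lines[startsWith(lines, "#")]
  get_meta <- function(key) {
    hit <- grep(sprintf("^# %s:", key), meta, value = TRUE)
    if (length(hit) == 0) {
      return(NA_character_)
    }
    trimws(sub(sprintf("^# %s:", key), "", hit[[1]]))
  }
  n_src <- suppressWarnings(as.integer(get_meta("n_source_tracks")))
  fi <- suppressWarnings(as.numeric(get_meta("frame_interval")))
  tbl <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  new_reference_curve(
    tbl,
    n_source_tracks = if (is.na(n_src)) 1L else n_src,
    frame_interval = if (is.na(fi)) NULL else fi
  )
}

# tile a reference end-to-start so queries straddling mitosis can match;
# percentages continue 100 -> 200 (reported modulo 100 downstream)
tile_reference <- function(reference, channels) {
  np <- nrow(reference)
  idx <- c(seq_len(np), seq(2L, np))
  out <- as_tibble(reference)[idx, c("percentage", channels)]
  out$percentage <- c(reference$percentage, 100 + reference$percentage[-1])
  out
}
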