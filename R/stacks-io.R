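#' Construct an image stack
#'
#' A light container for multichannel time-lapse data: a 4-axis array ordered
#' (time, channel, y, x) plus channel names and optional physical metadata.
#'
#' @param data Numeric 4-axis array `(time, channel, y, x)`, non-negative.
#' @param channels Character vector of channel names, one per channel.
#' @param pixel_size Optional pixel size in micrometres.
#' @param frame_interval Optional frame interval in minutes.
#' @return An object of class `fucci_stack`.
#' @export
image_stack <- function(data, channels, pixel_size = NULL, frame_interval = NULL) {
  if (!is.array(data) || length(dim(data)) != 4) {
    stop_fucci("image stack data must be a 4-axis (time, channel, y, x) array", "bad_input")
  }
  if (any(data < 0)) {
    stop_fucci("image intensities must be >= 0", "bad_input")
  }
  if (length(channels) != dim(data)[[2]]) {
    stop_fucci(
      sprintf(
        "%d channel names supplied for %d channels", length(channels), dim(data)[[2]]
      ),
      "bad_input"
    )
  }
  structure(
    list(
      data = data, channels = as.character(channels),
      pixel_size = pixel_size, frame_interval = frame_interval
    ),
    class = "fucci_stack"
  )
}

#' @export
print.fucci_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<fucci_stack> %d frame(s) x %d channel(s) [%s] x %d x %d px\n",
    d[[1]], d[[2]], paste(x$channels, collapse = ", "), d[[3]], d[[4]]
  ))
  invisible(x)
}

#' Read and write integer label stacks as multi-page TIFF
#'
#' Label stacks are (time, y, x) integer arrays with background 0. They are
#' stored as 16-bit multi-page TIFF (one page per frame) and round-trip
#' bit-exactly for label values up to 65535.
#'
#' @param path TIFF file path.
#' @return `read_label_stack()` returns a 3-axis integer array;
#'   `write_label_stack()` returns `path` invisibly.
#' @export
read_label_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  mats <- purrr::map(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    if (any(p < 0) || any(p != round(p))) {
      stop_fucci("label TIFF contains negative or non-integer values", "format")
    }
    p
  })
  out <- array(0L, dim = c(length(mats), nrow(mats[[1]]), ncol(mats[[1]])))
  for (t in seq_along(mats)) out[t, , ] <- as.integer(mats[[t]])
  out
}

#' @param labels 3-axis integer array `(time, y, x)`.
#' @rdname read_label_stack
#' @export
write_label_stack <- function(labels, path) {
  assert_label_stack(labels)
  if (max(labels) > 65535) {
    stop_fucci("label values above 65535 cannot be stored in 16-bit TIFF", "format")
  }
  pages <- purrr::map(seq_len(dim(labels)[[1]]), function(t) {
    matrix(labels[t, , ] / 65535, nrow = dim(labels)[[2]])
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read and write multichannel image stacks as multi-page TIFF
#'
#' Pages are time-major, channel-minor (frame 0 channel 1, frame 0 channel 2,
#' ...). Intensities are stored as 32-bit float rescaled to `[0, 1]` by the
#' stack maximum; fluorescence units are arbitrary, so the absolute scale is
#' not preserved (all downstream analysis is scale-invariant by design).
#'
#' @param path TIFF file path.
#' @param channels Channel names (their number determines the channel axis).
#' @inheritParams image_stack
#' @return `read_image_stack()` returns a [image_stack()] object;
#'   `write_image_stack()` returns `path` invisibly.
#' @export
read_image_stack <- function(path, channels) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  n_ch <- length(channels)
  if (length(pages) %% n_ch != 0) {
    stop_fucci(
      sprintf("%d TIFF pages are not divisible by %d channels", length(pages), n_ch),
      "format"
    )
  }
  n_t <- length(pages) %/% n_ch
  pg <- purrr::map(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  out <- array(0, dim = c(n_t, n_ch, nrow(pg[[1]]), ncol(pg[[1]])))
  k <- 1
  for (t in seq_len(n_t)) {
    for (c in seq_len(n_ch)) {
      out[t, c, , ] <- pg[[k]]
      k <- k + 1
    }
  }
  image_stack(out, channels)
}

#' @param images A [image_stack()] object.
#' @rdname read_image_stack
#' @export
write_image_stack <- function(images, path) {
  stopifnot(inherits(images, "fucci_stack"))
  d <- dim(images$data)
  scale <- max(images$data, 1e-12)
  pages <- list()
  k <- 1
  for (t in seq_len(d[[1]])) {
    for (c in seq_len(d[[2]])) {
      pages[[k]] <- matrix(images$data[t, c, , ] / scale, nrow = d[[3]])
      k <- k + 1
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read and write per-spot intensity tables
#'
#' One row per spot: `track`, `branch`, `frame`, `x`, `y`, `label`,
#' `interpolated`, then one intensity column per channel. CSV round-trips
#' exactly to printed precision.
#'
#' @param intensities Intensity table as returned by
#'   [extract_nuclear_intensities()].
#' @param path CSV file path.
#' @return `read_intensity_table()` returns a tibble;
#'   `write_intensity_table()` returns `path` invisibly.
#' @export
write_intensity_table <- function(intensities, path) {
  readr::write_csv(intensities, path)
  invisible(path)
}

#' @rdname write_intensity_table
#' @export
read_intensity_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE) |>
    mutate(
      across(dplyr::any_of(c("track_id", "frame", "label")), as.integer),
      across(dplyr::any_of("branch"), ~ dplyr::coalesce(as.character(.x), ""))
    )
}

phase_vocabulary <- c("G1", "G1S", "SG2M", "DARK")

check_phase_vocab <- function(phases) {
  bad <- setdiff(unique(phases), phase_vocabulary)
  if (length(bad) > 0) {
    stop_fucci(
      sprintf(
        "unknown phase label(s): %s; allowed values are %s",
        paste(bad, collapse = ", "), paste(phase_vocabulary, collapse = ", ")
      ),
      "vocabulary"
    )
  }
  invisible(phases)
}

#' Read and write phase-label JSON
#'
#' Phase annotations map a mask instance in a frame to a phase label. The
#' stored convention is a flat JSON object whose keys are `"frame_label"`
#' (0-based frame, underscore, mask label value) and whose values are one of
#' `G1`, `G1S`, `SG2M`, `DARK`. The key convention is a documented choice of
#' this package, not a published schema; pass `key_parser` to consume other
#' layouts.
#'
#' @param path JSON file path.
#' @param key_parser Function mapping one key string to a
#'   `c(frame, label)` integer vector. Defaults to splitting on `"_"`.
#' @return `read_phase_json()` returns a tibble with columns `frame`,
#'   `label`, `phase`; `write_phase_json()` returns `path` invisibly.
#' @examples
#' path <- tempfile(fileext = ".json")
#' writeLines('{"0_5": "G1"}', path)
#' read_phase_json(path)
#' @export
read_phase_json <- function(path, key_parser = NULL) {
  raw <- jsonlite::read_json(path)
  if (is.null(key_parser)) {
    key_parser <- function(key) {
      parts <- strsplit(key, "_", fixed = TRUE)[[1]]
      if (length(parts) != 2 || anyNA(suppressWarnings(as.integer(parts)))) {
        stop_fucci(
          sprintf("phase key '%s' does not follow the 'frame_label' convention", key),
          "format"
        )
      }
      as.integer(parts)
    }
  }
  phases <- as.character(unlist(raw))
  check_phase_vocab(phases)
  keys <- purrr::map(names(raw), key_parser)
  tibble(
    frame = purrr::map_int(keys, 1),
    label = purrr::map_int(keys, 2),
    phase = phases
  ) |>
    arrange(.data$frame, .data$label)
}

#' @param phases Tibble with columns `frame`, `label`, `phase`.
#' @rdname read_phase_json
#' @export
write_phase_json <- function(phases, path) {
  check_phase_vocab(phases$phase)
  obj <- as.list(stats::setNames(
    phases$phase,
    paste(phases$frame, phases$label, sep = "_")
  ))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
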