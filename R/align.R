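#' Alignment configuration
#'
#' @param channels Channel columns used as DTW features; with more than one
#'   channel the features are stacked into a multivariate sequence with L2
#'   local cost.
#' @param window Smoothing window in frames (odd, default 5).
#' @param threshold Arrest threshold on the relative time distortion
#'   (default 5, dataset-dependent; see [flag_arrest()]).
#' @param min_length Minimum query track length in frames (default 10).
#' @param tile Tile the reference end-to-start so queries straddling mitosis
#'   can match across the 100%/0% seam (default `TRUE`); pseudotime is
#'   reported modulo 100.
#' @param localize Run the window-localization scan before the DTW (default
#'   `TRUE`): the query is first located by comparing its per-window
#'   standardized shape against every equally long reference slice
#'   (each slice standardized the same way), which also yields a
#'   per-channel gain estimate used to put the query features on the
#'   reference's global scale. Without it, window-standardized query
#'   features are compared directly against the globally standardized
#'   reference, which is only reliable for near-full-cycle tracks.
#' @return A list of class `fucci_align_config`.
#' @export
align_config <- function(channels = c("cyan", "magenta"), window = 5L,
                         threshold = 5, min_length = 10L, tile = TRUE,
                         localize = TRUE) {
  structure(
    list(
      channels = channels, window = as.integer(window),
      threshold = threshold, min_length = as.integer(min_length),
      tile = isTRUE(tile), localize = isTRUE(localize)
    ),
    class = "fucci_align_config"
  )
}

# smoothed channel matrix plus noise diagnostics. The per-channel noise sd
# is estimated from the smoothing residual (high-frequency power); a
# channel is gated by the fraction of its windowed variance that exceeds
# three times the (smoothed) noise variance, so channels that carry only
# noise — a flat FUCCI reporter outside its expression window, or an
# arrested cell's plateau — contribute nothing to the alignment cost
# instead of being amplified to full scale by the standardization.
prep_channels <- function(tbl, channels, window, noiseless = FALSE) {
  n <- nrow(tbl)
  k <- length(channels)
  sm <- vapply(channels, function(ch) smooth_signal(tbl[[ch]], window), numeric(n))
  sm <- matrix(sm, ncol = k)
  sds <- apply(sm, 2, stats::sd)
  gates <- numeric(k)
  for (c in seq_len(k)) {
    if (noiseless || window == 1) {
      gates[[c]] <- as.numeric(sds[[c]] > 0)
    } else {
      resid <- tbl[[channels[[c]]]] - sm[, c]
      noise_var_sm <- stats::var(resid) / (1 - 1 / window) / window
      gates[[c]] <- sqrt(max(0, 1 - 3 * noise_var_sm / max(sds[[c]]^2, 1e-300)))
    }
  }
  # gated, centred channels on a shared scale: the largest gated channel sd.
  # A shared scale preserves the between-channel amplitude ratio (which a
  # per-channel standardization would erase) while removing the common
  # per-nucleus gain.
  centred <- sweep(sm, 2, colMeans(sm))
  gated <- sweep(centred, 2, gates, `*`)
  shared_sd <- max(apply(gated, 2, stats::sd))
  shape <- if (shared_sd > 0) {
    matrix(apply(gated / shared_sd, 2, diff), ncol = k)
  } else {
    matrix(0, n - 1, k)
  }
  list(sm = sm, sds = sds, gates = gates, shared_sd = shared_sd, shape = shape)
}

# localization scan: L2 between the query's gated shared-scale shape and
# every equally long reference slice transformed identically
localize_window <- function(q, smr, L) {
  m <- nrow(smr)
  k <- ncol(smr)
  n_starts <- m - L + 1
  costs <- numeric(n_starts)
  slice_scale <- numeric(n_starts)
  for (s in seq_len(n_starts)) {
    slice <- smr[s:(s + L - 1), , drop = FALSE]
    sc <- max(apply(slice, 2, stats::sd), 1e-12)
    slice_scale[[s]] <- sc
    centred <- sweep(slice, 2, colMeans(slice))
    sf <- matrix(apply(centred / sc, 2, diff), ncol = k)
    costs[[s]] <- sum((q$shape - sf)^2)
  }
  s_best <- which.min(costs)
  list(start = s_best, scale = slice_scale[[s_best]])
}

#' Align one intensity track to a reference cell-cycle curve
#'
#' The core analysis: the track's channels are smoothed, z-scored and
#' differenced ([preprocess_for_dtw()]), the reference curve is transformed
#' identically, and the query is located inside the reference by subsequence
#' DTW ([subsequence_dtw()]). Every frame then receives a cell-cycle
#' percentage (pseudotime) and the track receives a relative time-distortion
#' value; tracks whose distortion exceeds the threshold are flagged as
#' arrested. Because the features are normalized derivatives, the alignment
#' carries no information about absolute FUCCI intensities — high-distortion
#' alignments should be treated as unreliable rather than silently accepted,
#' which is exactly what the arrest flag surfaces.
#'
#' Zero-variance (DARK) channels cannot be z-scored; such tracks are
#' returned as unalignable (`alignable = FALSE`, `arrested = NA`) rather
#' than flagged as arrested.
#'
#' @param track Intensity track tibble for a single `(track_id, branch)`
#'   (columns `frame` plus the configured channels).
#' @param reference A `fucci_reference` (see [build_reference_curve()]).
#' @param config An [align_config()].
#' @return An object of class `fucci_alignment` with elements `track_id`,
#'   `branch`, `frames`, `pseudotime` (per frame), `path`, `distance`,
#'   `ref_window_pct`, `time_distortion`, `relative_time_distortion`,
#'   `arrested`, `alignable`.
#' @export
align_track <- function(track, reference, config = align_config()) {
  stopifnot(inherits(reference, "fucci_reference"))
  track <- track[order(track$frame), ]
  n <- nrow(track)
  if (n < config$min_length) {
    stop_fucci(
      sprintf("track of %d frames is shorter than min_length = %d", n, config$min_length),
      "bad_input"
    )
  }
  track_id <- if (!is.null(track$track_id)) track$track_id[[1]] else NA_integer_
  branch <- if (!is.null(track$branch)) track$branch[[1]] else ""

  q <- prep_channels(track, config$channels, config$window)
  if (all(q$sds == 0)) {
    # DARK track: no channel carries any variation, nothing to align
    return(new_alignment(
      track_id = track_id, branch = branch, frames = track$frame,
      alignable = FALSE, config = config
    ))
  }

  ref_tbl <- if (config$tile) {
    tile_reference(reference, config$channels)
  } else {
    as_tibble(reference)[, c("percentage", config$channels)]
  }
  r <- prep_channels(ref_tbl, config$channels, config$window, noiseless = TRUE)

  # reference features: per-channel globally standardized intensity plus its
  # derivative. The derivative carries the matching signal the method is
  # built on; the standardized intensity column anchors the path locally
  # (it has a far higher per-sample signal-to-noise ratio), which keeps the
  # warping from drifting on noisy derivatives.
  k <- length(config$channels)
  gmean <- colMeans(r$sm)
  r_z <- sweep(sweep(r$sm, 2, gmean), 2, pmax(r$sds, 1e-12), `/`)
  rf_full <- cbind(
    r_z[-nrow(r_z), , drop = FALSE],
    matrix(apply(r_z, 2, diff), ncol = k)
  )

  offset <- 0L
  n_q <- nrow(q$sm)
  if (config$localize && n_q <= nrow(r$sm)) {
    loc <- localize_window(q, r$sm, n_q)
    # per-nucleus gain from the matched slice; query channels are gated,
    # rescaled onto the reference's global per-channel scale, and shifted
    # to the matched slice's mean level on that scale
    alpha <- max(q$shared_sd / loc$scale, 1e-12)
    slice <- r$sm[loc$start:(loc$start + n_q - 1L), , drop = FALSE]
    off <- (colMeans(slice) - gmean) / pmax(r$sds, 1e-12)
    q_z <- sweep(
      sweep(q$sm, 2, colMeans(q$sm)), 2, pmax(r$sds, 1e-12), `/`
    ) / alpha
    q_z <- sweep(q_z, 2, q$gates, `*`)
    q_zo <- sweep(q_z, 2, off, `+`)
    qf <- cbind(
      q_zo[-nrow(q_zo), , drop = FALSE],
      matrix(apply(q_z, 2, diff), ncol = k)
    )
    # restrict the DTW to a padded subrange around the localized window so
    # local warping is free but the path cannot jump to a distant region
    pad <- ceiling(n_q / 2)
    lo <- max(1L, loc$start - pad)
    hi <- min(nrow(rf_full), loc$start + n_q - 1L + pad)
    rf <- rf_full[lo:hi, , drop = FALSE]
    offset <- lo - 1L
  } else {
    # near-full-cycle queries: per-track standardization is already on the
    # reference's global scale
    q_z <- sweep(q$sm, 2, colMeans(q$sm))
    q_sds <- apply(q_z, 2, stats::sd)
    q_z <- sweep(q_z, 2, pmax(q_sds, 1e-12), `/`)
    q_z <- sweep(q_z, 2, q$gates, `*`)
    qf <- cbind(
      q_z[-nrow(q_z), , drop = FALSE],
      matrix(apply(q_z, 2, diff), ncol = k)
    )
    rf <- rf_full
  }

  al <- subsequence_dtw(qf, rf)
  dist_steps <- time_distortion(al)
  rel <- relative_time_distortion(dist_steps, n)

  # feature sample i sits on the transition frame i -> i + 1; frames take the
  # left-edge percentage of their matched reference samples and the final
  # frame the right edge, so an exact reference slice maps to an exactly
  # linear pseudotime
  perc <- ref_tbl$percentage
  path_full <- al$path
  path_full[, 2] <- path_full[, 2] + offset
  pt_feat <- assign_pseudotime(path_full, perc, wrap = FALSE)
  last_refs <- path_full[path_full[, 1] == al$n_query, 2]
  pt_last <- mean(perc[pmin(last_refs + 1L, length(perc))])
  pseudotime <- wrap_percentage(c(pt_feat, pt_last))

  new_alignment(
    track_id = track_id, branch = branch, frames = track$frame,
    alignable = TRUE,
    path = path_full, distance = al$distance,
    ref_window_pct = wrap_percentage(perc[al$ref_window + offset]),
    pseudotime = pseudotime,
    time_distortion = dist_steps,
    relative_time_distortion = rel,
    arrested = flag_arrest(rel, config$threshold),
    config = config
  )
}

new_alignment <- function(track_id, branch, frames, alignable, config,
                          path = NULL, distance = NA_real_,
                          ref_window_pct = c(NA_real_, NA_real_),
                          pseudotime = rep(NA_real_, length(frames)),
                          time_distortion = NA_real_,
                          relative_time_distortion = NA_real_,
                          arrested = NA) {
  structure(
    list(
      track_id = track_id, branch = branch, frames = frames,
      n_frames = length(frames), alignable = alignable,
      path = path, distance = distance, ref_window_pct = ref_window_pct,
      pseudotime = pseudotime, time_distortion = time_distortion,
      relative_time_distortion = relative_time_distortion,
      arrested = arrested, config = config
    ),
    class = "fucci_alignment"
  )
}

#' @export
print.fucci_alignment <- function(x, ...) {
  if (!x$alignable) {
    cat(sprintf(
      "<fucci_alignment> track %s/%s: unalignable (zero-variance channel)\n",
      x$track_id, x$branch
    ))
    return(invisible(x))
  }
  cat(sprintf(
    paste0(
      "<fucci_alignment> track %s/%s: %d frames, distance %.3g,\n",
      "  relative time distortion %.3g (%s)\n"
    ),
    x$track_id, x$branch, x$n_frames, x$distance,
    x$relative_time_distortion,
    if (isTRUE(x$arrested)) "ARRESTED" else "cycling"
  ))
  invisible(x)
}

#' Align every track of an intensity table
#'
#' @param intensities Intensity table (see [extract_nuclear_intensities()]);
#'   tracks are identified by `(track_id, branch)`. Tracks shorter than
#'   `config$min_length` are skipped with a warning.
#' @inheritParams align_track
#' @return A list of `fucci_alignment` objects of class
#'   `fucci_alignment_set`; use [generics::tidy()] for the per-frame
#'   pseudotime table and [generics::glance()] for the per-track summary.
#' @export
align_tracks <- function(intensities, reference, config = align_config()) {
  pieces <- intensities |>
    dplyr::group_split(.data$track_id, .data$branch)
  keep <- purrr::map_lgl(pieces, ~ nrow(.x) >= config$min_length)
  if (any(!keep)) {
    warn(sprintf(
      "%d track(s) shorter than min_length = %d were skipped",
      sum(!keep), config$min_length
    ))
  }
  out <- purrr::map(pieces[keep], align_track,
                    reference = reference, config = config)
  structure(out, class = "fucci_alignment_set")
}

#' @rdname fuccitrack_tidiers
#' @export
tidy.fucci_alignment <- function(x, ...) {
  tibble(
    track_id = x$track_id, branch = x$branch,
    frame = x$frames, pseudotime = x$pseudotime,
    arrested = x$arrested
  )
}

#' Tidiers for alignment results
#'
#' `tidy()` returns one row per frame (`track_id`, `branch`, `frame`,
#' `pseudotime`, `arrested`); `glance()` returns one row per track with the
#' alignment distance, the matched reference window (in percent), the
#' relative time distortion and the arrest call.
#'
#' @param x A `fucci_alignment` or `fucci_alignment_set`.
#' @param ... Unused.
#' @name fuccitrack_tidiers
#' @export
glance.fucci_alignment <- function(x, ...) {
  tibble(
    track_id = x$track_id, branch = x$branch, n_frames = x$n_frames,
    alignable = x$alignable, distance = x$distance,
    ref_start_pct = x$ref_window_pct[[1]], ref_end_pct = x$ref_window_pct[[2]],
    time_distortion = x$time_distortion,
    relative_time_distortion = x$relative_time_distortion,
    arrested = x$arrested
  )
}

#' @rdname fuccitrack_tidiers
#' @export
tidy.fucci_alignment_set <- function(x, ...) {
  purrr::map(unclass(x), tidy) |> dplyr::bind_rows()
}

#' @rdname fuccitrack_tidiers
#' @export
glance.fucci_alignment_set <- function(x, ...) {
  purrr::map(unclass(x), glance) |> dplyr::bind_rows()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
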