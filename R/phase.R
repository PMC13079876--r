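#' Intensity-threshold cell-cycle phase call
#'
#' A channel is "on" when its mean nuclear intensity exceeds a fixed fraction
#' (default 10%) of the channel's maximum signal. The colour combination then
#' encodes the phase: cyan-only = G1, both = G1/S, magenta-only = S/G2/M,
#' neither = DARK (both reporters degraded, around mitosis). The call is
#' scale-invariant: rescaling a channel together with its maximum leaves it
#' unchanged.
#'
#' @param cyan,magenta Mean nuclear intensities (vectorized).
#' @param cyan_max,magenta_max Per-channel maximum signal (> 0).
#' @param relative_threshold Fraction of the maximum (default 0.1).
#' @return Character vector of phase labels in
#'   `c("G1", "G1S", "SG2M", "DARK")`.
#' @export
classify_intensity <- function(cyan, magenta, cyan_max, magenta_max,
                               relative_threshold = 0.1) {
  if (any(cyan_max <= 0) || any(magenta_max <= 0)) {
    stop_fucci("channel maxima must be > 0", "bad_input")
  }
  if (relative_threshold <= 0 || relative_threshold >= 1) {
    stop_fucci("relative_threshold must lie in (0, 1)", "bad_input")
  }
  cyan_on <- cyan > relative_threshold * cyan_max
  magenta_on <- magenta > relative_threshold * magenta_max
  dplyr::case_when(
    cyan_on & !magenta_on ~ "G1",
    cyan_on & magenta_on ~ "G1S",
    !cyan_on & magenta_on ~ "SG2M",
    .default = "DARK"
  )
}

#' Classify every frame of an intensity table
#'
#' Applies [classify_intensity()] per frame. The "maximum signal per channel"
#' is taken per track (`max_scope = "per_track"`, compensating expression
#' differences between nuclei) or over the whole table
#' (`"per_dataset"`, more robust for short tracks that may not visit their
#' intensity peak). Tracks whose channels are all zero are classified DARK
#' throughout, with a warning.
#'
#' @param intensities Intensity table with `cyan` and `magenta` columns (or
#'   the columns named in `channels`).
#' @param relative_threshold Fraction of the maximum (default 0.1).
#' @param max_scope `"per_track"` (default) or `"per_dataset"`.
#' @param channels Length-2 character vector naming the cyan-like and
#'   magenta-like columns.
#' @return The input tibble with a `phase` column appended.
#' @export
classify_track <- function(intensities, relative_threshold = 0.1,
                           max_scope = c("per_track", "per_dataset"),
                           channels = c("cyan", "magenta")) {
  max_scope <- match.arg(max_scope)
  if (!all(channels %in% names(intensities))) {
    stop_fucci(
      sprintf("channel column(s) not found: %s",
              paste(setdiff(channels, names(intensities)), collapse = ", ")),
      "bad_input"
    )
  }
  if (nrow(intensities) == 0) {
    stop_fucci("empty intensity table", "bad_input")
  }
  if (is.null(intensities$branch)) intensities$branch <- ""
  if (is.null(intensities$track_id)) intensities$track_id <- 0L
  cy <- intensities[[channels[[1]]]]
  mg <- intensities[[channels[[2]]]]

  grp <- if (max_scope == "per_track") {
    paste(intensities$track_id, intensities$branch, sep = "/")
  } else {
    rep("all", nrow(intensities))
  }
  cy_max <- stats::ave(cy, grp, FUN = function(v) max(v, na.rm = TRUE))
  mg_max <- stats::ave(mg, grp, FUN = function(v) max(v, na.rm = TRUE))

  dead <- cy_max <= 0 & mg_max <= 0
  out <- intensities
  out$phase <- NA_character_
  if (any(dead)) {
    warn(sprintf(
      "%d track(s) have all-zero channels; classified DARK throughout",
      length(unique(grp[dead]))
    ))
    out$phase[dead] <- "DARK"
  }
  live <- !dead
  if (any(live)) {
    out$phase[live] <- classify_intensity(
      cy[live], mg[live],
      pmax(cy_max[live], 1e-300), pmax(mg_max[live], 1e-300),
      relative_threshold = relative_threshold
    )
  }
  out
}

#' Sensor colour-combination schemes
#'
#' A sensor scheme maps the three informative colour combinations
#' (cyan-only, both, magenta-only) to phase names. Two schemes are built in:
#' `"fucci"` (this package's sensor: cyan-only = G1, both = G1/S,
#' magenta-only = S/G2/M) and `"pip_fucci"` (PIP-FUCCI: cyan-only = G1, both
#' = G2/M, magenta-only = S). Both sensors have windows with no intensity at
#' all (early G1, respectively early S), represented by the DARK label,
#' which is preserved by any mapping.
#'
#' @param name `"fucci"` or `"pip_fucci"`, or a custom scheme via `mapping`.
#' @param mapping Named character vector with names `cyan_only`, `both`,
#'   `magenta_only` giving phase names (bijective).
#' @return An object of class `fucci_sensor_scheme`.
#' @export
sensor_scheme <- function(name = c("fucci", "pip_fucci"), mapping = NULL) {
  if (is.null(mapping)) {
    name <- match.arg(name)
    mapping <- switch(name,
      fucci = c(cyan_only = "G1", both = "G1S", magenta_only = "SG2M"),
      pip_fucci = c(cyan_only = "G1", both = "G2/M", magenta_only = "S")
    )
  } else {
    name <- if (is.character(name)) name[[1]] else "custom"
  }
  combos <- c("cyan_only", "both", "magenta_only")
  if (!setequal(names(mapping), combos) || anyDuplicated(mapping) > 0) {
    stop_fucci(
      "scheme mapping must be a bijection on {cyan_only, both, magenta_only}",
      "bad_input"
    )
  }
  structure(
    list(name = name, mapping = mapping[combos]),
    class = "fucci_sensor_scheme"
  )
}

#' Translate phase labels between sensor schemes
#'
#' Relabels phases through the shared colour-combination key: a label is
#' looked up in the source scheme to find its colour combination, and the
#' target scheme names that combination. For FUCCI to PIP-FUCCI: G1 maps to
#' G1 (same colours in both sensors), G1/S (two-colour appearance) maps to
#' G2/M, and S/G2/M maps to S. DARK maps to DARK.
#'
#' @param labels Character vector of phase labels of the source scheme.
#' @param source,target [sensor_scheme()] objects.
#' @return Character vector of target-scheme phase names.
#' @export
map_phases <- function(labels, source = sensor_scheme("fucci"),
                       target = sensor_scheme("pip_fucci")) {
  stopifnot(inherits(source, "fucci_sensor_scheme"),
            inherits(target, "fucci_sensor_scheme"))
  combo_of <- stats::setNames(names(source$mapping), source$mapping)
  known <- c(source$mapping, "DARK")
  bad <- setdiff(unique(labels), known)
  if (length(bad) > 0) {
    stop_fucci(
      sprintf(
        "label(s) %s not in scheme '%s' (allowed: %s)",
        paste(bad, collapse = ", "), source$name, paste(known, collapse = ", ")
      ),
      "vocabulary"
    )
  }
  out <- ifelse(labels == "DARK", "DARK",
                unname(target$mapping[combo_of[labels]]))
  as.character(out)
}

#' Background-correct extracted mean intensities
#'
#' Subtracts, per channel, the minimum mean intensity observed in the table
#' (per dataset). A simple correction for a shared nuclear baseline
#' (autofluorescence) before intensity-threshold classification; proper
#' flat-field correction should happen upstream on the images.
#'
#' @param intensities Intensity table.
#' @param channels Channel columns to correct.
#' @return The table with corrected channel columns.
#' @export
background_correct <- function(intensities, channels = c("cyan", "magenta")) {
  for (ch in channels) {
    intensities[[ch]] <- intensities[[ch]] -
      min(intensities[[ch]], na.rm = TRUE)
  }
  intensities
}
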