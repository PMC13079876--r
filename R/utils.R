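# internal validators shared across modules

stop_fucci <- function(msg, class) {
  rlang::abort(msg, class = paste0("fuccitrack_", class))
}

assert_tracks_tbl <- function(tracks, call_name = "tracks") {
  need <- c("track_id", "branch", "frame", "x", "y")
  missing_cols <- setdiff(need, names(tracks))
  if (length(missing_cols) > 0) {
    stop_fucci(
      sprintf(
        "`%s` must contain columns %s; missing: %s",
        call_name, paste(need, collapse = ", "),
        paste(missing_cols, collapse = ", ")
      ),
      "bad_input"
    )
  }
  if (nrow(tracks) > 0 && any(tracks$frame < 0)) {
    stop_fucci("track frames must be >= 0", "bad_input")
  }
  invisible(tracks)
}

assert_label_stack <- function(labels) {
  if (!is.array(labels) || length(dim(labels)) != 3) {
    stop_fucci("label stack must be a 3-axis (time, y, x) array", "bad_input")
  }
  if (any(labels < 0) || any(labels != round(labels))) {
    stop_fucci("label stack must contain non-negative integers", "format")
  }
  invisible(labels)
}

# %% that maps 100 -> 100 rather than 0, for percentage wrap-around
wrap_percentage <- function(p) {
  out <- p %% 100
  out[p > 0 & out == 0] <- 100
  out
}
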