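#' Read tracks from TrackMate-dialect XML
#'
#' Parses the `Model/AllSpots` and `Model/AllTracks/Track/Edge` elements of a
#' TrackMate-style tracking file into a tidy spot table. Spots that are not
#' referenced by any track edge are dropped. Branch codes are derived from the
#' edge graph: the root lineage carries the empty code `""` and every division
#' appends one lowercase letter per daughter (in order of spot id), mirroring
#' the "auto naming" convention in which letters are appended per branch so
#' divisions can be detected from the spot name.
#'
#' @param path Path to an XML file.
#' @return A tibble with one row per spot: `spot_id`, `track_id`, `branch`
#'   (lineage code, `""` before any division), `frame` (0-based), `x`, `y`
#'   (pixels), `label` (mask instance id, 0 if unknown), `name`, and
#'   `interpolated` (always `FALSE` on read).
#' @examples
#' path <- tempfile(fileext = ".xml")
#' trk <- tibble::tibble(
#'   spot_id = 1:3, track_id = 0L, branch = "", frame = 0:2,
#'   x = c(1, 2, 3), y = c(1, 1, 1), label = 1L,
#'   name = c("s1", "s2", "s3"), interpolated = FALSE
#' )
#' write_trackmate_xml(trk, path)
#' read_trackmate_xml(path)
#' @export
read_trackmate_xml <- function(path) {
  if (!file.exists(path)) {
    stop_fucci(sprintf("file not found: %s", path), "io")
  }
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) {
      stop_fucci(sprintf("malformed XML in %s: %s", path, conditionMessage(e)), "parse")
    }
  )
  model <- xml2::xml_find_first(doc, ".//Model")
  if (inherits(model, "xml_missing")) {
    stop_fucci("malformed tracking XML: no <Model> element", "parse")
  }
  spot_nodes <- xml2::xml_find_all(model, ".//AllSpots//Spot")
  attr_num <- function(nodes, name) {
    as.numeric(xml2::xml_attr(nodes, name))
  }
  spots <- tibble(
    spot_id = as.integer(attr_num(spot_nodes, "ID")),
    frame = as.integer(attr_num(spot_nodes, "FRAME")),
    x = attr_num(spot_nodes, "POSITION_X"),
    y = attr_num(spot_nodes, "POSITION_Y"),
    label = {
      lv <- attr_num(spot_nodes, "LABEL_VALUE")
      as.integer(ifelse(is.na(lv), 0, lv))
    },
    name = dplyr::coalesce(xml2::xml_attr(spot_nodes, "name"), "")
  )
  if (nrow(spots) > 0 && anyNA(spots$spot_id)) {
    stop_fucci("malformed tracking XML: <Spot> without numeric ID attribute", "parse")
  }

  track_nodes <- xml2::xml_find_all(model, ".//AllTracks/Track")
  out <- purrr::map(track_nodes, function(tn) {
    track_id <- as.integer(as.numeric(xml2::xml_attr(tn, "TRACK_ID")))
    edges <- xml2::xml_find_all(tn, ".//Edge")
    if (length(edges) == 0) {
      return(NULL)
    }
    src <- as.integer(attr_num(edges, "SPOT_SOURCE_ID"))
    dst <- as.integer(attr_num(edges, "SPOT_TARGET_ID"))
    ids <- union(src, dst)
    unknown <- setdiff(ids, spots$spot_id)
    if (length(unknown) > 0) {
      stop_fucci(
        sprintf(
          "track %d references spot id(s) %s absent from <AllSpots>",
          track_id, paste(unknown, collapse = ", ")
        ),
        "integrity"
      )
    }
    codes <- derive_branch_codes(src, dst)
    sp <- spots[match(ids, spots$spot_id), ]
    sp$track_id <- track_id
    sp$branch <- unname(codes[as.character(ids)])
    sp
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble(
      spot_id = integer(), track_id = integer(), branch = character(),
      frame = integer(), x = double(), y = double(), label = integer(),
      name = character(), interpolated = logical()
    ))
  }
  out$interpolated <- FALSE
  out |>
    select("spot_id", "track_id", "branch", "frame", "x", "y",
           "label", "name", "interpolated") |>
    arrange(.data$track_id, .data$frame, .data$branch)
}

# branch code per spot id from a directed edge list (source -> target);
# divisions append a letter per daughter, ordered by target spot id
derive_branch_codes <- function(src, dst) {
  ids <- union(src, dst)
  roots <- setdiff(ids, dst)
  if (length(roots) != 1) {
    stop_fucci(
      sprintf("track edges do not form a single-rooted lineage (%d roots)", length(roots)),
      "integrity"
    )
  }
  children <- split(dst, src)
  codes <- stats::setNames(rep(NA_character_, length(ids)), as.character(ids))
  codes[as.character(roots)] <- ""
  queue <- roots
  while (length(queue) > 0) {
    node <- queue[[1]]
    queue <- queue[-1]
    kids <- sort(children[[as.character(node)]])
    if (is.null(kids)) next
    code <- codes[[as.character(node)]]
    if (length(kids) == 1) {
      codes[as.character(kids)] <- code
    } else {
      codes[as.character(kids)] <- paste0(code, letters[seq_along(kids)])
    }
    queue <- c(queue, kids)
  }
  codes
}

#' Write tracks to TrackMate-dialect XML
#'
#' Writes the minimal dialect this package reads back: `Model/AllSpots` with
#' per-frame `<Spot>` elements and `Model/AllTracks/Track/Edge` elements
#' linking each spot to its lineage predecessor. Mask instance ids are stored
#' in a `LABEL_VALUE` attribute.
#'
#' @param tracks Spot table as returned by [read_trackmate_xml()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trackmate_xml <- function(tracks, path) {
  assert_tracks_tbl(tracks)
  if (is.null(tracks$spot_id) || anyNA(tracks$spot_id)) {
    tracks$spot_id <- seq_len(nrow(tracks))
  }
  if (is.null(tracks$name)) tracks$name <- paste0("spot_", tracks$spot_id)
  if (is.null(tracks$label)) tracks$label <- 0L

  doc <- xml2::xml_new_root("TrackMate")
  model <- xml2::xml_add_child(doc, "Model", spatialunits = "pixel", timeunits = "frame")
  all_spots <- xml2::xml_add_child(model, "AllSpots")
  for (f in sort(unique(tracks$frame))) {
    sif <- xml2::xml_add_child(all_spots, "SpotsInFrame", frame = as.character(f))
    rows <- tracks[tracks$frame == f, ]
    for (i in seq_len(nrow(rows))) {
      xml2::xml_add_child(
        sif, "Spot",
        ID = as.character(rows$spot_id[[i]]),
        name = rows$name[[i]],
        FRAME = as.character(rows$frame[[i]]),
        POSITION_X = format(rows$x[[i]], digits = 12),
        POSITION_Y = format(rows$y[[i]], digits = 12),
        LABEL_VALUE = as.character(rows$label[[i]])
      )
    }
  }
  all_tracks <- xml2::xml_add_child(model, "AllTracks")
  for (tid in unique(tracks$track_id)) {
    tt <- tracks[tracks$track_id == tid, ]
    tn <- xml2::xml_add_child(all_tracks, "Track", TRACK_ID = as.character(tid))
    pred <- lineage_predecessors(tt)
    for (i in seq_len(nrow(tt))) {
      p <- pred[[i]]
      if (!is.na(p)) {
        xml2::xml_add_child(
          tn, "Edge",
          SPOT_SOURCE_ID = as.character(tt$spot_id[[p]]),
          SPOT_TARGET_ID = as.character(tt$spot_id[[i]])
        )
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

# row index of each spot's lineage predecessor within one track's rows
# (latest earlier spot whose branch code is a prefix of this spot's code)
lineage_predecessors <- function(tt) {
  n <- nrow(tt)
  vapply(seq_len(n), function(i) {
    cand <- which(
      tt$frame < tt$frame[[i]] &
        startsWith(tt$branch[[i]], tt$branch)
    )
    if (length(cand) == 0) {
      return(NA_integer_)
    }
    cand[[which.max(tt$frame[cand])]]
  }, integer(1))
}

#' Close gaps in tracks by inserting interpolated spots
#'
#' For every missing frame between a spot and its lineage predecessor, a new
#' spot is inserted with linearly interpolated `x`, `y`. Inserted spots carry
#' `label = 0` (their mask instance is unknown — positions are interpolated,
#' masks are not) and `interpolated = TRUE`, and are excluded from intensity
#' extraction by default. The operation is idempotent.
#'
#' @param tracks Spot table (see [read_trackmate_xml()]).
#' @return Spot table with contiguous frames along every lineage path.
#' @export
close_track_gaps <- function(tracks) {
  assert_tracks_tbl(tracks)
  if (nrow(tracks) == 0) {
    return(tracks)
  }
  dup <- tracks |>
    dplyr::count(.data$track_id, .data$branch, .data$frame) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop_fucci(
      sprintf(
        "duplicate frame(s) within one branch: track %s branch '%s' frame %s",
        dup$track_id[[1]], dup$branch[[1]], dup$frame[[1]]
      ),
      "integrity"
    )
  }
  if (is.null(tracks$interpolated)) tracks$interpolated <- FALSE
  if (is.null(tracks$label)) tracks$label <- 0L

  inserted <- tracks |>
    dplyr::group_split(.data$track_id) |>
    purrr::map(function(tt) {
      pred <- lineage_predecessors(tt)
      gaps <- which(!is.na(pred) & tt$frame - tt$frame[pred] > 1)
      if (length(gaps) == 0) {
        return(NULL)
      }
      purrr::map(gaps, function(i) {
        p <- pred[[i]]
        f0 <- tt$frame[[p]]; f1 <- tt$frame[[i]]
        fs <- seq(f0 + 1L, f1 - 1L)
        w <- (fs - f0) / (f1 - f0)
        tibble(
          spot_id = NA_integer_,
          track_id = tt$track_id[[i]],
          branch = tt$branch[[i]],
          frame = as.integer(fs),
          x = tt$x[[p]] + w * (tt$x[[i]] - tt$x[[p]]),
          y = tt$y[[p]] + w * (tt$y[[i]] - tt$y[[p]]),
          label = 0L,
          name = if (!is.null(tt$name)) tt$name[[i]] else NA_character_,
          interpolated = TRUE
        )
      }) |>
        dplyr::bind_rows()
    }) |>
    dplyr::bind_rows()

  dplyr::bind_rows(tracks, inserted) |>
    arrange(.data$track_id, .data$frame, .data$branch)
}

#' Split a lineage into one track per leaf branch
#'
#' Divisions are encoded in branch codes (letters appended per daughter).
#' Each output track is the simple root-to-leaf path of one leaf branch;
#' spots shared by several branches (the pre-division trunk) are duplicated
#' into each. The leaf code is written into the `branch` column of every row
#' of its output track, so output tracks are identified by
#' `(track_id, branch)`.
#'
#' @param tracks Spot table (see [read_trackmate_xml()]).
#' @return Spot table with one row per (leaf branch, spot).
#' @export
split_lineage <- function(tracks) {
  assert_tracks_tbl(tracks)
  if (nrow(tracks) == 0) {
    return(tracks)
  }
  tracks |>
    dplyr::group_split(.data$track_id) |>
    purrr::map(function(tt) {
      codes <- unique(tt$branch)
      leaves <- codes[!vapply(
        codes,
        function(a) any(codes != a & startsWith(codes, a)),
        logical(1)
      )]
      purrr::map(sort(leaves), function(leaf) {
        branch_rows <- tt[startsWith(leaf, tt$branch), ]
        branch_rows <- branch_rows[order(branch_rows$frame), ]
        if (anyDuplicated(branch_rows$frame) > 0) {
          stop_fucci(
            sprintf(
              "inconsistent branch codes in track %d: leaf '%s' visits a frame twice",
              tt$track_id[[1]], leaf
            ),
            "integrity"
          )
        }
        branch_rows$branch <- leaf
        branch_rows
      }) |>
        dplyr::bind_rows()
    }) |>
    dplyr::bind_rows()
}
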