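test_that("tracking XML round-trips and parses fixtures", {
  # zero-track file
  path0 <- withr::local_tempfile(fileext = ".xml")
  writeLines(
    "<TrackMate><Model><AllSpots/><AllTracks/></Model></TrackMate>", path0
  )
  expect_equal(nrow(read_trackmate_xml(path0)), 0)

  # two spots joined by one edge
  path1 <- withr::local_tempfile(fileext = ".xml")
  writeLines('<TrackMate><Model>
    <AllSpots><SpotsInFrame frame="0">
      <Spot ID="1" name="a1" FRAME="0" POSITION_X="1.5" POSITION_Y="2.5"/>
    </SpotsInFrame><SpotsInFrame frame="1">
      <Spot ID="2" name="a2" FRAME="1" POSITION_X="2.5" POSITION_Y="3.5"/>
      <Spot ID="9" name="orphan" FRAME="1" POSITION_X="9" POSITION_Y="9"/>
    </SpotsInFrame></AllSpots>
    <AllTracks><Track TRACK_ID="0">
      <Edge SPOT_SOURCE_ID="1" SPOT_TARGET_ID="2"/>
    </Track></AllTracks></Model></TrackMate>', path1)
  trk <- read_trackmate_xml(path1)
  expect_equal(nrow(trk), 2) # orphan spot dropped
  expect_equal(trk$frame, c(0L, 1L))
  expect_equal(trk$x, c(1.5, 2.5))
  expect_equal(trk$name, c("a1", "a2"))

  # division: 1 spot at frame 0, 2 at frame 1, 2 edges -> 2 branch codes
  path2 <- withr::local_tempfile(fileext = ".xml")
  writeLines('<TrackMate><Model>
    <AllSpots><SpotsInFrame frame="0">
      <Spot ID="1" name="m" FRAME="0" POSITION_X="0" POSITION_Y="0"/>
    </SpotsInFrame><SpotsInFrame frame="1">
      <Spot ID="2" name="da" FRAME="1" POSITION_X="-1" POSITION_Y="0"/>
      <Spot ID="3" name="db" FRAME="1" POSITION_X="1" POSITION_Y="0"/>
    </SpotsInFrame></AllSpots>
    <AllTracks><Track TRACK_ID="0">
      <Edge SPOT_SOURCE_ID="1" SPOT_TARGET_ID="2"/>
      <Edge SPOT_SOURCE_ID="1" SPOT_TARGET_ID="3"/>
    </Track></AllTracks></Model></TrackMate>', path2)
  div <- read_trackmate_xml(path2)
  expect_equal(nrow(div), 3)
  expect_setequal(div$branch, c("", "a", "b"))

  # writer round trip preserves positions and lineage
  rt_path <- withr::local_tempfile(fileext = ".xml")
  write_trackmate_xml(div, rt_path)
  rt <- read_trackmate_xml(rt_path)
  expect_equal(rt$x, div$x)
  expect_setequal(rt$branch, div$branch)
})

test_that("malformed or inconsistent XML is rejected", {
  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<TrackMate><Model>", bad)
  expect_error(read_trackmate_xml(bad), class = "fuccitrack_parse")

  dangling <- withr::local_tempfile(fileext = ".xml")
  writeLines('<TrackMate><Model><AllSpots/>
    <AllTracks><Track TRACK_ID="0">
      <Edge SPOT_SOURCE_ID="1" SPOT_TARGET_ID="2"/>
    </Track></AllTracks></Model></TrackMate>', dangling)
  expect_error(read_trackmate_xml(dangling), class = "fuccitrack_integrity")
})

test_that("gap closing interpolates positions and is idempotent", {
  trk <- make_linear_tracks(2)
  trk$frame <- c(1L, 3L)
  trk$x <- c(0, 2)
  trk$y <- c(0, 2)
  closed <- close_track_gaps(trk)
  expect_equal(closed$frame, 1:3)
  ins <- closed[closed$interpolated, ]
  expect_equal(c(ins$x, ins$y), c(1, 1))
  expect_equal(ins$label, 0L)

  # no gaps -> identity
  expect_equal(close_track_gaps(closed), closed)

  # gap of 3 frames with the spec's interpolation points
  trk2 <- make_linear_tracks(2)
  trk2$frame <- c(0L, 4L)
  trk2$x <- c(0, 3)
  trk2$y <- c(0, 6)
  closed2 <- close_track_gaps(trk2)
  expect_equal(closed2$x, c(0, 0.75, 1.5, 2.25, 3))
  expect_equal(closed2$y, c(0, 1.5, 3, 4.5, 6))

  dup <- make_linear_tracks(2)
  dup$frame <- c(1L, 1L)
  expect_error(close_track_gaps(dup), class = "fuccitrack_integrity")
})

test_that("gap closing yields consecutive frames on random lineages", {
  set.seed(42)
  for (rep in 1:10) {
    frames <- sort(sample(0:30, 8))
    trk <- make_linear_tracks(8)
    trk$frame <- as.integer(frames)
    trk$x <- cumsum(rnorm(8))
    closed <- close_track_gaps(trk)
    expect_equal(closed$frame, seq(min(frames), max(frames)))
    # idempotence
    expect_equal(nrow(close_track_gaps(closed)), nrow(closed))
  }
})

test_that("lineage splitting duplicates shared ancestors per leaf", {
  linear <- make_linear_tracks(4)
  expect_equal(split_lineage(linear)[, names(linear)], linear)

  div <- dplyr::bind_rows(
    make_linear_tracks(2),
    tibble::tibble(
      spot_id = 3:4, track_id = 1L, branch = c("a", "b"), frame = 2L,
      x = c(0, 4), y = 2, label = 1L, name = c("s3a", "s3b"),
      interpolated = FALSE
    )
  )
  leaves <- split_lineage(div)
  expect_equal(nrow(leaves), 6) # 2 shared spots duplicated into both leaves
  expect_setequal(unique(leaves$branch), c("a", "b"))
  expect_equal(sum(leaves$branch == "a"), 3)

  # two successive divisions -> four leaves
  div2 <- dplyr::bind_rows(
    div,
    tibble::tibble(
      spot_id = 5:8, track_id = 1L,
      branch = c("aa", "ab", "ba", "bb"), frame = 3L,
      x = 1:4, y = 2, label = 1L,
      name = paste0("s4", c("aa", "ab", "ba", "bb")), interpolated = FALSE
    )
  )
  leaves2 <- split_lineage(div2)
  expect_setequal(unique(leaves2$branch), c("aa", "ab", "ba", "bb"))
  expect_equal(nrow(leaves2), 4 * 4) # root(2) + branch + leaf per lineage
})

test_that("label stacks round-trip bit-exactly through TIFF", {
  labs <- array(0L, dim = c(3, 8, 10))
  labs[1, 2:4, 2:4] <- 7L
  labs[2, 5:6, 1:2] <- 260L
  labs[3, 1, 10] <- 65535L
  path <- withr::local_tempfile(fileext = ".tif")
  write_label_stack(labs, path)
  expect_identical(read_label_stack(path), labs)
})

test_that("image stacks preserve shape and relative intensities", {
  arr <- array(runif(2 * 2 * 6 * 5, 0, 300), dim = c(2, 2, 6, 5))
  st <- image_stack(arr, c("cyan", "magenta"))
  path <- withr::local_tempfile(fileext = ".tif")
  write_image_stack(st, path)
  rt <- read_image_stack(path, c("cyan", "magenta"))
  expect_equal(dim(rt$data), dim(arr))
  # stored rescaled to [0, 1] by the stack maximum
  expect_equal(rt$data, arr / max(arr), tolerance = 1e-6)
})

test_that("intensity tables round-trip through CSV", {
  tab <- make_linear_tracks(3)
  tab$cyan <- c(0.25, 0.5, 0.125)
  tab$magenta <- c(1, 2, 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_intensity_table(tab, path)
  rt <- read_intensity_table(path)
  expect_equal(rt$cyan, tab$cyan)
  expect_equal(rt$frame, tab$frame)
})

test_that("phase JSON follows the frame_label convention and vocabulary", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"0_5": "G1"}', path)
  got <- read_phase_json(path)
  expect_equal(got, tibble::tibble(frame = 0L, label = 5L, phase = "G1"))

  writeLines('{"0_5": "G0"}', path)
  err <- tryCatch(read_phase_json(path), error = identity)
  expect_s3_class(err, "fuccitrack_vocabulary")
  expect_match(conditionMessage(err), "G1S") # lists allowed values

  phases <- tibble::tibble(
    frame = c(0L, 1L, 1L), label = c(5L, 5L, 6L),
    phase = c("G1", "G1S", "DARK")
  )
  write_phase_json(phases, path)
  expect_equal(read_phase_json(path), phases)

  # custom key parser hook
  writeLines('{"f2-l7": "SG2M"}', path)
  got2 <- read_phase_json(path, key_parser = function(k) {
    as.integer(sub("f(\\d+)-l(\\d+)", "\\1", k)) -> f
    c(f, as.integer(sub("f(\\d+)-l(\\d+)", "\\2", k)))
  })
  expect_equal(got2$frame, 2L)
  expect_equal(got2$label, 7L)
})
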