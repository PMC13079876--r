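test_that("reference curve building resamples and averages", {
  n <- 101
  tr <- tibble::tibble(
    track_id = 1L, branch = "", frame = 0:(n - 1),
    cyan = seq(0, 1, length.out = n), magenta = rev(seq(0, 1, length.out = n))
  )
  ref <- build_reference_curve(tr)
  expect_equal(ref$percentage, seq(0, 100, length.out = 101))
  expect_equal(ref$cyan, tr$cyan)
  expect_equal(attr(ref, "n_source_tracks"), 1L)

  four <- dplyr::bind_rows(lapply(1:4, function(i) {
    dplyr::mutate(tr, track_id = i)
  }))
  ref4 <- build_reference_curve(four)
  expect_equal(ref4$cyan, ref$cyan)
  expect_equal(attr(ref4, "n_source_tracks"), 4L)

  # same shape at different lengths -> same curve within interpolation error
  shape <- function(n) {
    p <- seq(0, 1, length.out = n)
    tibble::tibble(
      track_id = n, branch = "", frame = seq_len(n) - 1L,
      cyan = sin(pi * p), magenta = p^2
    )
  }
  ref2 <- build_reference_curve(dplyr::bind_rows(shape(50), shape(100)))
  expect_equal(ref2$cyan, sin(pi * ref2$percentage / 100), tolerance = 5e-3)

  expect_error(build_reference_curve(shape(5)), class = "fuccitrack_bad_input")
  expect_error(build_reference_curve(shape(50)[0, ]), class = "fuccitrack_bad_input")
})

test_that("reference curves round-trip through CSV with metadata", {
  ref <- model_reference_curve(cycle_model())
  path <- withr::local_tempfile(fileext = ".csv")
  write_reference_curve(ref, path)
  rt <- read_reference_curve(path)
  expect_equal(rt$cyan, ref$cyan, tolerance = 1e-9)
  expect_equal(attr(rt, "n_source_tracks"), attr(ref, "n_source_tracks"))
})

test_that("a track cut from the reference aligns onto its own window", {
  model <- cycle_model(noise_sigma = 0)
  ref <- model_reference_curve(model)
  tr <- simulate_fucci_track(model, start_percentage = 25, n_frames = 30)
  al <- align_track(tr, ref)
  expect_true(al$alignable)
  err <- pct_diff(al$pseudotime, tr$true_percentage)
  expect_lt(sqrt(mean(err^2)), 2)
  expect_lt(al$relative_time_distortion, 0.2)
  expect_false(al$arrested)
})

test_that("arrested tracks score higher distortion than normal ones", {
  model <- cycle_model(noise_sigma = 0.05)
  ref <- model_reference_curve(model)
  norm <- align_track(
    simulate_fucci_track(model, 40, 40, seed = 21), ref
  )
  arr <- align_track(
    simulate_fucci_track(model, 20, 40, arrested = TRUE, seed = 22), ref
  )
  expect_gt(arr$relative_time_distortion, norm$relative_time_distortion)
})

test_that("a time-reversed track gets a very large distortion", {
  model <- cycle_model(noise_sigma = 0.05)
  ref <- model_reference_curve(model)
  tr <- simulate_fucci_track(model, 25, 40, seed = 77)
  rev_tr <- tr
  rev_tr$cyan <- rev(tr$cyan)
  rev_tr$magenta <- rev(tr$magenta)
  al_fwd <- align_track(tr, ref)
  al_rev <- align_track(rev_tr, ref)
  expect_gt(al_rev$relative_time_distortion,
            3 * al_fwd$relative_time_distortion)
})

test_that("DARK zero-variance tracks are unalignable, not arrested", {
  ref <- model_reference_curve(cycle_model())
  dark <- tibble::tibble(
    track_id = 1L, branch = "", frame = 0:19,
    cyan = rep(0.4, 20), magenta = rep(0.1, 20)
  )
  al <- align_track(dark, ref)
  expect_false(al$alignable)
  expect_true(is.na(al$arrested))

  short <- dark[1:5, ]
  expect_error(align_track(short, ref), class = "fuccitrack_bad_input")
})

test_that("relative distortion is invariant to query intensity scaling", {
  model <- cycle_model(noise_sigma = 0.05)
  ref <- model_reference_curve(model)
  tr <- simulate_fucci_track(model, 55, 35, seed = 5)
  tr2 <- dplyr::mutate(tr, cyan = 4 * .data$cyan, magenta = 4 * .data$magenta)
  a1 <- align_track(tr, ref)
  a2 <- align_track(tr2, ref)
  expect_equal(a1$relative_time_distortion, a2$relative_time_distortion)
  expect_equal(a1$pseudotime, a2$pseudotime, tolerance = 1e-9)
})

test_that("align_tracks tidiers return per-frame and per-track tables", {
  model <- cycle_model(noise_sigma = 0.05)
  ref <- model_reference_curve(model)
  pop <- simulate_population(model, n_tracks = 3, n_frames = 20,
                             arrest_fraction = 0, seed = 2)
  als <- align_tracks(pop, ref)
  td <- tidy(als)
  gl <- glance(als)
  expect_equal(nrow(td), 60)
  expect_equal(nrow(gl), 3)
  expect_true(all(c("frame", "pseudotime", "arrested") %in% names(td)))
  expect_true(all(gl$relative_time_distortion >= 0))
  expect_true(all(td$pseudotime >= 0 & td$pseudotime <= 100))

  expect_warning(
    align_tracks(pop[pop$frame < 5, ], ref),
    "skipped"
  )
})

test_that("alignment and reference plots build without error", {
  model <- cycle_model(noise_sigma = 0.05)
  ref <- model_reference_curve(model)
  al <- align_track(simulate_fucci_track(model, 10, 25, seed = 4), ref)
  expect_s3_class(ggplot2::autoplot(ref), "ggplot")
  expect_s3_class(ggplot2::autoplot(al), "ggplot")
  als <- align_tracks(simulate_population(model, 2, 20, seed = 3), ref)
  expect_s3_class(ggplot2::autoplot(als), "ggplot")
  expect_s3_class(plot_distortion_histogram(als, threshold = 1), "ggplot")
})
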