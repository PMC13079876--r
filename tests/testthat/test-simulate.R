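test_that("noiseless tracks sit exactly on the model profiles", {
  m <- cycle_model(noise_sigma = 0)
  tr <- simulate_fucci_track(m, start_percentage = 10, n_frames = 20)
  expect_equal(tr$cyan,
               approx(m$profiles$percentage, m$profiles$cyan,
                      xout = tr$true_percentage)$y)
  expect_equal(tr$true_percentage, seq(10, 29, by = 1))
})

test_that("arrested tracks hold a cyan-high magenta-dark G1 plateau", {
  m <- cycle_model(noise_sigma = 0)
  tr <- simulate_fucci_track(m, 10, 60, arrested = TRUE,
                             plateau_percentage = 20)
  plateau <- tr[tr$frame >= 15, ]
  expect_true(all(plateau$true_percentage == 20))
  expect_true(all(plateau$cyan > 0.8))
  expect_true(all(plateau$magenta < 0.05))
  expect_true(all(plateau$true_phase == "G1"))
})

test_that("track simulation is deterministic per seed", {
  m <- cycle_model(noise_sigma = 0.1, seed = 9)
  t1 <- simulate_fucci_track(m, 5, 30)
  t2 <- simulate_fucci_track(m, 5, 30)
  expect_identical(t1, t2)
  t3 <- simulate_fucci_track(m, 5, 30, seed = 10)
  expect_false(identical(t1$cyan, t3$cyan))
})

test_that("populations respect the arrest fraction", {
  m <- cycle_model(noise_sigma = 0.05)
  none <- simulate_population(m, 10, 20, arrest_fraction = 0)
  expect_false(any(none$arrested))
  all_arr <- simulate_population(m, 10, 20, arrest_fraction = 1)
  expect_true(all(all_arr$arrested))
  mixed <- simulate_population(m, 40, 20, arrest_fraction = 0.5)
  expect_equal(sum(mixed$arrested) / nrow(mixed), 0.5)
  expect_equal(dplyr::n_distinct(mixed$track_id), 40)
})

test_that("profile threshold crossings line up with phase boundaries", {
  m <- cycle_model()
  p <- m$profiles
  at <- function(chan, pct) approx(p$percentage, p[[chan]], xout = pct)$y
  expect_equal(at("cyan", 3), 0.1)     # dark-exit crossing
  expect_equal(at("cyan", 50), 0.1)    # G1/S -> S/G2/M crossing
  expect_equal(at("magenta", 35), 0.1) # G1 -> G1/S crossing
  expect_equal(at("magenta", 97), 0.1) # S/G2/M -> dark crossing
})

test_that("rendered movies are deterministic and geometrically checked", {
  m <- cycle_model(noise_sigma = 0, seed = 2)
  cfg <- movie_config(frames = 4, height = 80, width = 80, n_nuclei = 3,
                      target_snr = 2, seed = 2)
  mv1 <- render_movie(m, cfg)
  mv2 <- render_movie(m, cfg)
  expect_identical(mv1$images$data, mv2$images$data)
  expect_identical(mv1$labels, mv2$labels)

  expect_error(
    render_movie(m, movie_config(frames = 2, height = 64, width = 64,
                                 n_nuclei = 50)),
    class = "fuccitrack_geometry"
  )
})

test_that("noise- and bleed-free rendering paints exact track intensities", {
  m <- cycle_model(noise_sigma = 0, seed = 6)
  cfg <- movie_config(frames = 6, height = 96, width = 96, n_nuclei = 3,
                      target_snr = NA, nuclear_background = 0, seed = 6)
  mv <- render_movie(m, cfg)
  for (t in 1:6) {
    for (id in 1:3) {
      inside <- mv$labels[t, , ] == id
      vals <- mv$images$data[t, 1, , ][inside]
      truth <- mv$population$cyan[mv$population$track_id == id &
                                    mv$population$frame == t - 1]
      expect_equal(unique(vals), truth)
    }
  }
  # tubulin voids: zero inside every nucleus
  expect_true(all(mv$images$data[, 3, , ][mv$labels > 0] == 0))
})

test_that("the rendered SNR approximates its target within 20%", {
  m <- cycle_model(noise_sigma = 0, seed = 4)
  mv <- render_movie(m, movie_config(frames = 30, height = 200, width = 200,
                                     n_nuclei = 10, target_snr = 4, seed = 4))
  est <- compute_snr(mv$images, mv$labels)
  expect_lt(abs(est$snr - 4) / 4, 0.2)
})

test_that("extraction recovers configured means within 3 standard errors", {
  m <- cycle_model(noise_sigma = 0, seed = 8)
  mv <- render_movie(m, movie_config(frames = 10, height = 128, width = 128,
                                     n_nuclei = 4, target_snr = 4, seed = 8))
  ints <- extract_nuclear_intensities(mv$labels, mv$images, mv$tracks)
  joined <- dplyr::left_join(
    ints, mv$population,
    by = c("track_id", "frame"), suffix = c("", "_true")
  )
  for (t in seq_len(nrow(joined))) {
    area <- sum(mv$labels[joined$frame[t] + 1, , ] == joined$track_id[t])
    se <- mv$noise_sd / sqrt(area)
    expect_lt(
      abs(joined$cyan[t] -
            (joined$cyan_true[t] + mv$config$nuclear_background)),
      3 * se + 1e-9
    )
  }
})

test_that("the nearest-neighbour linker recovers synthetic identities", {
  m <- cycle_model(noise_sigma = 0, seed = 12)
  mv <- render_movie(m, movie_config(frames = 8, height = 128, width = 128,
                                     n_nuclei = 4, target_snr = NA, seed = 12))
  linked <- track_centroids(mv$labels)
  expect_equal(dplyr::n_distinct(linked$track_id), 4)
  # each linked track follows one ground-truth label
  per_track <- dplyr::count(linked, .data$track_id, .data$label)
  expect_equal(nrow(per_track), 4)
})
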