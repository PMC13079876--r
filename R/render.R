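#' Movie rendering configuration
#'
#' @param frames,height,width Movie dimensions (frames x pixels).
#' @param n_nuclei Number of nuclei.
#' @param radius_range Nuclear semi-axis range in pixels.
#' @param target_snr Target signal-to-noise ratio under [compute_snr()]'s
#'   definition; the additive Gaussian noise level is calibrated against the
#'   rendered noiseless stack so the measured SNR approximates this value.
#'   Use `NA` to disable noise. The default 4 corresponds to a
#'   high-contrast acquisition; live-imaging regimes go down to about 1.4.
#' @param tubulin Render a cytoplasmic tubulin channel (annulus around each
#'   nucleus with a nucleus-shaped void).
#' @param motion_sigma Random-walk step sd in pixels/frame.
#' @param arrest_fraction Fraction of G1-arrested nuclei.
#' @param nuclear_background Nuclear baseline intensity added to both FUCCI
#'   channels inside masks (autofluorescence-like, default 1.5 in units of
#'   the FUCCI dynamic range). A non-zero baseline keeps the pooled in-mask
#'   signal coherent enough for high target SNRs despite the cycle-dependent
#'   FUCCI heterogeneity; set to 0 for pure reporter signal.
#' @param seed Integer seed.
#' @return A list of class `fucci_movie_config`.
#' @export
movie_config <- function(frames = 60L, height = 256L, width = 256L,
                         n_nuclei = 10L, radius_range = c(8, 12),
                         target_snr = 4, tubulin = TRUE, motion_sigma = 1,
                         arrest_fraction = 0, nuclear_background = 1.5,
                         seed = 1L) {
  if (frames < 1 || height < 16 || width < 16 || n_nuclei < 1) {
    stop_fucci("movie dimensions must be positive (and at least 16 px)", "bad_input")
  }
  if (arrest_fraction < 0 || arrest_fraction > 1) {
    stop_fucci("arrest_fraction must lie in [0, 1]", "bad_input")
  }
  structure(
    list(
      frames = as.integer(frames), height = as.integer(height),
      width = as.integer(width), n_nuclei = as.integer(n_nuclei),
      radius_range = radius_range, target_snr = target_snr,
      tubulin = isTRUE(tubulin), motion_sigma = motion_sigma,
      arrest_fraction = arrest_fraction,
      nuclear_background = nuclear_background,
      seed = as.integer(seed)
    ),
    class = "fucci_movie_config"
  )
}

#' Render a synthetic FUCCI movie with ground truth
#'
#' Draws each simulated nucleus as an ellipse performing a seeded random
#' walk. Inside its mask, the cyan and magenta channels carry the track's
#' intensity for that frame (plus the nuclear baseline); the optional
#' tubulin channel is a cytoplasmic annulus around each nucleus with a
#' nucleus-shaped void. Bleed-through (from the model) adds a fraction of
#' the tubulin signal to the cyan channel. Additive Gaussian noise is scaled
#' so that [compute_snr()] on the output approximates
#' `movie_cfg$target_snr`. Ground-truth labels (stable per nucleus) and a
#' spot table are returned alongside the images.
#'
#' @param model A [cycle_model()] (its `bleed_through` is used pixel-wise).
#' @param movie_cfg A [movie_config()].
#' @param population Optional population from [simulate_population()];
#'   by default one is simulated with `movie_cfg`'s nucleus count, frame
#'   count, arrest fraction and seed, with `noise_sigma = 0` (pixel noise is
#'   added by the renderer, not the track model).
#' @return A list of class `fucci_movie`: `images` ([image_stack()]),
#'   `labels` (3-axis integer array), `tracks` (spot table), `population`
#'   (ground truth), `noise_sd` (calibrated), `config`.
#' @export
render_movie <- function(model, movie_cfg = movie_config(), population = NULL) {
  cfg <- movie_cfg
  r_max <- max(cfg$radius_range)
  if (cfg$n_nuclei * (3 * r_max)^2 > 0.9 * cfg$height * cfg$width) {
    stop_fucci(
      sprintf("%d nuclei of radius up to %g do not fit a %d x %d frame",
              cfg$n_nuclei, r_max, cfg$height, cfg$width),
      "geometry"
    )
  }
  if (is.null(population)) {
    quiet_model <- model
    quiet_model$noise_sigma <- 0
    population <- simulate_population(
      quiet_model, n_tracks = cfg$n_nuclei, n_frames = cfg$frames,
      arrest_fraction = cfg$arrest_fraction, seed = cfg$seed
    )
  }

  local_seed(cfg$seed + 1L, {
    n <- cfg$n_nuclei
    margin <- 2.5 * r_max
    # jittered grid placement, then reflected random walks
    n_side <- ceiling(sqrt(n))
    gx <- seq(margin, cfg$width - margin, length.out = max(n_side, 2))
    gy <- seq(margin, cfg$height - margin, length.out = max(n_side, 2))
    grid_pos <- expand.grid(x = gx, y = gy)[seq_len(n), ]
    ax <- stats::runif(n, cfg$radius_range[[1]], cfg$radius_range[[2]])
    bx <- stats::runif(n, cfg$radius_range[[1]], cfg$radius_range[[2]])
    theta <- stats::runif(n, 0, pi)

    pos_x <- matrix(0, cfg$frames, n)
    pos_y <- matrix(0, cfg$frames, n)
    pos_x[1, ] <- grid_pos$x + stats::runif(n, -2, 2)
    pos_y[1, ] <- grid_pos$y + stats::runif(n, -2, 2)
    if (cfg$frames > 1) {
      for (t in 2:cfg$frames) {
        pos_x[t, ] <- reflect(pos_x[t - 1, ] + stats::rnorm(n, sd = cfg$motion_sigma),
                              margin, cfg$width - margin)
        pos_y[t, ] <- reflect(pos_y[t - 1, ] + stats::rnorm(n, sd = cfg$motion_sigma),
                              margin, cfg$height - margin)
      }
    }

    channels <- c("cyan", "magenta", if (cfg$tubulin) "tubulin")
    imgs <- array(0, dim = c(cfg$frames, length(channels), cfg$height, cfg$width))
    labs <- array(0L, dim = c(cfg$frames, cfg$height, cfg$width))
    xs <- matrix(rep(seq_len(cfg$width), each = cfg$height), cfg$height)
    ys <- matrix(rep(seq_len(cfg$height), cfg$width), cfg$height)

    pop_val <- function(id, t_frame, col) {
      population[[col]][population$track_id == id & population$frame == t_frame]
    }

    for (t in seq_len(cfg$frames)) {
      cy_img <- matrix(0, cfg$height, cfg$width)
      mg_img <- matrix(0, cfg$height, cfg$width)
      tb_img <- matrix(0, cfg$height, cfg$width)
      lab_img <- matrix(0L, cfg$height, cfg$width)
      for (id in seq_len(n)) {
        dx <- xs - pos_x[t, id]
        dy <- ys - pos_y[t, id]
        u <- (dx * cos(theta[id]) + dy * sin(theta[id])) / ax[id]
        v <- (-dx * sin(theta[id]) + dy * cos(theta[id])) / bx[id]
        rr <- u^2 + v^2
        inside <- rr <= 1
        cyto <- rr > 1 & rr <= 2^2
        lab_img[inside] <- id
        cy_img[inside] <- cfg$nuclear_background + pop_val(id, t - 1L, "cyan")
        mg_img[inside] <- cfg$nuclear_background + pop_val(id, t - 1L, "magenta")
        if (cfg$tubulin) tb_img[cyto] <- pmax(tb_img[cyto], 0.6)
      }
      if (cfg$tubulin) {
        tb_img[lab_img > 0] <- 0  # nucleus-shaped void in the cytoplasmic channel
        cy_img <- cy_img + model$bleed_through * tb_img
      }
      imgs[t, 1, , ] <- cy_img
      imgs[t, 2, , ] <- mg_img
      if (cfg$tubulin) imgs[t, 3, , ] <- tb_img
      labs[t, , ] <- lab_img
    }

    noise_sd <- 0
    if (is.finite(cfg$target_snr) && cfg$target_snr > 0) {
      noise_sd <- calibrate_noise(imgs, labs, cfg$target_snr)
      imgs <- pmax(imgs + array(stats::rnorm(length(imgs), sd = noise_sd),
                                dim = dim(imgs)), 0)
    }

    tracks <- purrr::map(seq_len(n), function(id) {
      tibble(
        spot_id = (id - 1L) * cfg$frames + seq_len(cfg$frames),
        track_id = id, branch = "",
        frame = seq_len(cfg$frames) - 1L,
        x = pos_x[, id] - 1, y = pos_y[, id] - 1,  # 0-based pixel coords
        label = id,
        name = sprintf("n%d", id),
        interpolated = FALSE
      )
    }) |>
      dplyr::bind_rows()

    structure(
      list(
        images = image_stack(imgs, channels),
        labels = labs,
        tracks = tracks,
        population = population,
        noise_sd = noise_sd,
        config = cfg
      ),
      class = "fucci_movie"
    )
  })
}

reflect <- function(x, lo, hi) {
  x <- ifelse(x < lo, 2 * lo - x, x)
  ifelse(x > hi, 2 * hi - x, x)
}

# noise level such that the pooled mask SNR of the noisy stack hits the
# target: solve max_c (S_c - 0.4 sd) / sqrt(v_c + sd^2) = target
# (the 0.4 sd term accounts for the clipped background noise mean)
calibrate_noise <- function(imgs, labs, target) {
  inside <- labs > 0
  stats_c <- purrr::map(1:2, function(c_idx) {
    v <- imgs[, c_idx, , ]
    c(S = mean(v[inside]) - mean(v[!inside]), v = stats::var(v[inside]))
  })
  f <- function(sd) {
    max(purrr::map_dbl(stats_c, ~ (.x[["S"]] - 0.4 * sd) / sqrt(.x[["v"]] + sd^2))) - target
  }
  if (f(0) < 0) {
    stop_fucci(
      sprintf(
        "target SNR %.2g exceeds the noise-free SNR %.2g of this configuration;
increase nuclear_background or lower the target",
        target, f(0) + target
      ),
      "infeasible"
    )
  }
  upper <- 10 * sqrt(max(purrr::map_dbl(stats_c, ~ .x[["S"]]))^2 + 1)
  stats::uniroot(f, c(0, upper))$root
}

#' Nearest-neighbour centroid linker
#'
#' Minimal plumbing tracker for synthetic label stacks: links each instance
#' centroid to the nearest centroid of the previous frame (greedy, within
#' `max_dist`). Not a replacement for a real tracker; intended for tests and
#' examples where identities are unambiguous.
#'
#' @param labels Label stack `(time, y, x)`.
#' @param max_dist Maximum link distance in pixels.
#' @return Spot table in the format of [read_trackmate_xml()].
#' @export
track_centroids <- function(labels, max_dist = 15) {
  assert_label_stack(labels)
  n_t <- dim(labels)[[1]]
  cents <- purrr::map(seq_len(n_t), function(t) {
    lab <- labels[t, , ]
    ids <- sort(setdiff(unique(as.vector(lab)), 0))
    purrr::map(ids, function(id) {
      w <- which(lab == id, arr.ind = TRUE)
      tibble(frame = t - 1L, label = id,
             x = mean(w[, 2]) - 1, y = mean(w[, 1]) - 1)
    }) |>
      dplyr::bind_rows()
  })
  out <- cents[[1]]
  out$track_id <- seq_len(nrow(out))
  next_id <- nrow(out) + 1L
  prev <- out
  for (t in seq_len(n_t - 1)) {
    cur <- cents[[t + 1]]
    if (nrow(cur) == 0) {
      prev <- cur
      next
    }
    cur$track_id <- NA_integer_
    taken <- integer()
    for (i in seq_len(nrow(cur))) {
      if (nrow(prev) == 0) break
      d <- sqrt((prev$x - cur$x[[i]])^2 + (prev$y - cur$y[[i]])^2)
      d[prev$track_id %in% taken] <- Inf
      j <- which.min(d)
      if (is.finite(d[[j]]) && d[[j]] <= max_dist) {
        cur$track_id[[i]] <- prev$track_id[[j]]
        taken <- c(taken, prev$track_id[[j]])
      }
    }
    new <- is.na(cur$track_id)
    if (any(new)) {
      cur$track_id[new] <- seq.int(next_id, length.out = sum(new))
      next_id <- next_id + sum(new)
    }
    out <- dplyr::bind_rows(out, cur)
    prev <- cur
  }
  out$branch <- ""
  out$spot_id <- seq_len(nrow(out))
  out$name <- sprintf("t%d", out$track_id)
  out$interpolated <- FALSE
  out |>
    select("spot_id", "track_id", "branch", "frame", "x", "y",
           "label", "name", "interpolated") |>
    arrange(.data$track_id, .data$frame)
}
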