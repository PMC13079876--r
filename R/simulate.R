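# run code under a temporary RNG state so generators are reproducible
# without clobbering the caller's random stream
local_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(code)
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Cell-cycle model for the FUCCI track simulator
#'
#' Defines the intensity dynamics of the two FUCCI channels over one cell
#' cycle (0–100%). Phases occupy configurable fractions of the cycle
#' (defaults: G1 35%, G1/S 15%, S/G2/M 50%, typical of cultured mammalian
#' lines), with a dark window around mitosis in which both reporters are
#' degraded. The default profiles are piecewise-linear curves sampled at 1%
#' resolution from first-order synthesis/degradation kinetics — cyan
#' accumulates through G1 with saturating kinetics, both channels overlap in
#' G1/S, cyan is degraded at S entry while magenta accumulates through
#' S/G2/M — so the derivative varies continuously over the cycle, as real
#' FUCCI curves do. Profiles cross 10% of their maximum exactly at the
#' configured phase boundaries, making the generator consistent with the
#' intensity-threshold classifier by construction. A small floor (2% of the
#' dynamic range) emulates autofluorescence.
#'
#' @param cycle_frames Frames per full cycle (default 100).
#' @param phase_fractions Named fractions `c(G1=, G1S=, SG2M=)` summing to 1.
#' @param dark_window Half-width, in percent, of the dark window around
#'   mitosis (default 3).
#' @param noise_sigma Gaussian noise sd as a fraction of the dynamic range
#'   (default 0.05).
#' @param bleed_through Fraction of cytoplasmic (tubulin) signal added to
#'   the cyan channel during mitotic rounding (default 0).
#' @param profiles Optional custom breakpoint tibble with columns
#'   `percentage`, `cyan`, `magenta` (piecewise-linear interpolation).
#' @param seed Integer seed governing all stochastic draws of this model.
#' @return An object of class `fucci_cycle_model`.
#' @export
cycle_model <- function(cycle_frames = 100L,
                        phase_fractions = c(G1 = 0.35, G1S = 0.15, SG2M = 0.50),
                        dark_window = 3,
                        noise_sigma = 0.05,
                        bleed_through = 0,
                        profiles = NULL,
                        seed = 1L) {
  if (abs(sum(phase_fractions) - 1) > 1e-9 || any(phase_fractions <= 0)) {
    stop_fucci("phase fractions must be positive and sum to 1", "bad_input")
  }
  if (bleed_through < 0 || bleed_through >= 1) {
    stop_fucci("bleed_through must lie in [0, 1)", "bad_input")
  }
  b1 <- 100 * phase_fractions[["G1"]]
  b2 <- b1 + 100 * phase_fractions[["G1S"]]
  if (is.null(profiles)) {
    profiles <- default_profiles(b1, b2, dark_window)
  }
  if (any(profiles$cyan < 0) || any(profiles$magenta < 0)) {
    stop_fucci("profiles must be non-negative", "bad_input")
  }
  structure(
    list(
      cycle_frames = as.integer(cycle_frames),
      phase_fractions = phase_fractions,
      boundaries = c(g1_end = b1, g1s_end = b2),
      dark_window = dark_window,
      noise_sigma = noise_sigma,
      bleed_through = bleed_through,
      profiles = profiles,
      seed = as.integer(seed)
    ),
    class = "fucci_cycle_model"
  )
}

# piecewise-linear profiles sampled at 1% steps plus the exact boundary
# points. Each phase has two kinetic regimes (fast synthesis then slow
# saturation for cyan in G1; slow then fast accumulation for magenta in
# S/G2/M), as reporter degron kinetics show in practice; the resulting
# slope changes ("knees") make the normalized curve shape localizable
# everywhere along the cycle. Threshold crossings (10% of max) sit exactly
# on the phase boundaries, so the intensity classifier and the generator
# agree by construction.
default_profiles <- function(b1, b2, d, floor_level = 0.02, thr = 0.1) {
  pf <- b1 + 0.3 * (b2 - b1)          # cyan degradation onset inside G1/S
  m_on <- b1 - 2                      # magenta rise onset just before G1 end
  p_hi <- 100 - d                     # mitotic dark entry
  k_c <- d + 0.5 * (b1 - d)           # cyan synthesis knee (mid G1)
  k_m <- b1 + 0.6 * (p_hi - 1 - b1)   # magenta accumulation knee (mid S/G2)
  grid <- sort(unique(c(seq(0, 100, by = 1), d, b1, b2, pf, m_on,
                        p_hi, p_hi - 1, k_c, k_m)))

  cyan <- vapply(grid, function(p) {
    if (p <= d) {
      floor_level + (thr - floor_level) * p / d
    } else if (p <= k_c) {
      # fast initial synthesis
      tau <- (k_c - d) / 2.7
      thr + (0.85 - thr) * (1 - exp(-(p - d) / tau)) / (1 - exp(-(k_c - d) / tau))
    } else if (p <= b1) {
      # slow saturation to the G1/S peak
      0.85 + 0.15 * (p - k_c) / (b1 - k_c)
    } else if (p <= pf) {
      1
    } else if (p <= b2) {
      # abrupt degradation at S entry
      tau <- (b2 - pf) / 2.5
      e_end <- exp(-(b2 - pf) / tau)
      thr + (1 - thr) * (exp(-(p - pf) / tau) - e_end) / (1 - e_end)
    } else if (p <= p_hi) {
      thr * exp(-(p - b2) / 15)
    } else {
      v_hi <- thr * exp(-(p_hi - b2) / 15)
      v_hi + (floor_level - v_hi) * (p - p_hi) / d
    }
  }, numeric(1))

  magenta <- vapply(grid, function(p) {
    if (p <= m_on) {
      floor_level
    } else if (p <= b1) {
      floor_level + (thr - floor_level) * (p - m_on) / (b1 - m_on)
    } else if (p <= k_m) {
      # slow accumulation through S
      thr + (0.35 - thr) * ((p - b1) / (k_m - b1))^1.2
    } else if (p <= p_hi - 1) {
      # fast accumulation through G2/M
      0.35 + 0.65 * ((p - k_m) / (p_hi - 1 - k_m))^1.1
    } else if (p <= p_hi) {
      1 + (thr - 1) * (p - (p_hi - 1))
    } else {
      thr + (floor_level - thr) * (p - p_hi) / d
    }
  }, numeric(1))

  tibble(percentage = grid, cyan = cyan, magenta = magenta)
}

profile_at <- function(model, percentage, channel) {
  stats::approx(model$profiles$percentage, model$profiles[[channel]],
                xout = percentage %% 100, rule = 2)$y
}

# ground-truth phase of a cycle percentage under a model
phase_at_percentage <- function(model, percentage) {
  p <- percentage %% 100
  b <- model$boundaries
  d <- model$dark_window
  dplyr::case_when(
    p <= d | p >= 100 - d ~ "DARK",
    p <= b[["g1_end"]] ~ "G1",
    p < b[["g1s_end"]] ~ "G1S",
    .default = "SG2M"
  )
}

# mitotic-rounding indicator: 1 inside the dark window widened by 2%,
# used for cytoplasmic bleed-through into the cyan channel
rounding_at <- function(model, percentage) {
  p <- percentage %% 100
  d <- model$dark_window + 2
  as.numeric(p <= d | p >= 100 - d)
}

#' Simulate one FUCCI intensity track
#'
#' Normal cells advance their cycle percentage linearly
#' (`100 / cycle_frames` per frame), wrapping at 100; arrested cells advance
#' until they reach a G1 plateau percentage and then stay. Channel
#' intensities are the model profiles evaluated at the percentage plus
#' Gaussian noise (sd = `noise_sigma` x dynamic range), clipped at zero.
#' With `bleed_through > 0`, a fraction of the cytoplasmic signal is added
#' to the cyan channel during mitotic rounding, emulating the spectral
#' overlap that makes S/G2/M cells near mitosis look two-coloured.
#'
#' @param model A [cycle_model()].
#' @param start_percentage Cycle percentage at the first frame.
#' @param n_frames Number of frames (>= 2).
#' @param arrested Simulate a G1-arrested cell.
#' @param plateau_percentage G1 percentage at which arrested cells stop
#'   (default 20, mid-G1).
#' @param track_id Track id recorded in the output.
#' @param seed Seed (defaults to `model$seed`).
#' @return Tibble with columns `track_id`, `branch`, `frame`, `cyan`,
#'   `magenta`, `true_percentage`, `true_phase`, `arrested`.
#' @export
simulate_fucci_track <- function(model, start_percentage = 0, n_frames = 50L,
                                 arrested = FALSE, plateau_percentage = 20,
                                 track_id = 1L, seed = model$seed) {
  if (n_frames < 2) {
    stop_fucci("n_frames must be >= 2", "bad_input")
  }
  local_seed(seed, {
    step <- 100 / model$cycle_frames
    p <- (start_percentage + step * (seq_len(n_frames) - 1)) %% 100
    if (arrested) {
      # advance (wrapping) until the plateau is reached, then hold
      to_go <- (plateau_percentage - start_percentage) %% 100
      frames_to_plateau <- ceiling(to_go / step)
      hold <- seq_len(n_frames) - 1 >= frames_to_plateau
      p[hold] <- plateau_percentage
    }
    rng <- diff(range(model$profiles$cyan, model$profiles$magenta))
    noise_sd <- model$noise_sigma * rng
    cyan <- profile_at(model, p, "cyan") +
      model$bleed_through * rounding_at(model, p)
    magenta <- profile_at(model, p, "magenta")
    if (noise_sd > 0) {
      cyan <- cyan + stats::rnorm(n_frames, sd = noise_sd)
      magenta <- magenta + stats::rnorm(n_frames, sd = noise_sd)
    }
    tibble(
      track_id = as.integer(track_id), branch = "",
      frame = seq_len(n_frames) - 1L,
      cyan = pmax(cyan, 0), magenta = pmax(magenta, 0),
      true_percentage = p,
      true_phase = phase_at_percentage(model, p),
      arrested = arrested
    )
  })
}

#' Simulate a mixed population of normal and arrested tracks
#'
#' `round(arrest_fraction * n_tracks)` tracks are arrested, the remainder
#' cycle normally. Normal tracks start uniformly at random over the cycle;
#' arrested tracks sit at the G1 plateau for their whole duration (the
#' biological situation the arrest flag targets: cells already arrested,
#' e.g. by contact inhibition, when imaging starts).
#'
#' @param model A [cycle_model()].
#' @param n_tracks Number of tracks.
#' @param n_frames Frames per track.
#' @param arrest_fraction Fraction of arrested tracks in `[0, 1]`.
#' @param plateau_percentage G1 percentage at which arrested cells sit.
#' @param seed Seed (defaults to `model$seed`).
#' @return Long tibble (one row per track and frame) in the format of
#'   [simulate_fucci_track()].
#' @export
simulate_population <- function(model, n_tracks = 40L, n_frames = 60L,
                                arrest_fraction = 0, plateau_percentage = 20,
                                seed = model$seed) {
  n_arr <- round(arrest_fraction * n_tracks)
  local_seed(seed, {
    starts <- stats::runif(n_tracks, 0, 100)
    arrested <- seq_len(n_tracks) <= n_arr
    starts[arrested] <- plateau_percentage
    track_seeds <- sample.int(.Machine$integer.max - 1L, n_tracks)
    purrr::pmap(
      list(seq_len(n_tracks), starts, arrested, track_seeds),
      function(id, s0, arr, sd_i) {
        simulate_fucci_track(
          model, start_percentage = s0, n_frames = n_frames,
          arrested = arr, plateau_percentage = plateau_percentage,
          track_id = id, seed = sd_i
        )
      }
    ) |>
      dplyr::bind_rows()
  })
}

#' Reference curve of a cycle model
#'
#' The model's noiseless profiles as a `fucci_reference`, for aligning
#' simulated tracks.
#'
#' @param model A [cycle_model()].
#' @param n_points Percentage grid points (default 101).
#' @return A `fucci_reference` tibble.
#' @export
model_reference_curve <- function(model, n_points = 101L) {
  grid <- seq(0, 100, length.out = n_points)
  new_reference_curve(
    tibble(
      percentage = grid,
      cyan = profile_at(model, grid, "cyan"),
      magenta = profile_at(model, grid, "magenta")
    ),
    n_source_tracks = 1L
  )
}
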