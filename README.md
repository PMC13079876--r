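# fuccitrack

Cell-cycle pseudotime and arrest detection from FUCCI time-lapse tracks.

The FUCCI (Fluorescent Ubiquitination-based Cell Cycle Indicator) reporter
labels the cell cycle with two nuclear colours: in the convention used here,
cyan-only marks G1, both colours mark G1/S, magenta-only marks S/G2/M, and
around mitosis both reporters are degraded (DARK). After segmentation and
tracking, every nucleus yields a two-channel intensity time series — but a
track rarely spans a full cycle, and absolute intensities vary between
nuclei. `fuccitrack` solves the resulting decoding problem:

* **Where in the cycle is each cell at each frame?** The package builds a
  *reference curve* — average FUCCI dynamics over one cycle, indexed by
  cell-cycle percentage 0–100 — and locates each track inside it by
  **subsequence dynamic time warping (DTW)**: the query track is matched in
  full while the reference start and end stay free, the time axis is warped
  to minimise the accumulated Euclidean distance between preprocessed
  (smoothed, standardized, differenced) signals, and every frame inherits
  the cell-cycle percentage of its matched reference position — a
  *pseudotime*.
* **Which cells are not cycling at all?** The warping path's stretching and
  compression is summarised as the **relative time distortion**: the number
  of non-diagonal warping steps divided by the track length. Cells whose
  tracks must be strongly distorted to fit the reference — in particular
  G1-arrested cells sitting in a cyan-high plateau — score high and are
  flagged by thresholding the (typically bimodal) distortion histogram.

Around this core the package provides the standard workflow pieces:
tracking-XML import with gap closing and lineage splitting, nuclear
intensity extraction from label masks, frame-wise percentile normalization,
the 10%-of-maximum intensity phase classifier with FUCCI ↔ PIP-FUCCI
relabelling, IoU-matched instance-segmentation metrics (accuracy
`TP/(TP+FN+FP)`, precision `TP/(TP+FP)`, FP ratio, per-phase confusion
matrices), a mask-based SNR estimator, DAPI-equivalent channel construction,
and a fully seeded synthetic FUCCI movie simulator with ground truth, so the
whole pipeline is testable without any microscope data.

Intended users: bioimage analysts and cell biologists quantifying
cell-cycle progression, arrest, or drug response from multiplexed FUCCI
time lapses.

## Worked example

Simulate a mixed population (three cycling, three G1-arrested nuclei),
align every track to the model's reference curve, and flag arrest from the
distortion histogram:

```r
library(fuccitrack)
library(dplyr)

model     <- cycle_model(noise_sigma = 0.05, seed = 1)
reference <- model_reference_curve(model)
pop       <- simulate_population(model, n_tracks = 6, n_frames = 60,
                                 arrest_fraction = 0.5, seed = 1)

alignments <- align_tracks(pop, reference)
summary    <- glance(alignments)
thr        <- suggest_arrest_threshold(summary$relative_time_distortion)
summary |>
  mutate(arrested = flag_arrest(relative_time_distortion, thr)) |>
  select(track_id, distance, ref_start_pct, ref_end_pct,
         relative_time_distortion, arrested)
#> # A tibble: 6 × 6
#>   track_id distance ref_start_pct ref_end_pct relative_time_distortion arrested
#>      <int>    <dbl>         <dbl>       <dbl>                    <dbl> <lgl>
#> 1        1    16.6             44          44                   0.967  TRUE
#> 2        2    16.6             44          44                   0.967  TRUE
#> 3        3    16.6             44          44                   0.967  TRUE
#> 4        4     6.44            91          48                   0.0833 FALSE
#> 5        5     5.78            24          77                   0.183  FALSE
#> 6        6     7.47            90          47                   0.117  FALSE
```

The three arrested tracks collapse onto a single reference position
(`ref_start_pct == ref_end_pct`): fitting a 60-frame plateau onto one point
of the reference takes 58 non-diagonal warping steps, hence a relative time
distortion near 1 — far above the cycling tracks (≤ 0.19). `tidy()` gives
the per-frame pseudotime; track 5 starts at 24% of the cycle and reaches
78% sixty frames later, tracking its simulated ground truth:

```r
tidy(alignments) |> filter(track_id == 5) |> slice(c(1, 30, 60))
#> # A tibble: 3 × 5
#>   track_id branch frame pseudotime arrested
#>      <int> <chr>  <int>      <dbl> <lgl>
#> 1        5 ""         0         24 FALSE
#> 2        5 ""        29         48 FALSE
#> 3        5 ""        59         78 FALSE
```

`autoplot(alignments)` draws the pseudotime trajectories,
`plot_distortion_histogram(alignments, thr)` the arrest-score histogram,
and `autoplot(reference)` the reference curve.

The arrest threshold is dataset-dependent: the distortion scale depends on
the reference sampling and track lengths, so inspect the histogram (or use
`suggest_arrest_threshold()`) rather than relying on any fixed value.

## Command line

A thin CLI over the same functions ships with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "fucci.R", package = "fuccitrack"))')" \
    simulate tracks --seed 1 --out demo --n-tracks 6 --arrest-fraction 0.5
```

Subcommands: `simulate tracks|movie`, `extract`, `classify`, `align`,
`eval-seg`, `snr`, `dapi-equiv`, `merge-masks`, `filter-crops`,
`io convert|close-gaps`. Every run writes a `*.config.json` echo of its
parameters next to its outputs.

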