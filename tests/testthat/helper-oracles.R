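# Independent oracles kept deliberately simple and separate from the
# package's implementations.

# Exhaustive subsequence-DTW distance: for every reference start position,
# run a closed-begin DP (same step set, unit weights) and take the minimum
# over all end positions.
brute_subsequence_distance <- function(q, r) {
  q <- as.matrix(q)
  r <- as.matrix(r)
  n <- nrow(q)
  m <- nrow(r)
  best <- Inf
  for (s in seq_len(m)) {
    width <- m - s + 1
    D <- matrix(Inf, n, width)
    for (i in seq_len(n)) {
      for (jj in seq_len(width)) {
        j <- s + jj - 1
        cost <- sqrt(sum((q[i, ] - r[j, ])^2))
        if (i == 1 && jj == 1) {
          D[i, jj] <- cost
        } else {
          prev <- Inf
          if (i > 1 && jj > 1) prev <- min(prev, D[i - 1, jj - 1])
          if (i > 1) prev <- min(prev, D[i - 1, jj])
          if (jj > 1) prev <- min(prev, D[i, jj - 1])
          D[i, jj] <- prev + cost
        }
      }
    }
    best <- min(best, min(D[n, ]))
  }
  best
}

# Maximum number of one-to-one matches among pairs with IoU >= threshold,
# by exhaustive recursion over ground-truth rows.
brute_max_matching <- function(iou, threshold) {
  ok <- iou >= threshold
  n_gt <- nrow(ok)
  recurse <- function(g, used) {
    if (g > n_gt) {
      return(0L)
    }
    best <- recurse(g + 1, used) # leave g unmatched
    for (p in seq_len(ncol(ok))) {
      if (ok[g, p] && !(p %in% used)) {
        best <- max(best, 1L + recurse(g + 1, c(used, p)))
      }
    }
    best
  }
  if (n_gt == 0 || ncol(ok) == 0) {
    return(0L)
  }
  recurse(1L, integer())
}

# circular difference on the percentage axis
pct_diff <- function(a, b) {
  (a - b + 50) %% 100 - 50
}

# draw a random label image with up to n_obj square-ish objects
random_label_image <- function(size, n_obj, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  lab <- matrix(0L, size, size)
  for (id in seq_len(n_obj)) {
    w <- sample(2:6, 1)
    y <- sample(seq_len(size - w), 1)
    x <- sample(seq_len(size - w), 1)
    lab[y:(y + w), x:(x + w)] <- id
  }
  lab
}

make_linear_tracks <- function(n_frames = 5, track_id = 1L) {
  tibble::tibble(
    spot_id = seq_len(n_frames),
    track_id = track_id,
    branch = "",
    frame = seq_len(n_frames) - 1L,
    x = as.numeric(seq_len(n_frames)),
    y = rep(2, n_frames),
    label = 1L,
    name = paste0("s", seq_len(n_frames)),
    interpolated = FALSE
  )
}
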