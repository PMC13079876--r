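#' Subsequence dynamic time warping
#'
#' Aligns a query feature sequence to the best-matching window of a reference
#' feature sequence: the query is matched in full while the reference start
#' and end are free (open-begin / open-end on the reference only), so partial
#' cell-cycle tracks can be located inside a full-cycle reference. The local
#' cost is the Euclidean distance between feature vectors (absolute
#' difference in 1-D); allowed steps are diagonal `(1,1)`, query-only `(1,0)`
#' (compression) and reference-only `(0,1)` (expansion), all with unit
#' weight. Among equal-cost paths the one with fewer non-diagonal steps is
#' preferred, then the earliest reference start, making the time-distortion
#' value deterministic.
#'
#' @param query,reference Numeric vectors, matrices (rows = samples, columns
#'   = features) or [fucci_features()] objects. Feature dimensions must
#'   agree.
#' @return A list of class `fucci_dtw`: `path` (integer matrix with columns
#'   `query_idx`, `ref_idx`, 1-based), `distance` (accumulated cost),
#'   `ref_window` (`c(start, end)` reference sample indices),
#'   `n_query`, `n_reference`.
#' @export
subsequence_dtw <- function(query, reference) {
  q <- as_feature_matrix(query)
  r <- as_feature_matrix(reference)
  n <- nrow(q)
  m <- nrow(r)
  if (n < 1 || m < 1) {
    stop_fucci("query and reference must be non-empty", "bad_input")
  }
  if (ncol(q) != ncol(r)) {
    stop_fucci(
      sprintf("feature dimensions differ: query %d, reference %d", ncol(q), ncol(r)),
      "bad_input"
    )
  }

  # local cost: L2 over features
  C2 <- matrix(0, n, m)
  for (f in seq_len(ncol(q))) {
    C2 <- C2 + outer(q[, f], r[, f], `-`)^2
  }
  C <- sqrt(C2)

  D <- matrix(Inf, n, m)   # accumulated cost
  N <- matrix(0L, n, m)    # non-diagonal steps on the optimal path
  S <- matrix(0L, n, m)    # reference start index of the optimal path
  B <- matrix(0L, n, m)    # backpointer: 0 start, 1 diag, 2 query-only, 3 ref-only

  D[1, ] <- C[1, ]
  S[1, ] <- seq_len(m)
  if (n > 1) {
    for (i in 2:n) {
      # j = 1: only the query-only step is available
      D[i, 1] <- D[i - 1, 1] + C[i, 1]
      N[i, 1] <- N[i - 1, 1] + 1L
      S[i, 1] <- 1L
      B[i, 1] <- 2L
      for (j in 2:m) {
        cd <- D[i - 1, j - 1]
        cu <- D[i - 1, j]
        cl <- D[i, j - 1]
        # lexicographic (cost, non-diagonal count, start index); diagonal wins ties
        best_c <- cd; best_n <- N[i - 1, j - 1]; best_s <- S[i - 1, j - 1]; best_b <- 1L
        nn <- N[i - 1, j] + 1L
        if (cu < best_c ||
            (cu == best_c && (nn < best_n ||
                              (nn == best_n && S[i - 1, j] < best_s)))) {
          best_c <- cu; best_n <- nn; best_s <- S[i - 1, j]; best_b <- 2L
        }
        nn <- N[i, j - 1] + 1L
        if (cl < best_c ||
            (cl == best_c && (nn < best_n ||
                              (nn == best_n && S[i, j - 1] < best_s)))) {
          best_c <- cl; best_n <- nn; best_s <- S[i, j - 1]; best_b <- 3L
        }
        D[i, j] <- best_c + C[i, j]
        N[i, j] <- best_n
        S[i, j] <- best_s
        B[i, j] <- best_b
      }
    }
  }

  # open end: best terminal column, same tie-breaking
  ord <- order(D[n, ], N[n, ], S[n, ], seq_len(m))
  j_end <- ord[[1]]

  # traceback
  path <- matrix(0L, n + m, 2)
  i <- n; j <- j_end; k <- 0L
  repeat {
    k <- k + 1L
    path[k, ] <- c(i, j)
    if (i == 1 && B[i, j] == 0L) break
    b <- B[i, j]
    if (i == 1) b <- 0L
    if (b == 1L) {
      i <- i - 1L; j <- j - 1L
    } else if (b == 2L) {
      i <- i - 1L
    } else if (b == 3L) {
      j <- j - 1L
    } else {
      break
    }
  }
  path <- path[seq_len(k), , drop = FALSE][k:1, , drop = FALSE]
  colnames(path) <- c("query_idx", "ref_idx")

  structure(
    list(
      path = path,
      distance = D[n, j_end],
      ref_window = c(start = S[n, j_end], end = j_end),
      n_query = n,
      n_reference = m
    ),
    class = "fucci_dtw"
  )
}

as_feature_matrix <- function(x) {
  if (inherits(x, "fucci_features")) {
    return(unclass(x)[, , drop = FALSE])
  }
  if (is.matrix(x)) {
    return(x)
  }
  matrix(as.numeric(x), ncol = 1)
}

#' @export
print.fucci_dtw <- function(x, ...) {
  cat(sprintf(
    "<fucci_dtw> query %d ~ reference[%d..%d], distance %.4g, %d path steps\n",
    x$n_query, x$ref_window[["start"]], x$ref_window[["end"]],
    x$distance, nrow(x$path) - 1L
  ))
  invisible(x)
}

#' Time distortion of a warping path
#'
#' Counts the stretching and compression applied by the alignment: the number
#' of non-diagonal steps (reference-only expansions plus query-only
#' compressions) along the warping path, optionally weighted per step type. A
#' purely diagonal path — the query already runs at reference speed — scores
#' 0. This count is the arrest score before length normalization; it is kept
#' behind this single function so an alternative stretch/compression
#' weighting can be swapped in without touching callers.
#'
#' @param path A `fucci_dtw` object or its integer path matrix.
#' @param expansion_weight,compression_weight Per-step weights for
#'   reference-only and query-only steps (default 1 each).
#' @return Non-negative numeric scalar.
#' @export
time_distortion <- function(path, expansion_weight = 1, compression_weight = 1) {
  if (inherits(path, "fucci_dtw")) path <- path$path
  if (nrow(path) < 2) {
    return(0)
  }
  dq <- diff(path[, 1])
  dr <- diff(path[, 2])
  if (any(dq < 0) || any(dr < 0) || any(dq + dr == 0) || any(dq > 1) || any(dr > 1)) {
    stop_fucci("invalid warping path: steps must be (1,0), (0,1) or (1,1)", "bad_input")
  }
  expansion_weight * sum(dq == 0) + compression_weight * sum(dr == 0)
}

#' Relative time distortion
#'
#' The time-distortion value divided by the number of query frames, making
#' the arrest score comparable between tracks of different lengths.
#'
#' @param distortion Value from [time_distortion()].
#' @param query_len Number of query frames (>= 1).
#' @return Non-negative numeric scalar.
#' @export
relative_time_distortion <- function(distortion, query_len) {
  if (query_len < 1) {
    stop_fucci("query length must be >= 1", "bad_input")
  }
  distortion / query_len
}

#' Map a warping path to cell-cycle percentage per query sample
#'
#' Each query sample is assigned the mean reference percentage of the
#' reference samples it is matched to. The result need not be monotone (the
#' warping may locally plateau) but always lies within the span of the
#' matched reference window. With a tiled (wrap-around) reference the mean is
#' taken on the unwrapped axis and reported modulo 100.
#'
#' @param path A `fucci_dtw` object or path matrix.
#' @param percentage Reference percentage per reference sample (may exceed
#'   100 for tiled references).
#' @param wrap Report modulo 100 (default `TRUE`).
#' @return Numeric vector, one percentage per query sample.
#' @export
assign_pseudotime <- function(path, percentage, wrap = TRUE) {
  if (inherits(path, "fucci_dtw")) path <- path$path
  pt <- tapply(percentage[path[, 2]], path[, 1], mean)
  out <- as.numeric(pt[order(as.integer(names(pt)))])
  if (wrap) wrap_percentage(out) else out
}

#' Flag cell-cycle arrest from the relative time distortion
#'
#' A track is flagged as arrested when its relative time distortion exceeds
#' the threshold. The default threshold of 5 separates normally cycling from
#' G1-arrested cells in the dataset the method was developed on, but the
#' value is dataset-dependent (it was defined manually from the distortion
#' histogram) and should be checked against the histogram of each dataset,
#' e.g. with [suggest_arrest_threshold()].
#'
#' @param result A `fucci_alignment` object or a numeric relative
#'   time-distortion value.
#' @param threshold Positive arrest threshold (default 5).
#' @return Logical.
#' @export
flag_arrest <- function(result, threshold = 5) {
  if (threshold <= 0) {
    stop_fucci("arrest threshold must be > 0", "bad_input")
  }
  value <- if (inherits(result, "fucci_alignment")) {
    result$relative_time_distortion
  } else {
    as.numeric(result)
  }
  value > threshold
}

#' Suggest an arrest threshold from a distortion histogram
#'
#' Mirrors manual histogram thresholding of a bimodal relative
#' time-distortion distribution: returns the midpoint of the largest gap
#' between consecutive sorted values. Only meaningful when the population
#' actually contains two sub-populations.
#'
#' @param values Numeric vector of relative time-distortion values (>= 2).
#' @return Numeric threshold.
#' @export
suggest_arrest_threshold <- function(values) {
  values <- sort(values[is.finite(values)])
  if (length(values) < 2) {
    stop_fucci("need at least two distortion values", "bad_input")
  }
  gaps <- diff(values)
  i <- which.max(gaps)
  (values[[i]] + values[[i + 1]]) / 2
}
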