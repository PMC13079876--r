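#' Intersection-over-union matrix between two label images
#'
#' Entry `(g, p)` is the IoU of ground-truth instance `g` and predicted
#' instance `p` (background 0 excluded). Row and column names carry the
#' instance label values.
#'
#' @param gt,pred Integer label matrices (or single-frame label arrays) of
#'   the same shape.
#' @return Numeric matrix (ground truth x predicted) with values in
#'   `[0, 1]`.
#' @export
iou_matrix <- function(gt, pred) {
  gt <- drop(gt); pred <- drop(pred)
  if (!all(dim(gt) == dim(pred))) {
    stop_fucci("gt and pred label images must share their shape", "bad_input")
  }
  gt_ids <- sort(setdiff(unique(as.vector(gt)), 0))
  pred_ids <- sort(setdiff(unique(as.vector(pred)), 0))
  out <- matrix(
    0, length(gt_ids), length(pred_ids),
    dimnames = list(as.character(gt_ids), as.character(pred_ids))
  )
  if (length(gt_ids) == 0 || length(pred_ids) == 0) {
    return(out)
  }
  areas_gt <- table(factor(gt[gt > 0], levels = gt_ids))
  areas_pred <- table(factor(pred[pred > 0], levels = pred_ids))
  both <- gt > 0 & pred > 0
  if (any(both)) {
    inter <- table(
      factor(gt[both], levels = gt_ids),
      factor(pred[both], levels = pred_ids)
    )
    uni <- outer(as.numeric(areas_gt), as.numeric(areas_pred), `+`) - inter
    out[] <- as.numeric(inter) / as.numeric(uni)
  }
  out
}

#' Match instances at an IoU threshold
#'
#' One-to-one matching between ground-truth and predicted instances over the
#' pairs with IoU at or above the threshold, maximizing the number of
#' matches first and the total IoU among those (optimal assignment, not
#' greedy). Matched pairs are true positives; unmatched predictions are
#' false positives; unmatched ground-truth instances are false negatives.
#'
#' @param iou IoU matrix from [iou_matrix()].
#' @param threshold IoU threshold in `(0, 1]` (default 0.5, the conventional
#'   evaluation point).
#' @return A list of class `fucci_match`: `matches` (tibble with `gt`,
#'   `pred`, `iou`), `tp`, `fp`, `fn`, `threshold`.
#' @export
match_masks <- function(iou, threshold = 0.5) {
  if (threshold <= 0 || threshold > 1) {
    stop_fucci("IoU threshold must lie in (0, 1]", "bad_input")
  }
  n_gt <- nrow(iou)
  n_pred <- ncol(iou)
  cand <- which(iou >= threshold, arr.ind = TRUE)
  if (nrow(cand) == 0) {
    matches <- tibble(gt = integer(), pred = integer(), iou = double())
  } else {
    w <- iou[cand]
    # + 2 makes every additional match outweigh any total-IoU difference,
    # so cardinality is maximized first, total IoU second
    g <- igraph::make_bipartite_graph(
      types = c(rep(FALSE, n_gt), rep(TRUE, n_pred)),
      edges = as.vector(t(cbind(cand[, 1], n_gt + cand[, 2]))),
      directed = FALSE
    )
    mm <- igraph::max_bipartite_match(g, weights = w + 2)$matching
    matched_gt <- which(!is.na(mm[seq_len(n_gt)]))
    matched_pred <- mm[matched_gt] - n_gt
    matches <- tibble(
      gt = as.integer(rownames(iou)[matched_gt]),
      pred = as.integer(colnames(iou)[matched_pred]),
      iou = iou[cbind(matched_gt, matched_pred)]
    )
  }
  structure(
    list(
      matches = matches,
      tp = nrow(matches),
      fp = n_pred - nrow(matches),
      fn = n_gt - nrow(matches),
      threshold = threshold
    ),
    class = "fucci_match"
  )
}

#' @export
print.fucci_match <- function(x, ...) {
  cat(sprintf(
    "<fucci_match> IoU >= %.2f: TP %d, FP %d, FN %d (accuracy %.3f)\n",
    x$threshold, x$tp, x$fp, x$fn,
    if (x$tp + x$fp + x$fn > 0) x$tp / (x$tp + x$fp + x$fn) else NA_real_
  ))
  invisible(x)
}

#' Instance-segmentation summary metrics
#'
#' `accuracy_at_iou()` is the average-precision-style accuracy
#' `TP / (TP + FN + FP)`; `precision_at_iou()` is `TP / (TP + FP)`;
#' `fp_ratio()` is the number of false-positive labels divided by the number
#' of predicted masks, `FP / (TP + FP)`.
#'
#' @param m A `fucci_match` from [match_masks()].
#' @return Numeric scalar.
#' @export
accuracy_at_iou <- function(m) {
  if (m$tp + m$fp + m$fn == 0) {
    stop_fucci("accuracy undefined: no ground-truth or predicted instances", "undefined")
  }
  m$tp / (m$tp + m$fn + m$fp)
}

#' @rdname accuracy_at_iou
#' @export
precision_at_iou <- function(m) {
  if (m$tp + m$fp == 0) {
    stop_fucci("precision undefined: no predicted instances", "undefined")
  }
  m$tp / (m$tp + m$fp)
}

#' @rdname accuracy_at_iou
#' @export
fp_ratio <- function(m) {
  if (m$tp + m$fp == 0) {
    stop_fucci("FP ratio undefined: no predicted instances", "undefined")
  }
  m$fp / (m$tp + m$fp)
}

#' Accuracy as a function of the IoU threshold
#'
#' Evaluates [accuracy_at_iou()] over a sequence of thresholds on one shared
#' IoU matrix. The curve is monotone non-increasing in the threshold.
#'
#' @param gt,pred Label matrices (see [iou_matrix()]).
#' @param thresholds Numeric thresholds in `(0, 1]`.
#' @return Tibble with columns `threshold`, `accuracy`, `tp`, `fp`, `fn`.
#' @export
accuracy_curve <- function(gt, pred, thresholds = seq(0.5, 0.95, by = 0.05)) {
  iou <- iou_matrix(gt, pred)
  purrr::map(thresholds, function(th) {
    m <- match_masks(iou, th)
    tibble(
      threshold = th,
      accuracy = if (m$tp + m$fp + m$fn > 0) accuracy_at_iou(m) else NA_real_,
      tp = m$tp, fp = m$fp, fn = m$fn
    )
  }) |>
    dplyr::bind_rows()
}

#' Per-phase precision and accuracy matrices
#'
#' Matches masks at an IoU threshold, then cross-tabulates predicted versus
#' ground-truth phase over the matched pairs. The precision entry `(p, g)`
#' is the fraction of matched masks predicted as `p` whose ground truth is
#' `g` (rows computed over matched masks only). The accuracy entry
#' additionally charges segmentation errors: its denominator is the number
#' of matched pairs predicted `p` or labelled `g`, plus unmatched
#' ground-truth masks (FN) of class `g`, plus unmatched predicted masks
#' (FP) of class `p` — so the diagonal reduces to `TP/(TP+FN+FP)` per class
#' when classification is perfect. Rows or entries with an empty denominator
#' are `NaN` (undefined), not zero.
#'
#' @param gt,pred Label matrices.
#' @param gt_phases,pred_phases Tibbles with columns `label`, `phase` giving
#'   the phase of each mask instance.
#' @param threshold IoU matching threshold (default 0.5).
#' @param classes Phase classes of the matrices (default G1, G1S, SG2M).
#' @return A list of class `fucci_confusion`: `precision_matrix` and
#'   `accuracy_matrix` (predicted x ground truth), plus the `fucci_match`.
#' @export
class_confusion <- function(gt, pred, gt_phases, pred_phases, threshold = 0.5,
                            classes = c("G1", "G1S", "SG2M")) {
  m <- match_masks(iou_matrix(gt, pred), threshold)
  gt_lookup <- stats::setNames(gt_phases$phase, gt_phases$label)
  pred_lookup <- stats::setNames(pred_phases$phase, pred_phases$label)

  mt <- m$matches
  mt$gt_phase <- unname(gt_lookup[as.character(mt$gt)])
  mt$pred_phase <- unname(pred_lookup[as.character(mt$pred)])
  mt <- mt[mt$gt_phase %in% classes & mt$pred_phase %in% classes, ]

  counts <- table(
    factor(mt$pred_phase, levels = classes),
    factor(mt$gt_phase, levels = classes)
  )
  counts <- matrix(as.numeric(counts), length(classes), length(classes),
                   dimnames = list(predicted = classes, ground_truth = classes))

  gt_ids <- as.integer(rownames(iou_matrix(gt, pred)))
  # unmatched instances per class
  all_gt <- sort(setdiff(unique(as.vector(drop(gt))), 0))
  all_pred <- sort(setdiff(unique(as.vector(drop(pred))), 0))
  fn_ids <- setdiff(all_gt, m$matches$gt)
  fp_ids <- setdiff(all_pred, m$matches$pred)
  fn_by_class <- table(factor(unname(gt_lookup[as.character(fn_ids)]), levels = classes))
  fp_by_class <- table(factor(unname(pred_lookup[as.character(fp_ids)]), levels = classes))

  row_tot <- rowSums(counts)  # matched masks predicted p
  col_tot <- colSums(counts)  # matched masks with gt g
  precision_matrix <- sweep(counts, 1, row_tot, `/`)

  accuracy_matrix <- counts
  for (p in seq_along(classes)) {
    for (g in seq_along(classes)) {
      denom <- row_tot[[p]] + col_tot[[g]] - counts[p, g] +
        as.numeric(fn_by_class[[g]]) + as.numeric(fp_by_class[[p]])
      accuracy_matrix[p, g] <- if (denom > 0) counts[p, g] / denom else NaN
    }
  }

  structure(
    list(
      precision_matrix = precision_matrix,
      accuracy_matrix = accuracy_matrix,
      counts = counts,
      match = m
    ),
    class = "fucci_confusion"
  )
}

#' Signal-to-noise ratio from ground-truth nuclear masks
#'
#' Per FUCCI channel: the mean signal inside the nuclear masks is corrected
#' by the background (the mean signal outside the masks) and divided by the
#' standard deviation of the signal inside the masks. The final SNR is the
#' maximum over the two channels. The estimate is invariant under positive
#' affine transforms of the intensities.
#'
#' @param images A [image_stack()].
#' @param labels Ground-truth label stack of matching `(time, y, x)` shape.
#' @param channels Channel names to evaluate (default cyan and magenta).
#' @return A list of class `fucci_snr`: `per_channel_snr` (named numeric)
#'   and `snr` (their maximum).
#' @export
compute_snr <- function(images, labels, channels = c("cyan", "magenta")) {
  stopifnot(inherits(images, "fucci_stack"))
  assert_label_stack(labels)
  if (!all(dim(labels) == dim(images$data)[c(1, 3, 4)])) {
    stop_fucci("labels and images must share their (time, y, x) shape", "bad_input")
  }
  missing_ch <- setdiff(channels, images$channels)
  if (length(missing_ch) > 0) {
    stop_fucci(
      sprintf("channel(s) not in stack: %s", paste(missing_ch, collapse = ", ")),
      "bad_input"
    )
  }
  inside <- labels > 0
  if (!any(inside)) {
    stop_fucci("label stack contains no masks", "bad_input")
  }
  per <- vapply(channels, function(ch) {
    c_idx <- match(ch, images$channels)
    v <- images$data[, c_idx, , ]
    s_in <- v[inside]
    s_out <- v[!inside]
    sd_in <- stats::sd(s_in)
    if (!is.finite(sd_in) || sd_in == 0) {
      stop_fucci(
        sprintf(
          "zero in-mask variance in channel %s; the SNR is undefined on noise-free data",
          ch
        ),
        "undefined"
      )
    }
    (mean(s_in) - mean(s_out)) / sd_in
  }, numeric(1))
  structure(
    list(per_channel_snr = per, snr = max(per)),
    class = "fucci_snr"
  )
}

#' @export
print.fucci_snr <- function(x, ...) {
  cat(sprintf(
    "<fucci_snr> %s -> SNR %.3g\n",
    paste(sprintf("%s %.3g", names(x$per_channel_snr), x$per_channel_snr),
          collapse = ", "),
    x$snr
  ))
  invisible(x)
}
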