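test_that("IoU matrix matches hand-computed overlaps", {
  a <- matrix(0L, 6, 6)
  a[2:3, 2:3] <- 1L
  b <- a
  expect_equal(unname(iou_matrix(a, b)[1, 1]), 1)

  disjoint <- matrix(0L, 6, 6)
  disjoint[5:6, 5:6] <- 1L
  expect_equal(unname(iou_matrix(a, disjoint)[1, 1]), 0)

  half <- matrix(0L, 6, 6)
  half[2, 2:3] <- 1L # 2 of the 4 gt pixels
  expect_equal(unname(iou_matrix(a, half)[1, 1]), 0.5)

  expect_error(iou_matrix(a, matrix(0L, 5, 5)), class = "fuccitrack_bad_input")
})

test_that("mask matching satisfies the tp/fp/fn bookkeeping", {
  gt <- matrix(0L, 8, 8)
  gt[1:2, 1:2] <- 1L
  gt[5:6, 5:6] <- 2L
  m_same <- match_masks(iou_matrix(gt, gt), 0.5)
  expect_equal(c(m_same$tp, m_same$fp, m_same$fn), c(2, 0, 0))

  pred <- gt
  pred[1:2, 6:7] <- 3L # spurious object
  m_fp <- match_masks(iou_matrix(gt, pred), 0.5)
  expect_equal(c(m_fp$tp, m_fp$fp, m_fp$fn), c(2, 1, 0))
  expect_true(all(m_fp$matches$iou >= 0.5))
})

test_that("matching equals the brute-force maximum on random fixtures", {
  set.seed(17)
  for (case in 1:50) {
    gt <- random_label_image(24, sample(1:6, 1))
    pred <- random_label_image(24, sample(1:6, 1))
    iou <- iou_matrix(gt, pred)
    m <- match_masks(iou, 0.5)
    expect_equal(m$tp, brute_max_matching(iou, 0.5))
    expect_equal(m$fp, ncol(iou) - m$tp)
    expect_equal(m$fn, nrow(iou) - m$tp)
  }
})

test_that("summary metrics follow their quoted formulas", {
  m <- structure(list(tp = 9, fp = 1, fn = 1), class = "fucci_match")
  expect_equal(accuracy_at_iou(m), 9 / 11)
  expect_equal(precision_at_iou(m), 0.9)
  expect_equal(fp_ratio(m), 0.1)

  perfect <- structure(list(tp = 5, fp = 0, fn = 0), class = "fucci_match")
  expect_equal(accuracy_at_iou(perfect), 1)
  expect_equal(precision_at_iou(perfect), 1)
  expect_equal(fp_ratio(perfect), 0)

  empty <- structure(list(tp = 0, fp = 0, fn = 0), class = "fucci_match")
  expect_error(accuracy_at_iou(empty), class = "fuccitrack_undefined")
})

test_that("accuracy curves are monotone non-increasing", {
  gt <- matrix(0L, 6, 6)
  gt[2:3, 2:3] <- 1L
  half <- matrix(0L, 6, 6)
  half[2, 2:3] <- 1L
  curve <- accuracy_curve(gt, half, thresholds = c(0.3, 0.5, 0.6))
  expect_equal(curve$accuracy, c(1, 1, 0)) # drops above IoU 0.5

  ident <- accuracy_curve(gt, gt, thresholds = seq(0.05, 0.95, by = 0.1))
  expect_true(all(ident$accuracy == 1))

  set.seed(23)
  for (case in 1:10) {
    g <- random_label_image(32, 6)
    p <- random_label_image(32, 6)
    acc <- accuracy_curve(g, p, thresholds = seq(0.1, 0.9, by = 0.1))$accuracy
    expect_true(all(diff(acc) <= 1e-12))
  }
})

test_that("class confusion matrices separate precision and accuracy", {
  gt <- matrix(0L, 10, 10)
  gt[1:2, 1:2] <- 1L
  gt[5:6, 5:6] <- 2L
  gt[8:9, 8:9] <- 3L
  phases_gt <- tibble::tibble(label = 1:3, phase = c("G1", "G1S", "SG2M"))

  # perfect masks + labels -> identity matrices
  cc <- class_confusion(gt, gt, phases_gt, phases_gt)
  expect_equal(unname(diag(cc$precision_matrix)), rep(1, 3))
  expect_equal(unname(diag(cc$accuracy_matrix)), rep(1, 3))

  # all G1 predicted as G1S: that precision row concentrates on G1
  phases_pred <- tibble::tibble(
    label = 1:3, phase = c("G1S", "G1S", "SG2M")
  )
  cc2 <- class_confusion(gt, gt, phases_gt, phases_pred)
  expect_equal(unname(cc2$precision_matrix["G1S", "G1"]), 0.5)
  expect_equal(unname(cc2$precision_matrix["G1S", "G1S"]), 0.5)
  expect_true(is.nan(cc2$precision_matrix["G1", "G1"]))

  # with segmentation errors, accuracy entries cannot exceed precision
  pred <- gt
  pred[gt == 3L] <- 0L # miss one mask
  pred[1:2, 5:6] <- 4L # hallucinate one
  phases_pred2 <- tibble::tibble(label = c(1, 2, 4), phase = c("G1", "G1S", "G1"))
  cc3 <- class_confusion(gt, pred, phases_gt, phases_pred2)
  ok <- is.finite(cc3$precision_matrix)
  expect_true(all(cc3$accuracy_matrix[ok] <= cc3$precision_matrix[ok] + 1e-12))
  expect_equal(unname(cc3$accuracy_matrix["G1", "G1"]), 1 / 2) # 1 match, 1 FP
})

test_that("the SNR estimator matches the mask-based definition", {
  set.seed(5)
  labs <- array(0L, dim = c(1, 60, 60))
  labs[1, 11:40, 11:40] <- 1L
  img <- array(rnorm(3600, 2, 1e-3), dim = c(1, 2, 60, 60))
  noise <- rnorm(sum(labs == 1L), 10, 2)
  img[1, 1, , ][labs[1, , ] == 1L] <- noise
  img[1, 2, , ][labs[1, , ] == 1L] <- rnorm(sum(labs == 1L), 2, 1e-3) # ~no signal
  st <- image_stack(img, c("cyan", "magenta"))
  est <- compute_snr(st, labs)
  expect_equal(est$per_channel_snr[["cyan"]], 4, tolerance = 0.15)
  expect_equal(est$snr, max(est$per_channel_snr))

  # invariance under positive affine transforms
  st2 <- image_stack(3 * img + 5, c("cyan", "magenta"))
  est2 <- compute_snr(st2, labs)
  expect_equal(est2$per_channel_snr, est$per_channel_snr, tolerance = 1e-9)

  flat <- image_stack(array(1, dim = c(1, 2, 8, 8)),
                      c("cyan", "magenta"))
  labs2 <- array(0L, dim = c(1, 8, 8))
  labs2[1, 2:4, 2:4] <- 1L
  expect_error(compute_snr(flat, labs2), class = "fuccitrack_undefined")
})
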