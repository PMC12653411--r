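# Overlap and surface-distance metric tests against enumeration oracles.

test_that("confusion counts match exhaustive enumeration", {
  set.seed(1)
  for (rep in 1:10) {
    pred <- random_mask(4, 4); gt <- random_mask(4, 4)
    for (k in 0:2)
      expect_identical(lapply(confusion_counts(pred, gt, k), as.integer),
                       oracle_confusion(pred, gt, k))
  }
  g <- matrix(c(1, 1, 0, 2), 2, 2)
  expect_equal(confusion_counts(g, g, 1)$tp, 2)
  expect_equal(confusion_counts(g, g, 1)$fp, 0)
  all_bg <- matrix(0L, 2, 2)
  cc <- confusion_counts(all_bg, g, 1)
  expect_equal(cc$tp, 0); expect_equal(cc$fn, 2)
})

test_that("IoU and DSC arithmetic and their identity hold", {
  expect_equal(iou(list(tp = 6, fp = 0, fn = 0)), 1)
  expect_equal(iou(list(tp = 0, fp = 1, fn = 2)), 0)
  expect_equal(iou(list(tp = 2, fp = 2, fn = 2)), 1 / 3)
  expect_equal(dsc(list(tp = 2, fp = 2, fn = 2)), 0.5)
  expect_equal(dsc(list(tp = 5, fp = 0, fn = 0)), 1)
  # DSC = 2 IoU / (1 + IoU) on random masks, to near machine precision
  set.seed(2)
  for (rep in 1:50) {
    cc <- confusion_counts(random_mask(16, 16), random_mask(16, 16),
                           sample(0:2, 1))
    i <- iou(cc)
    expect_equal(dsc(cc), 2 * i / (1 + i), tolerance = 1e-12)
  }
})

test_that("accuracy counts correct pixels jointly over classes", {
  g <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_equal(accuracy(g, g), 1)
  p <- g; p[1, 1] <- 1; p[2, 2] <- 1
  expect_equal(accuracy(p, g), 0.5)
  b <- matrix(c(0, 1, 0, 1), 2, 2)
  expect_equal(accuracy(1 - b, b), 0)
  expect_error(accuracy(matrix(0, 2, 2), matrix(0, 3, 3)), "mismatch")
})

test_that("surface extraction uses the 4-neighborhood with border outside", {
  m <- matrix(0L, 5, 5)
  m[3, 3] <- 1L
  expect_equal(extract_surface(m, 1), cbind(row = 2L, col = 2L))
  sq <- matrix(0L, 5, 5); sq[2:4, 2:4] <- 1L
  s <- extract_surface(sq, 1)
  expect_equal(nrow(s), 8L)                        # center pixel excluded
  expect_false(any(s[, 1] == 2 & s[, 2] == 2))
  expect_equal(nrow(extract_surface(m, 2)), 0L)    # absent class: empty set
  # a full-image class is all boundary at the image border
  full <- matrix(1L, 3, 3)
  expect_equal(nrow(extract_surface(full, 1)), 8L)
})

test_that("HD95 and ASSD match the all-pairs brute-force oracle", {
  set.seed(3)
  for (rep in 1:30) {
    A <- random_points(sample(2:50, 1))
    B <- random_points(sample(2:50, 1))
    o <- oracle_surface_metrics(A, B)
    expect_equal(hd95(A, B), o$hd95, tolerance = 1e-9)
    expect_equal(assd(A, B), o$assd, tolerance = 1e-9)
    expect_equal(hd95(A, B), hd95(B, A), tolerance = 1e-12)
    expect_equal(assd(A, B), assd(B, A), tolerance = 1e-12)
    expect_equal(hd95(A, A), 0)
    expect_equal(assd(A, A), 0)
  }
})

test_that("unit translation of an open contour gives unit distances", {
  A <- cbind(0:9, rep(0L, 10))
  B <- cbind(0:9, rep(1L, 10))        # shifted by (0, 1)
  expect_equal(hd95(A, B), 1)
  expect_equal(assd(A, B), 1)
  expect_equal(assd(cbind(0L, 0L), cbind(0L, 3L)), 3)
  expect_error(hd95(A, A[0, , drop = FALSE]), "nonempty")
})

test_that("evaluate_masks is exact on a hand-computed pair", {
  gt <- matrix(0L, 4, 4); gt[1:2, 1:2] <- 1L; gt[3:4, 3:4] <- 2L
  r <- evaluate_masks(gt, gt)
  expect_equal(r$accuracy, 1)
  expect_equal(r$mean_iou, 1)
  expect_equal(r$mean_dsc, 1)
  expect_equal(r$mean_hd95, 0)
  expect_equal(r$mean_assd, 0)
  # perturb two pixels and compare against enumerated counts
  pred <- gt; pred[1, 1] <- 0L; pred[3, 3] <- 1L
  r2 <- evaluate_masks(pred, gt)
  ious <- vapply(0:2, function(k) iou(oracle_confusion(pred, gt, k)),
                 numeric(1))
  expect_equal(r2$per_class$iou, ious)
  expect_equal(r2$mean_iou, mean(ious))
  expect_equal(r2$accuracy, 14 / 16)
  expect_equal(r2$mean_dsc, mean(vapply(0:2, function(k)
    dsc(oracle_confusion(pred, gt, k)), numeric(1))))
})

test_that("macro mean equals the mean of reported per-class values", {
  set.seed(4)
  pred <- random_mask(12, 12); gt <- random_mask(12, 12)
  r <- evaluate_masks(pred, gt)
  expect_equal(r$mean_iou, mean(r$per_class$iou, na.rm = TRUE))
  expect_equal(r$mean_dsc, mean(r$per_class$dsc, na.rm = TRUE))
  rf <- evaluate_masks(pred, gt, exclude_background = TRUE)
  expect_equal(rf$mean_iou, mean(r$per_class$iou[2:3], na.rm = TRUE))
})

test_that("empty-class policy skips or penalizes as configured", {
  gt <- matrix(0L, 6, 6); gt[2:3, 2:3] <- 1L      # no nucleus anywhere
  r <- evaluate_masks(gt, gt)
  expect_equal(r$per_class$flag, c("ok", "ok", "absent_both"))
  expect_true(is.na(r$per_class$iou[3]))
  expect_equal(r$mean_iou, 1)                     # skipped from the mean
  pred <- matrix(0L, 6, 6)                        # cytoplasm totally missed
  r2 <- evaluate_masks(pred, gt)
  expect_equal(r2$per_class$flag[2], "absent_one")
  expect_equal(r2$per_class$iou[2], 0)
  expect_equal(r2$per_class$hd95[2], sqrt(72))    # image diagonal
})

test_that("metrics are invariant under simultaneous horizontal flips", {
  set.seed(5)
  pred <- random_mask(10, 10); gt <- random_mask(10, 10)
  r1 <- evaluate_masks(pred, gt)
  r2 <- evaluate_masks(pred[, 10:1], gt[, 10:1])
  expect_equal(r1$mean_iou, r2$mean_iou)
  expect_equal(r1$mean_dsc, r2$mean_dsc)
  expect_equal(r1$mean_hd95, r2$mean_hd95)
  expect_equal(r1$mean_assd, r2$mean_assd)
  expect_equal(r1$accuracy, r2$accuracy)
})
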