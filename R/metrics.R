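# Evaluation statistics for three-class (background/cytoplasm/nucleus)
# segmentation masks: pixel accuracy, IoU, Dice, and the surface-distance
# metrics HD95 and ASSD.
#
# Conventions (documented in the methods vignette):
#   * masks are integer matrices over {0, 1, 2};
#   * boundaries use the 4-neighborhood, with the image border counting as
#     outside;
#   * distances are Euclidean in pixel units on pixel centers;
#   * the 95th percentile uses linear interpolation on the sorted distances;
#   * macro means average over all three classes by default
#     (`exclude_background` drops class 0); a class absent from both masks is
#     skipped from the mean, a class absent from exactly one scores 0
#     overlap and the image diagonal as surface distance, flagged.

check_mask_pair <- function(pred, gt) {
  if (!all(dim(pred) == dim(gt)))
    stop("mask shape mismatch: ", paste(dim(pred), collapse = "x"), " vs ",
         paste(dim(gt), collapse = "x"))
  if (length(pred) == 0L) stop("empty masks")
}

#' One-vs-rest confusion counts for a class
#'
#' @param pred,gt Integer label matrices of equal shape.
#' @param class_id The class treated as positive.
#' @return A list with `tp`, `fp`, `fn`, `tn` pixel counts.
#' @export
confusion_counts <- function(pred, gt, class_id) {
  check_mask_pair(pred, gt)
  p <- pred == class_id
  g <- gt == class_id
  tp <- sum(p & g)
  list(tp = tp, fp = sum(p) - tp, fn = sum(g) - tp,
       tn = sum(!p & !g))
}

#' Intersection over union (Jaccard index) from confusion counts
#'
#' `tp / (tp + fp + fn)`.  When the union is empty the class is absent from
#' both masks and the score is `NA` (skipped from macro means).
#'
#' @param c Counts from [confusion_counts()].
#' @return A score in `[0, 1]`, or `NA` for an empty union.
#' @export
iou <- function(c) {
  u <- c$tp + c$fp + c$fn
  if (u == 0) return(NA_real_)
  c$tp / u
}

#' Dice similarity coefficient from confusion counts
#'
#' `2 tp / (2 tp + fp + fn)`; satisfies `DSC = 2 IoU / (1 + IoU)`.
#'
#' @inheritParams iou
#' @return A score in `[0, 1]`, or `NA` when both masks lack the class.
#' @export
dsc <- function(c) {
  den <- 2 * c$tp + c$fp + c$fn
  if (den == 0) return(NA_real_)
  2 * c$tp / den
}

#' Overall pixel accuracy
#'
#' Proportion of pixels whose predicted label equals the ground truth,
#' jointly over all classes.
#'
#' @param pred,gt Integer label matrices of equal, nonempty shape.
#' @return A score in `[0, 1]`.
#' @export
accuracy <- function(pred, gt) {
  check_mask_pair(pred, gt)
  mean(pred == gt)
}

#' Extract the boundary pixels of a class
#'
#' A class pixel is a surface point when at least one of its 4-neighbors
#' lies outside the class; the image border counts as outside.
#'
#' @param mask Integer label matrix.
#' @param class_id Class whose boundary is extracted.
#' @return A two-column matrix of 0-based `(row, col)` coordinates (possibly
#'   zero rows).
#' @export
extract_surface <- function(mask, class_id) {
  m <- mask == class_id
  H <- nrow(m); W <- ncol(m)
  pad <- function(sh, sv) {
    out <- matrix(FALSE, H, W)
    out[max(1, 1 + sh):min(H, H + sh), max(1, 1 + sv):min(W, W + sv)] <-
      m[max(1, 1 - sh):min(H, H - sh), max(1, 1 - sv):min(W, W - sv)]
    out
  }
  interior <- m & pad(1, 0) & pad(-1, 0) & pad(0, 1) & pad(0, -1)
  idx <- which(m & !interior, arr.ind = TRUE)
  out <- cbind(idx[, 1] - 1L, idx[, 2] - 1L)
  dimnames(out) <- list(NULL, c("row", "col"))
  out
}

# Directed nearest-neighbor distances from each point of A to the set B,
# chunked to bound memory on large boundaries.
directed_nn <- function(A, B, chunk = 2048L) {
  nA <- nrow(A)
  out <- numeric(nA)
  for (s in seq(1L, nA, by = chunk)) {
    e <- min(nA, s + chunk - 1L)
    d2 <- outer(A[s:e, 1], B[, 1], "-")^2 + outer(A[s:e, 2], B[, 2], "-")^2
    out[s:e] <- sqrt(apply(d2, 1, min))
  }
  out
}

#' 95th-percentile Hausdorff distance between two surface point sets
#'
#' The maximum of the two directed 95th-percentile nearest-neighbor
#' Euclidean distances (linear-interpolation percentile), in pixel units.
#'
#' @param A,B Two-column `(row, col)` coordinate matrices; both nonempty.
#' @return A nonnegative distance.
#' @export
hd95 <- function(A, B) {
  if (nrow(A) == 0L || nrow(B) == 0L)
    stop("hd95: both point sets must be nonempty")
  dab <- directed_nn(A, B)
  dba <- directed_nn(B, A)
  max(stats::quantile(dab, 0.95, names = FALSE, type = 7),
      stats::quantile(dba, 0.95, names = FALSE, type = 7))
}

#' Average symmetric surface distance between two surface point sets
#'
#' `(sum_a min_b |a-b| + sum_b min_a |b-a|) / (|A| + |B|)`; symmetric in its
#' arguments by construction.
#'
#' @inheritParams hd95
#' @return A nonnegative distance in pixel units.
#' @export
assd <- function(A, B) {
  if (nrow(A) == 0L || nrow(B) == 0L)
    stop("assd: both point sets must be nonempty")
  (sum(directed_nn(A, B)) + sum(directed_nn(B, A))) / (nrow(A) + nrow(B))
}

#' Evaluate a predicted mask against the ground truth
#'
#' Computes per-class one-vs-rest IoU/Dice/accuracy for classes 0-2,
#' overall pixel accuracy, and HD95/ASSD per foreground class, with
#' unweighted macro means.  Empty-class policy: a class absent from both
#' masks is skipped from the macro mean; a class absent from exactly one
#' scores 0 overlap and the image diagonal as surface distance (flagged).
#'
#' @param pred,gt Integer label matrices over \{0, 1, 2\}.
#' @param exclude_background Drop class 0 from the overlap macro means.
#' @return An object of class `wbc_metrics` with fields `per_class`
#'   (data frame), `accuracy`, `mean_iou`, `mean_dsc`, `mean_hd95`,
#'   `mean_assd`, and `mode`.
#' @export
evaluate_masks <- function(pred, gt, exclude_background = FALSE) {
  check_mask_pair(pred, gt)
  pred <- matrix(as.integer(pred), nrow(pred), ncol(pred))
  gt <- matrix(as.integer(gt), nrow(gt), ncol(gt))
  diag_len <- sqrt(nrow(gt)^2 + ncol(gt)^2)
  classes <- 0:2
  rows <- lapply(classes, function(k) {
    cc <- confusion_counts(pred, gt, k)
    in_pred <- (cc$tp + cc$fp) > 0
    in_gt <- (cc$tp + cc$fn) > 0
    flag <- "ok"
    if (!in_pred && !in_gt) {
      flag <- "absent_both"
      iou_k <- NA_real_; dsc_k <- NA_real_
    } else if (!in_pred || !in_gt) {
      flag <- "absent_one"
      iou_k <- 0; dsc_k <- 0
    } else {
      iou_k <- iou(cc); dsc_k <- dsc(cc)
    }
    acc_k <- (cc$tp + cc$tn) / (cc$tp + cc$tn + cc$fp + cc$fn)
    hd <- asd <- NA_real_
    if (k > 0) {
      if (flag == "ok") {
        A <- extract_surface(gt, k)
        B <- extract_surface(pred, k)
        hd <- hd95(A, B)
        asd <- assd(A, B)
      } else if (flag == "absent_one") {
        hd <- diag_len; asd <- diag_len
      }
    }
    data.frame(class = k, iou = iou_k, dsc = dsc_k, accuracy = acc_k,
               hd95 = hd, assd = asd, flag = flag,
               stringsAsFactors = FALSE)
  })
  per_class <- do.call(rbind, rows)
  keep <- if (exclude_background) per_class$class > 0 else rep(TRUE, 3)
  structure(list(
    per_class = per_class,
    accuracy = accuracy(pred, gt),
    mean_iou = mean(per_class$iou[keep], na.rm = TRUE),
    mean_dsc = mean(per_class$dsc[keep], na.rm = TRUE),
    mean_hd95 = mean(per_class$hd95[per_class$class > 0], na.rm = TRUE),
    mean_assd = mean(per_class$assd[per_class$class > 0], na.rm = TRUE),
    mode = if (exclude_background) "foreground_macro" else "macro"
  ), class = "wbc_metrics")
}

#' @export
print.wbc_metrics <- function(x, ...) {
  cat("Segmentation metrics (", x$mode, " mean)\n", sep = "")
  cat(sprintf("  accuracy %.4f  mean IoU %.4f  mean DSC %.4f\n",
              x$accuracy, x$mean_iou, x$mean_dsc))
  cat(sprintf("  mean HD95 %.4f px  mean ASSD %.4f px\n",
              x$mean_hd95, x$mean_assd))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}
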