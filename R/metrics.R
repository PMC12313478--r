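# Evaluation metrics on hard label maps (plus probability MAE). All operate
# on plain integer arrays; no autodiff involved.

#' Per-class Dice coefficient
#'
#' `2|A n B| / (|A| + |B|)` between predicted and true pixel sets of each
#' class. Classes empty in both maps are reported as `NA` and excluded from
#' any mean.
#'
#' @param pred,truth integer label arrays (H,W,N) or `mask_batch`es.
#' @param classes integer class labels to evaluate (default: all foreground
#'   classes present in either map plus those requested).
#' @return named numeric vector of Dice values in \[0,1\] (or `NA`).
#' @export
dice_metric <- function(pred, truth, classes = NULL) {
  pred <- as_labels(pred); truth <- as_labels(truth)
  if (!all(dim(pred) == dim(truth))) stop("shape mismatch")
  if (is.null(classes)) classes <- sort(setdiff(unique(c(pred, truth)), 0L))
  out <- setNames(numeric(length(classes)), as.character(classes))
  for (i in seq_along(classes)) {
    a <- pred == classes[i]
    b <- truth == classes[i]
    sa <- sum(a); sb <- sum(b)
    out[i] <- if (sa + sb == 0L) NA_real_ else 2 * sum(a & b) / (sa + sb)
  }
  out
}

#' Mean intersection-over-union
#'
#' Mean over classes of `|A n B| / |A u B|`; both-empty classes are
#' excluded.
#'
#' @inheritParams dice_metric
#' @return scalar mIoU in \[0,1\].
#' @export
miou_metric <- function(pred, truth, classes = NULL) {
  pred <- as_labels(pred); truth <- as_labels(truth)
  if (!all(dim(pred) == dim(truth))) stop("shape mismatch")
  if (is.null(classes)) classes <- sort(setdiff(unique(c(pred, truth)), 0L))
  ious <- vapply(classes, function(k) {
    a <- pred == k
    b <- truth == k
    u <- sum(a | b)
    if (u == 0L) NA_real_ else sum(a & b) / u
  }, numeric(1))
  mean(ious, na.rm = TRUE)
}

# Boundary pixels of a binary 2D mask: set pixels with at least one
# 4-neighbour outside the set (grid edges count as outside).
boundary_pixels <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- mask
  inner <- pad[2:(H + 1L), 2:(W + 1L)] &
    pad[1:H, 2:(W + 1L)] & pad[3:(H + 2L), 2:(W + 1L)] &
    pad[2:(H + 1L), 1:W] & pad[2:(H + 1L), 3:(W + 2L)]
  which(mask & !inner, arr.ind = TRUE)
}

#' 95th-percentile Hausdorff distance
#'
#' Pools the directed nearest-neighbour Euclidean distances between the two
#' boundaries (A to B and B to A) and reports their 95th percentile in pixel
#' units (linear-interpolation percentile). Symmetric by construction.
#'
#' @param pred,truth integer label arrays (H,W) or (H,W,1), or
#'   `mask_batch`es with one sample.
#' @param class class label whose boundary is compared.
#' @return scalar distance, or `NA` when either map lacks the class
#'   (undefined rather than silently zero).
#' @export
hd95 <- function(pred, truth, class = 1L) {
  pred <- drop(as_labels(pred)); truth <- drop(as_labels(truth))
  if (!all(dim(pred) == dim(truth))) stop("shape mismatch")
  A <- boundary_pixels(pred == class)
  B <- boundary_pixels(truth == class)
  if (nrow(A) == 0L || nrow(B) == 0L) return(NA_real_)
  d2 <- outer(A[, 1], B[, 1], "-")^2 + outer(A[, 2], B[, 2], "-")^2
  dAB <- sqrt(apply(d2, 1, min))
  dBA <- sqrt(apply(d2, 2, min))
  unname(quantile(c(dAB, dBA), 0.95, type = 7))
}

#' Mean absolute error of the probability map
#'
#' Mean over all pixels and classes of the absolute difference between
#' predicted class probabilities and the one-hot truth.
#'
#' @param probs probabilities (K,H,W,N): array, node or `seg_output`.
#' @param truth integer labels (H,W,N) or `mask_batch`.
#' @return scalar in \[0,1\].
#' @export
mae_metric <- function(probs, truth) {
  p <- val(as_probs(probs))
  oh <- one_hot(truth, dim(p)[1])
  mean(abs(p - oh))
}

#' Full metric report for a prediction batch
#'
#' Per-class Dice (sample-averaged, both-empty samples excluded per class),
#' mean foreground Dice, mIoU, mean HD95 over samples where defined, and
#' probability MAE.
#'
#' @param seg a `seg_output` (or probability array).
#' @param truth integer labels (H,W,N) or `mask_batch`.
#' @param classes foreground class labels.
#' @return a `metric_report` list.
#' @export
metric_report <- function(seg, truth, classes = NULL) {
  probs <- if (inherits(seg, "seg_output")) seg$probs else seg
  pred <- if (inherits(seg, "seg_output")) seg$labels else seg_output(probs)$labels
  truth <- as_labels(truth)
  K <- dim(probs)[1]
  if (is.null(classes)) classes <- seq_len(K - 1L)
  N <- dim(truth)[3]
  per_sample <- lapply(seq_len(N), function(n)
    dice_metric(pred[, , n, drop = FALSE], truth[, , n, drop = FALSE], classes))
  dice_per_class <- setNames(vapply(seq_along(classes), function(i) {
    v <- vapply(per_sample, `[[`, numeric(1), i)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1)), as.character(classes))
  miou_s <- vapply(seq_len(N), function(n)
    miou_metric(pred[, , n, drop = FALSE], truth[, , n, drop = FALSE], classes),
    numeric(1))
  hd_s <- vapply(seq_len(N), function(n) {
    v <- vapply(classes, function(k) hd95(pred[, , n], truth[, , n], k), numeric(1))
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  structure(list(
    dice_per_class = dice_per_class,
    mean_dice = mean(dice_per_class, na.rm = TRUE),
    miou = mean(miou_s, na.rm = TRUE),
    hd95 = if (all(is.na(hd_s))) NA_real_ else mean(hd_s, na.rm = TRUE),
    mae = mae_metric(probs, truth),
    n = N), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("metric report (n = %d)\n", x$n))
  cat("  dice per class:",
      paste(sprintf("%s=%.4f", names(x$dice_per_class), x$dice_per_class),
            collapse = " "), "\n")
  cat(sprintf("  mean dice %.4f | mIoU %.4f | HD95 %s | MAE %.4f\n",
              x$mean_dice, x$miou,
              if (is.na(x$hd95)) "NA" else sprintf("%.3f", x$hd95), x$mae))
  invisible(x)
}
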