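# Detection metrics (greedy score-ordered matching, precision/recall,
# COCO-style interpolated average precision) and the detection-to-counting
# regression analysis.

#' Match detections to ground truth at an IoU threshold
#'
#' Detections are processed in descending score order; each is matched to the
#' highest-IoU not-yet-matched ground-truth box when that IoU reaches the
#' threshold (true positive), otherwise it is a false positive. Every ground
#' truth is matched at most once; unmatched ground truths count as false
#' negatives.
#'
#' @param dets matrix/data.frame with columns `score`, `cx`, `cy`, `w`, `h`.
#' @param gts matrix with columns `cx`, `cy`, `w`, `h` (same units as dets).
#' @param iou_threshold IoU threshold in (0, 1).
#' @return list with `tp` (logical, in descending-score order), `scores`
#'   (sorted), `fn` (count), `n_gt`.
#' @export
match_detections <- function(dets, gts, iou_threshold = 0.5) {
  if (iou_threshold <= 0 || iou_threshold >= 1)
    stop("match_detections: IoU threshold must be in (0, 1)")
  dets <- as.data.frame(dets)
  nd <- nrow(dets); ng <- if (is.null(gts)) 0L else nrow(gts)
  if (nd == 0L) return(list(tp = logical(0), scores = numeric(0), fn = ng, n_gt = ng))
  ord <- order(dets$score, decreasing = TRUE)
  dets <- dets[ord, , drop = FALSE]
  db <- cxcywh_to_xyxy(as.matrix(dets[, c("cx", "cy", "w", "h")]))
  tp <- logical(nd)
  if (ng > 0L) {
    gb <- cxcywh_to_xyxy(as.matrix(gts[, c("cx", "cy", "w", "h"), drop = FALSE]))
    iou <- box_iou(db, gb)
    taken <- logical(ng)
    for (i in seq_len(nd)) {
      cand <- which(!taken & iou[i, ] >= iou_threshold)
      if (length(cand)) {
        j <- cand[which.max(iou[i, cand])]
        taken[j] <- TRUE
        tp[i] <- TRUE
      }
    }
    fn <- sum(!taken)
  } else fn <- 0L
  list(tp = tp, scores = dets$score, fn = fn, n_gt = ng)
}

#' Precision and recall of a match result (percent)
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`; a zero denominator yields 0
#' with a warning.
#'
#' @param m result of [match_detections()].
#' @return named vector `c(P = , R = )` in percent.
#' @export
precision_recall <- function(m) {
  tp <- sum(m$tp); fp <- sum(!m$tp); fn <- m$fn
  if (tp + fp == 0) { warning("no detections: precision undefined, set to 0"); P <- 0 }
  else P <- 100 * tp / (tp + fp)
  if (tp + fn == 0) { warning("no ground truth: recall undefined, set to 0"); R <- 0 }
  else R <- 100 * tp / (tp + fn)
  c(P = P, R = R)
}

#' Average precision from scored match flags
#'
#' Area under the precision-recall curve. `"interp101"` (default) evaluates
#' the interpolated precision `max_{R' >= R} P(R')` at 101 equally spaced
#' recall points (the COCO convention); `"continuous"` integrates the
#' interpolated curve exactly over every recall step.
#'
#' @param scores detection scores.
#' @param flags logical TP flags aligned with `scores`.
#' @param n_gt number of ground-truth boxes (> 0).
#' @param method `"interp101"` or `"continuous"`.
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(scores, flags, n_gt, method = c("interp101", "continuous")) {
  method <- match.arg(method)
  if (n_gt <= 0) stop("average_precision: undefined without ground truth")
  if (length(scores) == 0L) return(0)
  ord <- order(scores, decreasing = TRUE)
  f <- flags[ord]
  tp <- cumsum(f); fp <- cumsum(!f)
  rec <- tp / n_gt
  prec <- tp / (tp + fp)
  # interpolated precision: running max from the right
  ip <- rev(cummax(rev(prec)))
  if (method == "interp101") {
    grid <- seq(0, 1, by = 0.01)
    pr <- vapply(grid, function(r) {
      k <- which(rec >= r - 1e-12)
      if (length(k)) ip[k[1]] else 0
    }, numeric(1))
    mean(pr)
  } else {
    r0 <- c(0, rec)
    sum((rec - r0[-length(r0)]) * ip)
  }
}

#' mAP50 and mAP50:95 over a detection set
#'
#' Per class and IoU threshold, detections are pooled over images, matched
#' greedily per image, and AP computed with 101-point interpolation; mAP
#' averages classes. Classes with no ground truth are excluded with a
#' warning.
#'
#' @param dets list (per image) of data frames with `class`, `score`, `cx`,
#'   `cy`, `w`, `h`.
#' @param gts list (per image) of matrices with columns `class`, `cx`, `cy`,
#'   `w`, `h`.
#' @param method AP integration method, see [average_precision()].
#' @return named vector `c(mAP50 = , mAP50_95 = )` in percent.
#' @export
map_suite <- function(dets, gts, method = "interp101") {
  classes <- sort(unique(unlist(lapply(gts, function(g)
    if (length(g)) g[, 1] else numeric(0)))))
  pred_classes <- unlist(lapply(dets, function(d) d$class))
  skipped <- setdiff(unique(pred_classes), classes)
  if (length(skipped))
    warning("classes with no ground truth excluded: ",
            paste(skipped, collapse = ", "))
  thresholds <- seq(0.5, 0.95, by = 0.05)
  ap <- matrix(0, length(classes), length(thresholds))
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    for (ti in seq_along(thresholds)) {
      flags <- logical(0); scores <- numeric(0); ngt <- 0L
      for (i in seq_along(dets)) {
        d <- dets[[i]]
        d <- d[d$class == cl, , drop = FALSE]
        g <- gts[[i]]
        g <- if (length(g)) g[g[, 1] == cl, -1, drop = FALSE] else NULL
        ngt <- ngt + if (is.null(g)) 0L else nrow(g)
        m <- match_detections(d, g, thresholds[ti])
        flags <- c(flags, m$tp); scores <- c(scores, m$scores)
      }
      ap[ci, ti] <- if (ngt > 0) average_precision(scores, flags, ngt, method) else NA
    }
  }
  ok <- !is.na(ap[, 1])
  c(mAP50 = 100 * mean(ap[ok, 1]),
    mAP50_95 = 100 * mean(rowMeans(ap[ok, , drop = FALSE])))
}

#' Detection-to-counting regression analysis
#'
#' Ordinary least squares of the machine counts on the manual counts,
#' with the coefficient of determination and the count-error summary
#' statistics (MAE and RMSE of machine - manual).
#'
#' @param records data frame with columns `machine` (integer counts from the
#'   detector) and `manual` (reference counts, e.g. a mean of repeated
#'   manual counts).
#' @return list with `slope`, `intercept`, `r2`, `mae`, `rmse`, and the
#'   fitted `lm` object.
#' @export
count_regression <- function(records) {
  records <- as.data.frame(records)
  if (nrow(records) < 3) stop("count_regression: need at least 3 records")
  if (any(records$machine < 0) || any(records$manual < 0))
    stop("count_regression: counts must be nonnegative")
  if (stats::sd(records$manual) == 0)
    stop("count_regression: manual counts have zero variance; R^2 undefined")
  fit <- stats::lm(machine ~ manual, data = records)
  res <- records$machine - stats::predict(fit)
  r2 <- 1 - sum(res^2) / sum((records$machine - mean(records$machine))^2)
  d <- records$machine - records$manual
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = r2, mae = mean(abs(d)), rmse = sqrt(mean(d^2)), fit = fit)
}

#' Scatter plot of machine vs manual counts with the fitted line
#' @param records data frame with `machine` and `manual` columns.
#' @param file optional PNG path; when given the plot is written there.
#' @return the [count_regression()] result, invisibly.
#' @export
plot_count_regression <- function(records, file = NULL) {
  cr <- count_regression(records)
  if (!is.null(file)) {
    grDevices::png(file, width = 720, height = 720, res = 120)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(records$manual, records$machine,
                 xlab = "manual count", ylab = "machine count",
                 pch = 19, col = "#00000088",
                 main = sprintf("R² = %.4f, MAE = %.2f, RMSE = %.2f",
                                cr$r2, cr$mae, cr$rmse))
  graphics::abline(cr$intercept, cr$slope, col = "red3", lwd = 2)
  graphics::abline(0, 1, lty = 3)
  invisible(cr)
}
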