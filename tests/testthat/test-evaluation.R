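box_df <- function(score, cx, cy, w, h)
  data.frame(score = score, cx = cx, cy = cy, w = w, h = h)

test_that("greedy matching follows the single-match rule", {
  gts <- cbind(cx = 10, cy = 10, w = 4, h = 4)
  # perfect overlap: TP at any threshold below 1
  m <- match_detections(box_df(0.9, 10, 10, 4, 4), gts, 0.99)
  expect_equal(sum(m$tp), 1); expect_equal(m$fn, 0)
  # two detections on one ground truth: one TP, one FP
  m2 <- match_detections(box_df(c(0.9, 0.8), c(10, 10), c(10, 10), c(4, 4), c(4, 4)), gts, 0.5)
  expect_equal(m2$tp, c(TRUE, FALSE))
  expect_equal(m2$fn, 0)
  expect_error(match_detections(box_df(1, 1, 1, 1, 1), gts, 1.5), "threshold")
})

test_that("greedy matching agrees with an independent oracle on random sets", {
  # oracle: literal restatement of the rule, coded separately
  greedy_oracle <- function(d, g, thr) {
    ord <- order(d$score, decreasing = TRUE)
    d <- d[ord, ]
    taken <- rep(FALSE, nrow(g))
    tp <- logical(nrow(d))
    for (i in seq_len(nrow(d))) {
      best <- 0; bj <- 0
      for (j in seq_len(nrow(g))) {
        if (taken[j]) next
        ax <- c(d$cx[i] - d$w[i]/2, d$cy[i] - d$h[i]/2, d$cx[i] + d$w[i]/2, d$cy[i] + d$h[i]/2)
        bx <- c(g[j,1] - g[j,3]/2, g[j,2] - g[j,4]/2, g[j,1] + g[j,3]/2, g[j,2] + g[j,4]/2)
        iw <- max(0, min(ax[3], bx[3]) - max(ax[1], bx[1]))
        ih <- max(0, min(ax[4], bx[4]) - max(ax[2], bx[2]))
        inter <- iw * ih
        iou <- inter / (d$w[i]*d$h[i] + g[j,3]*g[j,4] - inter)
        if (iou >= thr && iou > best) { best <- iou; bj <- j }
      }
      if (bj > 0) { taken[bj] <- TRUE; tp[i] <- TRUE }
    }
    list(tp = tp, fn = sum(!taken))
  }
  set.seed(1)
  for (rep in 1:25) {
    nd <- 5
    d <- box_df(runif(nd), runif(nd, 5, 15), runif(nd, 5, 15),
                runif(nd, 2, 6), runif(nd, 2, 6))
    ng <- sample(1:4, 1)
    g <- cbind(cx = runif(ng, 5, 15), cy = runif(ng, 5, 15),
               w = runif(ng, 2, 6), h = runif(ng, 2, 6))
    m <- match_detections(d, g, 0.3)
    o <- greedy_oracle(d, g, 0.3)
    expect_equal(m$tp, o$tp)
    expect_equal(m$fn, o$fn)
  }
})

test_that("precision and recall follow their defining ratios", {
  m <- list(tp = c(rep(TRUE, 8), rep(FALSE, 2)), fn = 2)
  expect_equal(unname(precision_recall(m)), c(80, 80))
  m2 <- list(tp = rep(TRUE, 5), fn = 0)
  expect_equal(unname(precision_recall(m2)), c(100, 100))
  expect_warning(
    expect_warning(pr <- precision_recall(list(tp = logical(0), fn = 0)),
                   "precision undefined"),
    "recall undefined")
  expect_equal(unname(pr), c(0, 0))
  # random match sets against the direct formulas
  set.seed(2)
  for (rep in 1:20) {
    tp <- sample(c(TRUE, FALSE), 10, TRUE); fn <- sample(0:5, 1)
    expect_equal(unname(precision_recall(list(tp = tp, fn = fn))),
                 c(100 * sum(tp) / 10, 100 * sum(tp) / (sum(tp) + fn)))
  }
})

test_that("average precision handles the boundary cases", {
  expect_equal(average_precision(0.9, TRUE, 1), 1)
  expect_equal(average_precision(c(0.9, 0.4), c(FALSE, FALSE), 3), 0)
  expect_error(average_precision(0.9, TRUE, 0), "ground truth")
})

test_that("interpolated AP matches an exact step-integration oracle", {
  # oracle: integrate max_{R' >= R} P(R') exactly over the recall steps
  ap_oracle <- function(scores, flags, n_gt) {
    ord <- order(scores, decreasing = TRUE)
    f <- flags[ord]
    tp <- cumsum(f); fp <- cumsum(!f)
    rec <- tp / n_gt; prec <- tp / (tp + fp)
    area <- 0; last_r <- 0
    for (i in seq_along(rec)) {
      ip <- max(prec[i:length(prec)])
      area <- area + (rec[i] - last_r) * ip
      last_r <- rec[i]
    }
    area
  }
  set.seed(3)
  for (rep in 1:10) {
    scores <- runif(10)
    flags <- sample(c(TRUE, FALSE), 10, TRUE)
    n_gt <- sum(flags) + sample(0:3, 1)
    if (n_gt == 0) next
    expect_equal(average_precision(scores, flags, n_gt, method = "continuous"),
                 ap_oracle(scores, flags, n_gt), tolerance = 1e-12)
    # the 101-point value is within a grid step of the exact area
    expect_lt(abs(average_precision(scores, flags, n_gt) -
                    ap_oracle(scores, flags, n_gt)), 0.05)
  }
})

test_that("AP is invariant to strictly monotone score rescaling", {
  set.seed(4)
  scores <- runif(12); flags <- sample(c(TRUE, FALSE), 12, TRUE)
  a <- average_precision(scores, flags, 6)
  b <- average_precision(scores^3 + 2, flags, 6)
  expect_equal(a, b)
})

test_that("mAP50 dominates mAP50:95 and classes without truth are excluded", {
  set.seed(5)
  dets <- list(data.frame(class = c(0, 0, 1), score = c(0.9, 0.6, 0.8),
                          cx = c(10, 30, 50), cy = c(10, 30, 50),
                          w = c(4, 4, 4), h = c(4, 4, 4)))
  gts <- list(cbind(class = 0, cx = c(10.5, 30), cy = c(10, 30.5),
                    w = c(4, 4), h = c(4, 4)))
  expect_warning(m <- map_suite(dets, gts), "excluded")
  expect_gte(m["mAP50"], m["mAP50_95"])
})

test_that("counting regression matches closed-form least squares", {
  rec <- data.frame(machine = c(12, 25, 33, 48), manual = c(12, 25, 33, 48))
  r <- count_regression(rec)
  expect_equal(r$r2, 1); expect_equal(r$mae, 0); expect_equal(r$rmse, 0)
  # constant bias: MAE = RMSE = bias, perfect linearity
  rec2 <- data.frame(machine = c(14, 27, 35, 50), manual = c(12, 25, 33, 48))
  r2 <- count_regression(rec2)
  expect_equal(r2$mae, 2); expect_equal(r2$rmse, 2)
  expect_equal(r2$r2, 1)
  # 50 random pairs against the normal-equations oracle
  set.seed(6)
  manual <- runif(50, 10, 120)
  machine <- round(3 + 0.95 * manual + rnorm(50, sd = 4))
  machine <- pmax(machine, 0)
  r3 <- count_regression(data.frame(machine = machine, manual = manual))
  X <- cbind(1, manual)
  beta <- solve(t(X) %*% X, t(X) %*% machine)
  expect_equal(r3$intercept, beta[1], tolerance = 1e-10)
  expect_equal(r3$slope, beta[2], tolerance = 1e-10)
  expect_error(count_regression(data.frame(machine = 1:2, manual = 1:2)), "3")
  expect_error(count_regression(data.frame(machine = 1:4, manual = rep(2, 4))),
               "variance")
})

test_that("RMSE is never below MAE, with equality for constant errors", {
  set.seed(7)
  for (rep in 1:20) {
    manual <- runif(10, 10, 50)
    machine <- manual + rnorm(10, sd = runif(1, 0.5, 5))
    r <- count_regression(data.frame(machine = machine, manual = manual))
    expect_gte(r$rmse, r$mae - 1e-12)
  }
})
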