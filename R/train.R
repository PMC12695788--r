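# Training: Hungarian matching, the standard DETR-style set loss
# (classification + L1 + generalized IoU with auxiliary heads), and Adam.
# The loss is the stock real-time DETR recipe; nothing here is modified
# relative to the baseline detector.

#' Solve the linear assignment problem (minimal cost)
#'
#' Hungarian algorithm with row/column potentials; handles rectangular
#' matrices with `nrow <= ncol`.
#'
#' @param cost numeric matrix (nr x nc, nr <= nc).
#' @return integer vector of length `nrow(cost)`: the column assigned to
#'   each row.
#' @export
hungarian <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L) return(integer(0))
  if (n > m) stop("hungarian: more rows than columns")
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1); v <- numeric(m + 1)
  p <- integer(m + 1); way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(INF, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- INF; j1 <- 0L
      for (j in seq_len(m)) if (!used[j + 1]) {
        cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
        if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
        if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
      }
      for (j in 0:m) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else minv[j + 1] <- minv[j + 1] - delta
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    while (j0 != 0L) {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
    }
  }
  ans <- integer(n)
  for (j in seq_len(m)) if (p[j + 1] != 0L) ans[p[j + 1]] <- j
  ans
}

# ---- box utilities (plain, for costs) --------------------------------------

cxcywh_to_xyxy <- function(b) {
  cbind(b[, 1] - b[, 3] / 2, b[, 2] - b[, 4] / 2,
        b[, 1] + b[, 3] / 2, b[, 2] + b[, 4] / 2)
}

#' Pairwise IoU of two box sets
#' @param a,b matrices (na x 4, nb x 4) in xyxy.
#' @return na x nb IoU matrix.
#' @export
box_iou <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  out <- matrix(0, na, nb)
  if (na == 0 || nb == 0) return(out)
  areaa <- pmax(0, a[, 3] - a[, 1]) * pmax(0, a[, 4] - a[, 2])
  areab <- pmax(0, b[, 3] - b[, 1]) * pmax(0, b[, 4] - b[, 2])
  for (j in seq_len(nb)) {
    iw <- pmin(a[, 3], b[j, 3]) - pmax(a[, 1], b[j, 1])
    ih <- pmin(a[, 4], b[j, 4]) - pmax(a[, 2], b[j, 2])
    inter <- pmax(0, iw) * pmax(0, ih)
    out[, j] <- inter / pmax(areaa + areab[j] - inter, 1e-12)
  }
  out
}

box_giou <- function(a, b) {
  iou <- box_iou(a, b)
  out <- iou
  areaa <- pmax(0, a[, 3] - a[, 1]) * pmax(0, a[, 4] - a[, 2])
  areab <- pmax(0, b[, 3] - b[, 1]) * pmax(0, b[, 4] - b[, 2])
  for (j in seq_len(nrow(b))) {
    cw <- pmax(a[, 3], b[j, 3]) - pmin(a[, 1], b[j, 1])
    ch <- pmax(a[, 4], b[j, 4]) - pmin(a[, 2], b[j, 2])
    iw <- pmin(a[, 3], b[j, 3]) - pmax(a[, 1], b[j, 1])
    ih <- pmin(a[, 4], b[j, 4]) - pmax(a[, 2], b[j, 2])
    inter <- pmax(0, iw) * pmax(0, ih)
    uni <- areaa + areab[j] - inter
    hull <- pmax(cw * ch, 1e-12)
    out[, j] <- inter / pmax(uni, 1e-12) - (hull - uni) / hull
  }
  out
}

# Differentiable GIoU loss of matched predictions against constant targets.
ag_giou_loss <- function(pred, gt) {
  # pred: (k x 4) node in cxcywh; gt: constant matrix (k x 4) cxcywh
  k <- nrow(gt)
  px1 <- ag_sub(ag_cols(pred, 1), ag_scale(ag_cols(pred, 3), 0.5))
  py1 <- ag_sub(ag_cols(pred, 2), ag_scale(ag_cols(pred, 4), 0.5))
  px2 <- ag_add(ag_cols(pred, 1), ag_scale(ag_cols(pred, 3), 0.5))
  py2 <- ag_add(ag_cols(pred, 2), ag_scale(ag_cols(pred, 4), 0.5))
  g <- cxcywh_to_xyxy(gt)
  gx1 <- g[, 1, drop = FALSE]; gy1 <- g[, 2, drop = FALSE]
  gx2 <- g[, 3, drop = FALSE]; gy2 <- g[, 4, drop = FALSE]
  iw <- ag_pmax2(ag_sub(ag_pmin2(px2, gx2), ag_pmax2(px1, gx1)), matrix(0, k, 1))
  ih <- ag_pmax2(ag_sub(ag_pmin2(py2, gy2), ag_pmax2(py1, gy1)), matrix(0, k, 1))
  inter <- ag_mul(iw, ih)
  pa <- ag_mul(ag_sub(px2, px1), ag_sub(py2, py1))
  ga <- (gx2 - gx1) * (gy2 - gy1)
  uni <- ag_sub(ag_add(pa, ga), inter)
  cw <- ag_sub(ag_pmax2(px2, gx2), ag_pmin2(px1, gx1))
  ch <- ag_sub(ag_pmax2(py2, gy2), ag_pmin2(py1, gy1))
  hull <- ag_add(ag_mul(cw, ch), 1e-9)
  giou <- ag_sub(ag_div(inter, ag_add(uni, 1e-9)),
                 ag_div(ag_sub(hull, uni), hull))
  ag_mean(ag_sub(1, giou))
}

# ---- DETR set loss ---------------------------------------------------------

#' Hungarian-matched detection loss for one image
#'
#' Standard recipe: a Hungarian assignment under a class + L1 + GIoU cost,
#' then BCE classification over all queries (matched queries positive for
#' their class), and L1 + GIoU box regression on matched queries. Applied to
#' every decoder layer and to the selected encoder outputs (auxiliary heads).
#'
#' @param out forward output of [bd_forward.detector()].
#' @param gt_boxes matrix (n x 4) normalized cxcywh ground-truth boxes.
#' @param gt_class integer vector (0-based class ids).
#' @param w loss weights (class, l1, giou).
#' @param neg_weight BCE weight on unmatched queries.
#' @return scalar loss node.
#' @export
detr_loss <- function(out, gt_boxes, gt_class, w = c(cls = 1, l1 = 5, giou = 2),
                      neg_weight = 1) {
  heads <- c(out$dec, list(out$enc))
  total <- NULL
  ngt <- nrow(gt_boxes)
  for (hd in heads) {
    sc <- hd$scores; bx <- hd$boxes
    scv <- ag_value(sc); bxv <- ag_value(bx)
    nq <- nrow(scv); nc <- ncol(scv)
    tgt <- matrix(0, nq, nc)
    lw <- matrix(neg_weight, nq, nc)
    if (ngt > 0) {
      p <- 1 / (1 + exp(-scv))
      cost_cls <- -p[, gt_class + 1L, drop = FALSE]          # nq x ngt
      l1 <- matrix(0, nq, ngt)
      for (j in seq_len(ngt)) l1[, j] <- rowSums(abs(bxv - matrix(gt_boxes[j, ], nq, 4, byrow = TRUE)))
      gi <- box_giou(cxcywh_to_xyxy(bxv), cxcywh_to_xyxy(gt_boxes))
      cost <- w["cls"] * t(cost_cls) + w["l1"] * t(l1) + w["giou"] * t(-gi)
      assign <- hungarian(cost)                               # query per gt
      tgt[cbind(assign, gt_class + 1L)] <- 1
      lw[assign, ] <- 1
      lcls <- ag_bce_logits(sc, tgt, lw)
      matched <- ag_rows(bx, assign)
      ll1 <- ag_mean(ag_abs(ag_sub(matched, gt_boxes)))
      lgiou <- ag_giou_loss(matched, gt_boxes)
      lh <- ag_add(ag_scale(lcls, w["cls"]),
                   ag_add(ag_scale(ll1, w["l1"]), ag_scale(lgiou, w["giou"])))
    } else {
      lh <- ag_scale(ag_bce_logits(sc, tgt, lw), w["cls"])
    }
    total <- if (is.null(total)) lh else ag_add(total, lh)
  }
  ag_scale(total, 1 / length(heads))
}

# ---- Adam ------------------------------------------------------------------

#' Create an Adam optimizer over bound parameter nodes
#' @param nodes named list of `ag_param` nodes (see `bd_bind`).
#' @param lr learning rate.
#' @param beta1,beta2,eps Adam constants.
#' @param clip global gradient-norm clip.
#' @param warmup steps of linear learning-rate warmup.
#' @return optimizer state environment with a `$step()` method.
#' @export
adam <- function(nodes, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                 clip = 0.5, warmup = 10L) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(nodes, function(p) 0 * ag_value(p))
  st$v <- st$m
  st$t <- 0L
  st$step <- function() {
    st$t <- st$t + 1L
    gsq <- 0
    for (p in nodes) if (!is.null(p$g)) gsq <- gsq + sum(p$g * p$g)
    if (!is.finite(gsq)) { for (p in nodes) p$g <- NULL; return(invisible()) }
    sc <- if (sqrt(gsq) > clip) clip / sqrt(gsq) else 1
    lr_t <- (st$lr %||% lr) * min(1, st$t / max(1, warmup))
    for (i in seq_along(nodes)) {
      p <- nodes[[i]]
      if (is.null(p$g)) next
      g <- p$g * sc
      st$m[[i]] <- beta1 * st$m[[i]] + (1 - beta1) * g
      st$v[[i]] <- beta2 * st$v[[i]] + (1 - beta2) * g * g
      mh <- st$m[[i]] / (1 - beta1^st$t)
      vh <- st$v[[i]] / (1 - beta2^st$t)
      p$v <- p$v - lr_t * mh / (sqrt(vh) + eps)
      p$g <- NULL
    }
    invisible()
  }
  st
}

#' One training step on a batch of annotated images
#'
#' @param bound result of `bd_bind()` on a detector.
#' @param opt optimizer from [adam()].
#' @param batch list of items with `$img` (`c(3,H,W)`) and `$boxes`
#'   (n x 5 matrix: class, cx, cy, w, h normalized).
#' @param step apply the optimizer update (set `FALSE` to only compute).
#' @param train_bn use batch statistics in the normalization layers (update
#'   running stats); `FALSE` keeps the stored statistics (useful for short
#'   overfitting runs, where the frozen affine form is less noisy).
#' @return the batch loss (numeric).
#' @export
train_step <- function(bound, opt, batch, step = TRUE, train_bn = TRUE) {
  if (train_bn) {
    bd_train_mode(TRUE)
    on.exit(bd_train_mode(FALSE))
  }
  loss <- ag_with_tape({
    tot <- NULL
    for (it in batch) {
      out <- bd_forward(bound$module, it$img)
      l <- detr_loss(out, it$boxes[, 2:5, drop = FALSE],
                     as.integer(it$boxes[, 1]))
      tot <- if (is.null(tot)) l else ag_add(tot, l)
    }
    ag_scale(tot, 1 / length(batch))
  })
  ag_backward(loss)
  if (step) opt$step()
  .ag$tape <- NULL; .ag$n <- 0L
  ag_value(loss)
}

#' Re-estimate batch-normalization running statistics
#'
#' Runs forward passes in training mode (no gradients) so the running
#' statistics converge to the current parameters' activation distribution
#' ("precise BN"); standard before evaluating a model trained with small
#' batches.
#'
#' @param model a `bd_module` (e.g. a bound detector module).
#' @param images list of `c(3,H,W)` arrays.
#' @export
bd_refresh_stats <- function(model, images) {
  bd_train_mode(TRUE)
  on.exit(bd_train_mode(FALSE))
  for (im in images) invisible(bd_forward(model, im))
  invisible()
}

#' Overfit a reduced detector on a small synthetic training set
#'
#' Builds a reduced model (2-layer decoder, narrow widths, 96 px input),
#' renders a small synthetic orchard set, and fits it with Adam under the
#' Hungarian-matched set loss, evaluating mAP50 on the training images.
#' Demonstrates end-to-end trainability of the full architecture; stops
#' early once the target training mAP50 is reached.
#'
#' @param n_images training images.
#' @param steps maximum optimizer steps.
#' @param seed RNG seed for scenes, initialization, and batching.
#' @param size image size (divisible by 32).
#' @param batch images per optimizer step.
#' @param lr peak learning rate.
#' @param target early-stop threshold on training mAP50 (percent).
#' @param eval_every evaluation cadence (steps) once past `eval_from`.
#' @param eval_from first step at which mAP is checked.
#' @param verbose print progress.
#' @return list with `map50`, `map50_95`, `steps_used`, `losses`, `model`,
#'   and the training `scenes`.
#' @export
smoke_overfit <- function(n_images = 20L, steps = 200L, seed = 1L, size = 96L,
                          batch = 5L, lr = 1.5e-3, target = 90,
                          eval_every = 25L, eval_from = 75L, verbose = FALSE) {
  set.seed(seed)
  p <- scene_params(size = size, lambda = 3.5, radius_range = c(10, 16),
                    occlusion_fraction = 0.05, clutter = 0.35,
                    illumination_range = c(0.9, 1.1))
  scenes <- generate_dataset(n_images, p, seed = seed * 101L %% 100000L)
  items <- lapply(scenes, function(t) list(img = aperm(t$img, c(3, 1, 2)),
                                           boxes = t$boxes))
  ecfg <- list(stem_width = 8L, stage_widths = c(16L, 32L, 64L, 128L),
               stage_depths = c(1L, 1L, 1L, 1L), n = c(1L, 1L, 1L, 1L),
               hidden_frac = 0.5)
  dcfg <- detector_config(input_size = size, queries = 20L, dec_layers = 2L,
                          hidden = 48L, nhead = 4L, ffn = 96L,
                          anchor_base = 0.15)
  model <- assemble("mde_detr", dcfg, efenet_cfg = ecfg)
  bound <- bd_bind(model)
  opt <- adam(bound$nodes, lr = lr, warmup = 15L)
  eval_map <- function() {
    dets <- list(); gts <- list()
    for (i in seq_along(items)) {
      out <- bd_forward(bound$module, items[[i]]$img)
      sc <- 1 / (1 + exp(-ag_value(out$final$scores)))
      bx <- ag_value(out$final$boxes)
      keep <- which(sc[, 1] >= 0.01)
      dets[[i]] <- data.frame(class = rep(0, length(keep)), score = sc[keep, 1],
                              cx = bx[keep, 1] * size, cy = bx[keep, 2] * size,
                              w = bx[keep, 3] * size, h = bx[keep, 4] * size)
      g <- scenes[[i]]$boxes
      g[, 2:5] <- g[, 2:5] * size
      gts[[i]] <- g
    }
    map_suite(dets, gts)
  }
  losses <- numeric(0)
  res <- c(mAP50 = 0, mAP50_95 = 0)
  used <- steps
  for (s in seq_len(steps)) {
    if (s == 150L) opt$lr <- lr / 3
    idx <- sample(n_images, batch)
    losses[s] <- train_step(bound, opt, items[idx], train_bn = FALSE)
    if (s >= eval_from && (s %% eval_every == 0L || s == steps)) {
      res <- eval_map()
      if (verbose)
        message(sprintf("step %d  loss %.3f  mAP50 %.1f", s, losses[s], res[1]))
      if (res[1] >= target) { used <- s; break }
    }
  }
  if (used == steps && res[1] < target) res <- eval_map()
  list(map50 = unname(res[1]), map50_95 = unname(res[2]), steps_used = used,
       losses = losses, model = bound$module, scenes = scenes)
}
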