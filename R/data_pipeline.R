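# Dataset construction: deterministic splits, offline augmentation,
# YOLO / COCO annotation I/O.

clamp01 <- function(x) { x[x < 0] <- 0; x[x > 1] <- 1; x }
#
# An annotated image is a list:
#   id     character
#   img    (H, W, 3) array in [0, 1] (may be NULL for label-only work)
#   boxes  n x 5 matrix: class, cx, cy, w, h, all normalized to [0, 1]
#   split  optional split tag

#' Create an annotated image record
#' @param id identifier.
#' @param img `(H, W, 3)` array in `[0,1]`, or `NULL`.
#' @param boxes n x 5 matrix `(class, cx, cy, w, h)` normalized.
#' @param split optional split tag.
#' @export
annotated_image <- function(id, img = NULL, boxes = empty_boxes(), split = NA_character_) {
  boxes <- as.matrix(boxes)
  if (ncol(boxes) != 5L) stop("boxes must have 5 columns: class cx cy w h")
  if (nrow(boxes) && (any(boxes[, 2:5] < 0) || any(boxes[, 2:5] > 1)))
    stop("box coordinates must be normalized to [0, 1]")
  if (nrow(boxes) && any(boxes[, 4:5] <= 0))
    stop("degenerate zero-area box")
  structure(list(id = as.character(id), img = img, boxes = boxes, split = split),
            class = "annotated_image")
}

empty_boxes <- function() matrix(numeric(0), 0, 5,
                                 dimnames = list(NULL, c("class", "cx", "cy", "w", "h")))

#' Split items into train/validation/test sets
#'
#' Deterministic shuffle under `seed`, then `floor(n * r1)` training items,
#' `round(n * r2)` validation items, remainder test. This rounding
#' reproduces the 1367/391/196 partition of 1954 items at the standard
#' 7:2:1 ratio.
#'
#' @param items list (or vector) of items.
#' @param ratios length-3 ratios summing to 1.
#' @param seed integer RNG seed.
#' @return list with `train`, `val`, `test`.
#' @export
split_dataset <- function(items, ratios = c(0.7, 0.2, 0.1), seed = 0L) {
  n <- length(items)
  if (n == 0L) stop("split_dataset: empty input")
  if (abs(sum(ratios) - 1) > 1e-9) stop("split_dataset: ratios must sum to 1")
  set.seed(seed)
  ord <- sample.int(n)
  ntr <- floor(n * ratios[1])
  nva <- round(n * ratios[2])
  nte <- n - ntr - nva
  if (nte < 0) stop("split_dataset: degenerate ratios")
  list(train = items[ord[seq_len(ntr)]],
       val = items[ord[ntr + seq_len(nva)]],
       test = items[ord[ntr + nva + seq_len(nte)]])
}

# ---- box-aware geometric transforms ---------------------------------------

flip_h <- function(it) {
  if (!is.null(it$img)) it$img <- it$img[, rev(seq_len(dim(it$img)[2])), , drop = FALSE]
  if (nrow(it$boxes)) it$boxes[, 2] <- 1 - it$boxes[, 2]
  it
}

flip_v <- function(it) {
  if (!is.null(it$img)) it$img <- it$img[rev(seq_len(dim(it$img)[1])), , , drop = FALSE]
  if (nrow(it$boxes)) it$boxes[, 3] <- 1 - it$boxes[, 3]
  it
}

# Affine warp of the image (backward map via bilinear sampling) and the
# axis-aligned hull of transformed box corners. `ang` in degrees about the
# image centre; `tx`, `ty` translation as a fraction of the size.
warp_affine <- function(it, ang = 0, tx = 0, ty = 0, visibility = 0.2) {
  th <- ang * pi / 180
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  if (!is.null(it$img)) {
    d <- dim(it$img) # H W 3
    H <- d[1]; W <- d[2]
    cxp <- (W - 1) / 2; cyp <- (H - 1) / 2
    g <- expand.grid(y = seq_len(H) - 1, x = seq_len(W) - 1)
    # backward map: source = R^T (dst - c - t) + c
    dx <- g$x - cxp - tx * W
    dy <- g$y - cyp - ty * H
    sx <- R[1, 1] * dx + R[2, 1] * dy + cxp
    sy <- R[1, 2] * dx + R[2, 2] * dy + cyp
    chw <- aperm(it$img, c(3, 1, 2))
    s <- .cpp_bilinear_sample(chw, dim(chw), sx, sy)
    out <- array(s, c(3, H, W))
    it$img <- aperm(out, c(2, 3, 1))
  }
  if (nrow(it$boxes)) {
    nb <- it$boxes
    keep <- logical(nrow(nb))
    for (i in seq_len(nrow(nb))) {
      b <- nb[i, ]
      cs <- rbind(c(b[2] - b[4] / 2, b[3] - b[5] / 2), c(b[2] + b[4] / 2, b[3] - b[5] / 2),
                  c(b[2] - b[4] / 2, b[3] + b[5] / 2), c(b[2] + b[4] / 2, b[3] + b[5] / 2))
      cs <- sweep(cs, 2, c(0.5, 0.5))
      cs <- t(R %*% t(cs))
      cs <- sweep(cs, 2, c(0.5 + tx, 0.5 + ty), "+")
      x1 <- max(0, min(cs[, 1])); x2 <- min(1, max(cs[, 1]))
      y1 <- max(0, min(cs[, 2])); y2 <- min(1, max(cs[, 2]))
      area0 <- b[4] * b[5]
      if (x2 > x1 && y2 > y1 && (x2 - x1) * (y2 - y1) >= visibility * area0) {
        nb[i, 2:5] <- c((x1 + x2) / 2, (y1 + y2) / 2, x2 - x1, y2 - y1)
        keep[i] <- TRUE
      }
    }
    it$boxes <- nb[keep, , drop = FALSE]
  }
  it
}

crop_item <- function(it, x1, y1, x2, y2, visibility = 0.2) {
  # crop window in normalized coords, then rescale to full frame
  if (!is.null(it$img)) {
    d <- dim(it$img)
    xi <- pmax(1L, round(x1 * d[2] + 1)):pmin(d[2], round(x2 * d[2]))
    yi <- pmax(1L, round(y1 * d[1] + 1)):pmin(d[1], round(y2 * d[1]))
    crop <- it$img[yi, xi, , drop = FALSE]
    chw <- aperm(crop, c(3, 1, 2))
    it$img <- aperm(resize_chw(chw, d[1], d[2]), c(2, 3, 1))
  }
  if (nrow(it$boxes)) {
    nb <- it$boxes; keep <- logical(nrow(nb))
    sw <- x2 - x1; sh <- y2 - y1
    for (i in seq_len(nrow(nb))) {
      b <- nb[i, ]
      bx1 <- max(x1, b[2] - b[4] / 2); bx2 <- min(x2, b[2] + b[4] / 2)
      by1 <- max(y1, b[3] - b[5] / 2); by2 <- min(y2, b[3] + b[5] / 2)
      if (bx2 > bx1 && by2 > by1 &&
          (bx2 - bx1) * (by2 - by1) >= visibility * b[4] * b[5]) {
        nb[i, 2:5] <- c(((bx1 + bx2) / 2 - x1) / sw, ((by1 + by2) / 2 - y1) / sh,
                        (bx2 - bx1) / sw, (by2 - by1) / sh)
        keep[i] <- TRUE
      }
    }
    it$boxes <- nb[keep, , drop = FALSE]
  }
  it
}

occlude_item <- function(it, frac = 0.12) {
  if (is.null(it$img)) return(it)
  d <- dim(it$img)
  ow <- max(2L, round(d[2] * frac)); oh <- max(2L, round(d[1] * frac))
  ox <- sample.int(d[2] - ow + 1L, 1L); oy <- sample.int(d[1] - oh + 1L, 1L)
  it$img[oy:(oy + oh - 1L), ox:(ox + ow - 1L), ] <- stats::runif(1, 0, 0.3)
  it
}

blur_item <- function(it, k = 3L) {
  if (is.null(it$img)) return(it)
  chw <- aperm(it$img, c(3, 1, 2))
  w <- array(1 / (k * k), c(3, 1, k, k))
  sm <- .cpp_conv2d(chw, dim(chw), w, dim(w), NULL, 1L, 1L, (k - 1L) %/% 2L, (k - 1L) %/% 2L, 3L)
  it$img <- aperm(array(sm, dim(chw)), c(2, 3, 1))
  it
}

#' Offline dataset augmentation
#'
#' Expands a set to `factor` times its size: the originals plus
#' `factor - 1` randomly transformed copies of each image, drawn from the
#' operation menu (rotation, horizontal/vertical flip, translation, Gaussian
#' blur/noise, brightness adjustment, random crop, local occlusion). Boxes
#' transform consistently; boxes clipped below the visibility threshold are
#' dropped.
#'
#' @param items list of `annotated_image`s.
#' @param factor total expansion factor (>= 1); 1367 inputs at factor 4
#'   give 5468 outputs.
#' @param seed integer RNG seed.
#' @param visibility minimum remaining box-area fraction to keep a clipped box.
#' @return list of `factor * length(items)` annotated images.
#' @export
augment_offline <- function(items, factor = 4L, seed = 0L, visibility = 0.2) {
  if (factor < 1L) stop("augment_offline: factor must be >= 1")
  set.seed(seed)
  out <- vector("list", length(items) * factor)
  k <- 0L
  ops <- c("rot", "fliph", "flipv", "shift", "blur", "noise", "bright", "crop", "occl")
  for (it in items) {
    k <- k + 1L; out[[k]] <- it
    if (factor == 1L) next
    for (r in seq_len(factor - 1L)) {
      aug <- it
      aug$id <- paste0(it$id, "_aug", r)
      for (op in sample(ops, sample(1:2, 1))) {
        aug <- switch(op,
          rot = warp_affine(aug, ang = stats::runif(1, -15, 15), visibility = visibility),
          fliph = flip_h(aug),
          flipv = flip_v(aug),
          shift = warp_affine(aug, tx = stats::runif(1, -0.1, 0.1),
                              ty = stats::runif(1, -0.1, 0.1), visibility = visibility),
          blur = blur_item(aug),
          noise = { if (!is.null(aug$img))
            aug$img <- clamp01(aug$img + array(stats::rnorm(length(aug$img), sd = 0.03),
                                               dim(aug$img))); aug },
          bright = { if (!is.null(aug$img))
            aug$img <- clamp01(aug$img * stats::runif(1, 0.6, 1.4)); aug },
          crop = { x1 <- stats::runif(1, 0, 0.2); y1 <- stats::runif(1, 0, 0.2)
                   crop_item(aug, x1, y1, x1 + stats::runif(1, 0.7, 0.8),
                             y1 + stats::runif(1, 0.7, 0.8), visibility) },
          occl = occlude_item(aug))
      }
      k <- k + 1L; out[[k]] <- aug
    }
  }
  out
}

# ---- YOLO / COCO annotation I/O -------------------------------------------

#' Read YOLO-format labels
#'
#' One `class cx cy w h` line per box, normalized coordinates.
#'
#' @param path label file (may be missing/empty: zero boxes).
#' @param id image id (defaults to the file stem).
#' @return an `annotated_image` (without pixels).
#' @export
read_yolo <- function(path, id = sub("\\.txt$", "", basename(path))) {
  if (!file.exists(path) || file.size(path) == 0)
    return(annotated_image(id))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  boxes <- matrix(0, length(lines), 5)
  for (i in seq_along(lines)) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (length(v) != 5 || anyNA(v))
      stop(sprintf("malformed YOLO line in %s, line %d: '%s'", path, i, lines[i]))
    boxes[i, ] <- v
  }
  colnames(boxes) <- c("class", "cx", "cy", "w", "h")
  annotated_image(id, boxes = boxes)
}

#' Write YOLO-format labels
#' @param item an `annotated_image`.
#' @param path output file.
#' @param digits coordinate precision (default 6 decimals).
#' @export
write_yolo <- function(item, path, digits = 6) {
  fmt <- paste0("%d %.", digits, "f %.", digits, "f %.", digits, "f %.", digits, "f")
  lines <- apply(item$boxes, 1, function(b)
    sprintf(fmt, as.integer(b[1]), b[2], b[3], b[4], b[5]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a COCO-format annotation file
#'
#' @param path COCO JSON with `images`, `annotations`, `categories`.
#' @return list of `annotated_image`s (without pixels); boxes converted from
#'   absolute `[x, y, w, h]` to normalized `cx cy w h`.
#' @export
read_coco <- function(path) {
  j <- tryCatch(jsonlite::read_json(path),
                error = function(e) stop("malformed COCO JSON in ", path, ": ",
                                         conditionMessage(e)))
  imgs <- j$images
  anns <- j$annotations
  byimg <- split(anns, vapply(anns, function(a) a$image_id[[1]], numeric(1)))
  lapply(imgs, function(im) {
    W <- im$width[[1]]; H <- im$height[[1]]
    aa <- byimg[[as.character(im$id[[1]])]]
    boxes <- empty_boxes()
    if (!is.null(aa)) {
      boxes <- t(vapply(aa, function(a) {
        b <- unlist(a$bbox)
        c(a$category_id[[1]] - 1, (b[1] + b[3] / 2) / W, (b[2] + b[4] / 2) / H,
          b[3] / W, b[4] / H)
      }, numeric(5)))
      colnames(boxes) <- c("class", "cx", "cy", "w", "h")
    }
    annotated_image(im$file_name[[1]], boxes = boxes)
  })
}

#' Write COCO-format annotations
#'
#' @param items list of `annotated_image`s.
#' @param path output JSON path.
#' @param sizes named list or single `c(H, W)` of pixel sizes per image id.
#' @param categories character vector of category names (ids 1..k).
#' @export
write_coco <- function(items, path, sizes, categories = "object") {
  get_size <- function(id) if (is.list(sizes)) sizes[[id]] else sizes
  images <- list(); annotations <- list(); aid <- 0L
  for (i in seq_along(items)) {
    it <- items[[i]]
    hw <- get_size(it$id)
    images[[i]] <- list(id = i, file_name = it$id, height = hw[1], width = hw[2])
    if (nrow(it$boxes)) for (r in seq_len(nrow(it$boxes))) {
      b <- it$boxes[r, ]
      aid <- aid + 1L
      annotations[[aid]] <- list(
        id = aid, image_id = i, category_id = as.integer(b[1]) + 1L,
        bbox = c((b[2] - b[4] / 2) * hw[2], (b[3] - b[5] / 2) * hw[1],
                 b[4] * hw[2], b[5] * hw[1]),
        area = b[4] * hw[2] * b[5] * hw[1], iscrowd = 0L)
    }
  }
  cats <- lapply(seq_along(categories), function(k)
    list(id = k, name = categories[k]))
  jsonlite::write_json(list(images = images, annotations = annotations,
                            categories = cats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
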