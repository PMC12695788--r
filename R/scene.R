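# Synthetic orchard-scene generator.
#
# Emulates the conditions the detector is aimed at: many small near-circular
# berries (red or green) in dense clusters on a cluttered green-textured
# background, partial occlusion by leaf-shaped blobs, and global illumination
# variation. Every berry whose visible fraction stays above a threshold
# yields a ground-truth box; rendering is deterministic given the seed.

#' Parameters of the synthetic scene generator
#'
#' @param size square image size in pixels.
#' @param lambda mean berry count per image (Poisson, floored at 1).
#' @param radius_range berry radius range in pixels (>= 2).
#' @param occlusion_fraction fraction of berries overlaid by a leaf occluder,
#'   in `[0, 1)`.
#' @param illumination_range global gain range.
#' @param clutter background texture amplitude in `[0, 1]`.
#' @param red_fraction fraction of ripe (red) berries; the rest are green.
#' @param visibility minimum visible fraction for a berry to be labelled.
#' @param cluster_size mean berries per cluster (controls density).
#' @return a parameter list for [generate_scene()].
#' @export
scene_params <- function(size = 640L, lambda = 40, radius_range = c(6, 14),
                         occlusion_fraction = 0.3,
                         illumination_range = c(0.7, 1.3), clutter = 0.5,
                         red_fraction = 0.7, visibility = 0.25,
                         cluster_size = 5) {
  if (radius_range[1] < 2) stop("scene_params: radius must be >= 2 px")
  if (occlusion_fraction < 0 || occlusion_fraction >= 1)
    stop("scene_params: occlusion fraction must be in [0, 1)")
  list(size = as.integer(size), lambda = lambda, radius_range = radius_range,
       occlusion_fraction = occlusion_fraction,
       illumination_range = illumination_range, clutter = clutter,
       red_fraction = red_fraction, visibility = visibility,
       cluster_size = cluster_size)
}

# Low-frequency value-noise field in [-1, 1], size x size.
noise_field <- function(size, cell = 16L) {
  g <- ceiling(size / cell) + 1L
  coarse <- matrix(stats::runif(g * g, -1, 1), g, g)
  chw <- array(coarse, c(1, g, g))
  fine <- resize_chw(chw, size, size)
  array(fine, c(size, size))
}

draw_disc <- function(img, own, id, cx, cy, r, col, shade = TRUE) {
  size <- dim(img)[1]
  x0 <- max(1L, floor(cx - r)); x1 <- min(size, ceiling(cx + r))
  y0 <- max(1L, floor(cy - r)); y1 <- min(size, ceiling(cy + r))
  if (x0 > x1 || y0 > y1) return(list(img = img, own = own))
  xs <- x0:x1; ys <- y0:y1
  dx <- outer(rep(1, length(ys)), xs - 1 - cx)
  dy <- outer(ys - 1 - cy, rep(1, length(xs)))
  d <- sqrt(dx * dx + dy * dy)
  alpha <- pmin(1, pmax(0, r + 0.5 - d))
  if (all(alpha == 0)) return(list(img = img, own = own))
  sh <- if (shade) 0.65 + 0.45 * pmax(0, 1 - ((dx + 0.35 * r)^2 + (dy + 0.35 * r)^2) / (1.7 * r)^2) else 1
  for (ch in 1:3) {
    patch <- img[ys, xs, ch]
    img[ys, xs, ch] <- patch * (1 - alpha) + col[ch] * sh * alpha
  }
  own[ys, xs][alpha > 0.5] <- id
  list(img = img, own = own)
}

draw_leaf <- function(img, own, cx, cy, a, b, ang, col) {
  size <- dim(img)[1]
  ext <- max(a, b)
  x0 <- max(1L, floor(cx - ext)); x1 <- min(size, ceiling(cx + ext))
  y0 <- max(1L, floor(cy - ext)); y1 <- min(size, ceiling(cy + ext))
  if (x0 > x1 || y0 > y1) return(list(img = img, own = own))
  xs <- x0:x1; ys <- y0:y1
  dx <- outer(rep(1, length(ys)), xs - 1 - cx)
  dy <- outer(ys - 1 - cy, rep(1, length(xs)))
  u <- cos(ang) * dx + sin(ang) * dy
  v <- -sin(ang) * dx + cos(ang) * dy
  d <- sqrt((u / a)^2 + (v / b)^2)
  alpha <- pmin(1, pmax(0, (1 - d) * max(a, b) + 0.5))
  alpha <- pmin(1, pmax(0, alpha))
  if (all(alpha == 0)) return(list(img = img, own = own))
  sh <- 0.8 + 0.4 * pmax(0, 1 - d)
  for (ch in 1:3) {
    patch <- img[ys, xs, ch]
    img[ys, xs, ch] <- patch * (1 - alpha) + col[ch] * sh * alpha
  }
  own[ys, xs][alpha > 0.5] <- 0L
  list(img = img, own = own)
}

#' Render a synthetic orchard scene with ground-truth boxes
#'
#' @param p parameters from [scene_params()].
#' @param seed integer seed; identical seeds give bit-identical scenes.
#' @param id image identifier.
#' @return an `annotated_image` with pixels and normalized boxes (class 0).
#' @export
generate_scene <- function(p = scene_params(), seed = 0L, id = sprintf("scene%06d", seed)) {
  set.seed(seed)
  size <- p$size
  # background: dark green base + two octaves of value noise + dim foliage
  img <- array(0, c(size, size, 3))
  base <- c(0.16, 0.30, 0.10)
  n1 <- noise_field(size, max(8L, size %/% 8L))
  n2 <- noise_field(size, max(4L, size %/% 32L))
  tex <- 0.5 * n1 + 0.25 * n2
  for (ch in 1:3) img[, , ch] <- clamp01(base[ch] * (1 + p$clutter * tex))
  own <- matrix(0L, size, size)
  nleaf_bg <- max(2L, round(p$clutter * 12))
  for (i in seq_len(nleaf_bg)) {
    lp <- draw_leaf(img, own, stats::runif(1, 0, size), stats::runif(1, 0, size),
                    stats::runif(1, 0.05, 0.12) * size, stats::runif(1, 0.02, 0.05) * size,
                    stats::runif(1, 0, pi),
                    c(0.10, 0.22, 0.07) * stats::runif(1, 0.7, 1.3))
    img <- lp$img; own <- lp$own
  }
  # berries in clusters
  n <- max(1L, stats::rpois(1, p$lambda))
  nclust <- max(1L, round(n / p$cluster_size))
  ccx <- stats::runif(nclust, 0.1, 0.9) * size
  ccy <- stats::runif(nclust, 0.1, 0.9) * size
  berries <- data.frame(cx = numeric(n), cy = numeric(n), r = numeric(n),
                        red = logical(n))
  for (i in seq_len(n)) {
    k <- sample.int(nclust, 1L)
    r <- stats::runif(1, p$radius_range[1], p$radius_range[2])
    berries$cx[i] <- min(size - 1 - r, max(r, stats::rnorm(1, ccx[k], 2.2 * p$radius_range[2])))
    berries$cy[i] <- min(size - 1 - r, max(r, stats::rnorm(1, ccy[k], 2.2 * p$radius_range[2])))
    berries$r[i] <- r
    berries$red[i] <- stats::runif(1) < p$red_fraction
  }
  base_px <- integer(n)
  for (i in seq_len(n)) {
    col <- if (berries$red[i])
      c(stats::runif(1, 0.55, 0.8), stats::runif(1, 0.05, 0.15), stats::runif(1, 0.10, 0.22))
    else
      c(stats::runif(1, 0.45, 0.6), stats::runif(1, 0.55, 0.7), stats::runif(1, 0.15, 0.3))
    dd <- draw_disc(img, own, i, berries$cx[i], berries$cy[i], berries$r[i], col)
    img <- dd$img; own <- dd$own
  }
  for (i in seq_len(n)) base_px[i] <- sum(own == i)
  # leaf occluders over a fraction of berries
  nocc <- round(p$occlusion_fraction * n)
  if (nocc > 0) for (i in sample.int(n, nocc)) {
    lp <- draw_leaf(img, own,
                    berries$cx[i] + stats::rnorm(1, 0, berries$r[i]),
                    berries$cy[i] + stats::rnorm(1, 0, berries$r[i]),
                    stats::runif(1, 0.8, 2.0) * berries$r[i],
                    stats::runif(1, 0.4, 0.9) * berries$r[i],
                    stats::runif(1, 0, pi),
                    c(0.13, 0.28, 0.09) * stats::runif(1, 0.8, 1.2))
    img <- lp$img; own <- lp$own
  }
  gain <- stats::runif(1, p$illumination_range[1], p$illumination_range[2])
  img <- clamp01(img * gain)
  # labels: berries still sufficiently visible
  boxes <- empty_boxes()
  for (i in seq_len(n)) {
    if (base_px[i] == 0) next
    vis <- sum(own == i) / base_px[i]
    if (vis < p$visibility) next
    r <- berries$r[i]
    x1 <- max(0, berries$cx[i] - r) / size; x2 <- min(size, berries$cx[i] + r + 1) / size
    y1 <- max(0, berries$cy[i] - r) / size; y2 <- min(size, berries$cy[i] + r + 1) / size
    boxes <- rbind(boxes, c(0, (x1 + x2) / 2, (y1 + y2) / 2, x2 - x1, y2 - y1))
  }
  colnames(boxes) <- c("class", "cx", "cy", "w", "h")
  annotated_image(id, img = img, boxes = boxes)
}

#' Generate a synthetic dataset
#' @param n number of scenes.
#' @param p scene parameters.
#' @param seed base seed; scene i uses `seed + i`.
#' @return list of `annotated_image`s.
#' @export
generate_dataset <- function(n, p = scene_params(), seed = 0L) {
  lapply(seq_len(n), function(i)
    generate_scene(p, seed = seed + i, id = sprintf("scene%06d", seed + i)))
}
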