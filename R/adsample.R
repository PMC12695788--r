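# ADSample: adaptive deformable downsampling.
#
# A 3x3 convolution (stride = the downsampling stride) predicts 2N spatial
# offsets per output location. Sampling coordinates are the regular
# stride-spaced base grid P0, plus a fixed n x n pattern template Pn covering
# the stride window, plus the learned offsets. Features are gathered by
# bilinear interpolation (zero outside the grid), the N samples per output
# cell are stacked along the height axis, and an (N, 1) column convolution
# with stride (N, 1) aggregates them, followed by SiLU.
#
# Coordinates are 0-based with x = column, y = row; no [-1, 1] normalization.
# The offset convolution is zero-initialized so training starts from regular
# patterned sampling, where the module reduces exactly to a patterned strided
# convolution.

#' Fixed sampling-pattern template
#'
#' Lays out `N = n^2` points on an n x n grid spanning the stride window:
#' per-axis offsets `(0:(n-1)) * stride / n`. Returned as a length-2N vector
#' interleaved (x1, y1, x2, y2, ...), points in row-major order.
#'
#' @param N number of sampling points (a perfect square).
#' @param stride downsampling stride.
#' @return numeric vector of length `2N`.
#' @export
adsample_pattern <- function(N, stride) {
  n <- as.integer(round(sqrt(N)))
  if (n * n != N) stop("adsample: N must be a perfect square")
  ax <- (seq_len(n) - 1) * stride / n
  g <- expand.grid(x = ax, y = ax) # row-major over x first
  as.numeric(t(as.matrix(g[, c("x", "y")])))
}

#' Regular base sampling grid at the output stride
#'
#' @param Hp,Wp output spatial dims.
#' @param stride downsampling stride.
#' @param N sampling points per location.
#' @return array `c(2N, Hp, Wp)`; channel `2k-1` holds x (column) and
#'   channel `2k` holds y (row) of point `k`, all equal to the cell origin.
#' @export
adsample_base_grid <- function(Hp, Wp, stride, N) {
  xs <- (seq_len(Wp) - 1) * stride
  ys <- (seq_len(Hp) - 1) * stride
  g <- array(0, c(2L * N, Hp, Wp))
  for (k in seq_len(N)) {
    g[2L * k - 1L, , ] <- matrix(xs, Hp, Wp, byrow = TRUE)
    g[2L * k, , ] <- matrix(ys, Hp, Wp)
  }
  g
}

#' Adaptive sampling coordinates: base grid + pattern + offsets
#'
#' @param P0 base grid `c(2N, Hp, Wp)` (see [adsample_base_grid()]).
#' @param Pn pattern template, length `2N` (see [adsample_pattern()]).
#' @param delta predicted offsets `c(2N, Hp, Wp)`.
#' @return coordinates `c(2N, Hp, Wp)`, continuous and unclamped.
#' @export
build_coords <- function(P0, Pn, delta) {
  d <- dim(ag_value(delta))
  ag_add(delta, P0 + array(Pn, d))
}

#' Bilinear interpolation stencil at a continuous point
#'
#' Returns the four integer neighbours and their weights,
#' `w = max(0, 1 - |px - floor(px)|) * max(0, 1 - |py - floor(py)|)` and
#' companions; weights sum to 1 for in-bounds points.
#'
#' @param px,py coordinates (0-based, x = column).
#' @return list with `q` (4 x 2 matrix of x, y integer neighbours, order
#'   lt, rb, lb, rt) and `w` (length-4 weights).
#' @export
bilinear_weights <- function(px, py) {
  x0 <- floor(px); y0 <- floor(py)
  fx <- px - x0; fy <- py - y0
  q <- rbind(lt = c(x0, y0), rb = c(x0 + 1, y0 + 1),
             lb = c(x0, y0 + 1), rt = c(x0 + 1, y0))
  w <- c(lt = max(0, 1 - abs(fx)) * max(0, 1 - abs(fy)),
         rb = max(0, 1 - abs(1 - fx)) * max(0, 1 - abs(1 - fy)),
         lb = max(0, 1 - abs(fx)) * max(0, 1 - abs(1 - fy)),
         rt = max(0, 1 - abs(1 - fx)) * max(0, 1 - abs(fy)))
  colnames(q) <- c("x", "y")
  list(q = q, w = w)
}

#' Create an ADSample module
#'
#' @param cin,cout channel counts.
#' @param stride downsampling stride.
#' @param N sampling points per output location (perfect square).
#' @return a `bd_module` of kind `adsample`.
#' @export
mk_adsample <- function(cin, cout, stride = 2L, N = 4L) {
  pn <- adsample_pattern(N, stride)
  params <- list(
    w_off = array(0, c(2L * N, cin, 3L, 3L)), # zero init: regular sampling
    b_off = numeric(2L * N),
    w_col = init_kernel(cout, cin, N, 1L),
    b_col = numeric(cout))
  new_module("adsample", params, buffers = list(pattern = pn),
             cfg = list(cin = cin, cout = cout, stride = as.integer(stride), N = as.integer(N)))
}

# Stack per-point samples along height: list of N (C, Hp*Wp) matrices to a
# (C, Hp*N, Wp) map with row block k of cell i holding point k.
ag_stack_points <- function(fs, Hp, Wp) {
  N <- length(fs)
  C <- nrow(ag_value(fs[[1]]))
  v <- array(0, c(C, Hp * N, Wp))
  for (k in seq_len(N))
    v[, seq(k, Hp * N, by = N), ] <- array(ag_value(fs[[k]]), c(C, Hp, Wp))
  ag_make(v, fs, function(g) {
    lapply(seq_len(N), function(k) {
      gk <- g[, seq(k, Hp * N, by = N), , drop = FALSE]
      dim(gk) <- c(C, Hp * Wp)
      gk
    })
  })
}

#' @export
bd_forward.adsample <- function(m, x, ...) {
  cfg <- m$cfg
  d <- dim(ag_value(x))
  if (d[1] != cfg$cin)
    stop(sprintf("adsample: input has %d channels, expected %d", d[1], cfg$cin))
  if (d[2] %% cfg$stride != 0L || d[3] %% cfg$stride != 0L)
    stop("adsample: stride must divide input dims")
  Hp <- d[2] %/% cfg$stride; Wp <- d[3] %/% cfg$stride
  delta <- ag_conv2d(x, m$params$w_off, m$params$b_off,
                     stride = cfg$stride, pad = 1)
  P0 <- adsample_base_grid(Hp, Wp, cfg$stride, cfg$N)
  P <- build_coords(P0, m$buffers$pattern, delta)
  fs <- vector("list", cfg$N)
  for (k in seq_len(cfg$N)) {
    px <- ag_slice_c(P, 2L * k - 1L)
    py <- ag_slice_c(P, 2L * k)
    fs[[k]] <- ag_bilinear(x, ag_reshape(px, Hp * Wp), ag_reshape(py, Hp * Wp))
  }
  stacked <- ag_stack_points(fs, Hp, Wp)
  y <- ag_conv2d(stacked, m$params$w_col, m$params$b_col,
                 stride = c(cfg$N, 1L), pad = 0)
  ag_silu(y)
}
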