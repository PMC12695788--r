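# Differentiable wrappers over the compiled feature-map kernels.
#
# All feature maps are (C, H, W) arrays; kernels are (Cout, Cin/groups, kh, kw).

#' 2-D convolution on a (C, H, W) feature map
#'
#' @param x input map, array `c(C, H, W)` (or `ag_node`).
#' @param w kernel, array `c(Cout, Cin/groups, kh, kw)`.
#' @param b optional bias vector of length `Cout`.
#' @param stride,pad integer scalars or length-2 vectors (height, width).
#' @param groups channel groups; `groups = C` gives a depthwise convolution.
#' @return output map `c(Cout, H', W')`.
#' @export
ag_conv2d <- function(x, w, b = NULL, stride = 1, pad = 0, groups = 1) {
  xv <- ag_value(x); wv <- ag_value(w); bv <- if (is.null(b)) NULL else ag_value(b)
  s <- rep(as.integer(stride), length.out = 2)
  p <- rep(as.integer(pad), length.out = 2)
  xd <- dim(xv); wd <- dim(wv)
  if (xd[1] != wd[2] * groups)
    stop(sprintf("conv2d: input has %d channels but kernel expects %d x %d groups",
                 xd[1], wd[2], groups))
  v <- .cpp_conv2d(xv, xd, wv, wd, bv, s[1], s[2], p[1], p[2], as.integer(groups))
  if (.bd_meter$on) {
    hw <- prod(dim(v)[2:3])
    meter_add("conv_macs", prod(wd) / wd[1] * dim(v)[1] * hw)
    if (!is.null(bv)) meter_add("elementwise", dim(v)[1] * hw)
  }
  ag_make(v, list(x, w, b), function(g) {
    need_dx <- ag_is(x); need_dw <- ag_is(w); need_db <- !is.null(b) && ag_is(b)
    r <- .cpp_conv2d_backward(xv, xd, wv, wd, g, s[1], s[2], p[1], p[2],
                              as.integer(groups), need_dx, need_dw, need_db)
    list(if (need_dx) r$dx else NULL,
         if (need_dw) r$dw else NULL,
         if (need_db) r$db else NULL)
  })
}

#' Max pooling on a (C, H, W) map
#' @inheritParams ag_conv2d
#' @param k pooling window size.
#' @export
ag_maxpool <- function(x, k, stride, pad = 0) {
  xv <- ag_value(x); xd <- dim(xv)
  r <- .cpp_maxpool(xv, xd, as.integer(k), as.integer(stride), as.integer(pad))
  meter_add("resample", as.numeric(k)^2 * length(r$y))
  ag_make(r$y, list(x), function(g) list(.cpp_maxpool_backward(g, r$arg, xd)))
}

#' Bilinear sampling at continuous coordinates
#'
#' Samples a (C, H, W) map at M continuous positions with zero padding outside
#' the grid; differentiable in both the map and the coordinates.
#'
#' @param x feature map `c(C, H, W)`.
#' @param px,py coordinate vectors (0-based; `px` = column, `py` = row).
#' @return a `c(C, M)` matrix of sampled features.
#' @export
ag_bilinear <- function(x, px, py) {
  xv <- ag_value(x); pxv <- ag_value(px); pyv <- ag_value(py)
  if (anyNA(pxv) || anyNA(pyv) || any(!is.finite(pxv)) || any(!is.finite(pyv)))
    stop("bilinear sampling: non-finite coordinates")
  xd <- dim(xv)
  v <- .cpp_bilinear_sample(xv, xd, as.numeric(pxv), as.numeric(pyv))
  meter_add("resample", 4 * length(v))
  ag_make(v, list(x, px, py), function(g) {
    need_dx <- ag_is(x); need_dp <- ag_is(px) || ag_is(py)
    r <- .cpp_bilinear_sample_backward(xv, xd, as.numeric(pxv), as.numeric(pyv),
                                       g, need_dx, need_dp)
    list(if (need_dx) r$dx else NULL,
         if (need_dp) array(r$dpx, dim(pxv) %||% length(pxv)) else NULL,
         if (need_dp) array(r$dpy, dim(pyv) %||% length(pyv)) else NULL)
  })
}

#' Space-to-depth rearrangement (2x2)
#'
#' Losslessly moves each 2x2 spatial neighbourhood into four channel groups,
#' halving the resolution. Sub-maps are concatenated in the order
#' (0,0), (1,0), (0,1), (1,1) over (row offset, column offset).
#'
#' @param x map `c(C, H, W)` with even `H`, `W`.
#' @return map `c(4C, H/2, W/2)`.
#' @export
ag_space_to_depth <- function(x) {
  xv <- ag_value(x); d <- dim(xv)
  C <- d[1]; H <- d[2]; W <- d[3]
  if (H %% 2L != 0L || W %% 2L != 0L)
    stop(sprintf("space_to_depth: spatial dims (%d x %d) must be even", H, W))
  idx <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L)) # (row, col) offsets
  v <- array(0, c(4L * C, H %/% 2L, W %/% 2L))
  for (i in seq_along(idx)) {
    off <- idx[[i]]
    v[(i - 1L) * C + seq_len(C), , ] <-
      xv[, seq(1L + off[1], H, by = 2L), seq(1L + off[2], W, by = 2L), drop = FALSE]
  }
  ag_make(v, list(x), function(g) {
    dx <- array(0, d)
    for (i in seq_along(idx)) {
      off <- idx[[i]]
      dx[, seq(1L + off[1], H, by = 2L), seq(1L + off[2], W, by = 2L)] <-
        g[(i - 1L) * C + seq_len(C), , , drop = FALSE]
    }
    list(dx)
  })
}

#' Inverse of [ag_space_to_depth()]
#' @param x map `c(4C, H, W)`.
#' @return map `c(C, 2H, 2W)`.
#' @export
ag_depth_to_space <- function(x) {
  xv <- ag_value(x); d <- dim(xv)
  C4 <- d[1]; H <- d[2]; W <- d[3]
  stopifnot(C4 %% 4L == 0L)
  C <- C4 %/% 4L
  idx <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  v <- array(0, c(C, 2L * H, 2L * W))
  for (i in seq_along(idx)) {
    off <- idx[[i]]
    v[, seq(1L + off[1], 2L * H, by = 2L), seq(1L + off[2], 2L * W, by = 2L)] <-
      xv[(i - 1L) * C + seq_len(C), , , drop = FALSE]
  }
  ag_make(v, list(x), function(g) {
    dx <- array(0, d)
    for (i in seq_along(idx)) {
      off <- idx[[i]]
      dx[(i - 1L) * C + seq_len(C), , ] <-
        g[, seq(1L + off[1], 2L * H, by = 2L), seq(1L + off[2], 2L * W, by = 2L), drop = FALSE]
    }
    list(dx)
  })
}

#' Nearest-neighbour 2x upsampling
#' @param x map `c(C, H, W)`.
#' @export
ag_upsample2 <- function(x) {
  xv <- ag_value(x); d <- dim(xv)
  hi <- rep(seq_len(d[2]), each = 2L); wi <- rep(seq_len(d[3]), each = 2L)
  v <- xv[, hi, wi, drop = FALSE]
  ag_make(v, list(x), function(g) {
    dx <- g[, seq(1L, 2L * d[2], by = 2L), seq(1L, 2L * d[3], by = 2L), drop = FALSE] +
      g[, seq(2L, 2L * d[2], by = 2L), seq(1L, 2L * d[3], by = 2L), drop = FALSE] +
      g[, seq(1L, 2L * d[2], by = 2L), seq(2L, 2L * d[3], by = 2L), drop = FALSE] +
      g[, seq(2L, 2L * d[2], by = 2L), seq(2L, 2L * d[3], by = 2L), drop = FALSE]
    list(dx)
  })
}
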