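# Reverse-mode automatic differentiation over dense R arrays.
#
# A minimal tape: every differentiable op appends a node holding its value,
# its parent nodes and a backward closure. Plain arrays flow through the same
# ops untouched, so inference runs with zero bookkeeping; gradients are only
# tracked while a tape is active AND at least one input is a node.
#
# Values are either 3-d feature maps dim c(C, H, W), matrices (tokens x dim),
# vectors, or scalars. Gradients always match the value's shape.

.ag <- new.env(parent = emptyenv())
.ag$on <- FALSE
.ag$tape <- NULL
.ag$n <- 0L

#' Run an expression with gradient recording enabled
#'
#' Activates a fresh tape, evaluates `expr`, and leaves the tape in place so
#' [ag_backward()] can run on the result. Parameters participating in the
#' computation must be wrapped with [ag_param()].
#'
#' @param expr expression to evaluate under the tape.
#' @return the value of `expr`.
#' @keywords internal
#' @export
ag_with_tape <- function(expr) {
  .ag$on <- TRUE
  .ag$tape <- vector("list", 1024L)
  .ag$n <- 0L
  on.exit(.ag$on <- FALSE)
  expr
}

ag_is <- function(x) inherits(x, "ag_node")

#' @keywords internal
#' @export
ag_value <- function(x) if (ag_is(x)) x$v else x

#' Wrap an array as a trainable tape parameter
#' @param v numeric array/matrix/vector.
#' @keywords internal
#' @export
ag_param <- function(v) {
  n <- new.env(parent = emptyenv())
  n$v <- v; n$g <- NULL; n$bw <- NULL; n$prev <- list()
  class(n) <- "ag_node"
  n
}

# Create an interior node (records on tape). `bw` receives the upstream
# gradient and returns a list of gradients aligned with `parents`.
ag_make <- function(v, parents, bw) {
  if (!.ag$on || !any(vapply(parents, ag_is, logical(1)))) return(v)
  n <- new.env(parent = emptyenv())
  n$v <- v; n$g <- NULL; n$bw <- bw; n$prev <- parents
  class(n) <- "ag_node"
  k <- .ag$n + 1L
  if (k > length(.ag$tape)) .ag$tape <- c(.ag$tape, vector("list", length(.ag$tape)))
  .ag$tape[[k]] <- n
  .ag$n <- k
  n
}

ag_accum <- function(node, g) {
  if (!ag_is(node) || is.null(g)) return(invisible())
  node$g <- if (is.null(node$g)) g else node$g + g
  invisible()
}

#' Backpropagate from a scalar loss node
#'
#' Seeds the loss gradient with 1 and sweeps the tape in reverse; afterwards
#' every [ag_param()] that influenced the loss carries its gradient in `$g`.
#'
#' @param loss an `ag_node` holding a scalar.
#' @keywords internal
#' @export
ag_backward <- function(loss) {
  stopifnot(ag_is(loss), length(loss$v) == 1L)
  loss$g <- 1
  if (.ag$n > 0L) for (k in .ag$n:1L) {
    n <- .ag$tape[[k]]
    if (is.null(n$g) || is.null(n$bw)) next
    gs <- n$bw(n$g)
    for (i in seq_along(n$prev)) ag_accum(n$prev[[i]], gs[[i]])
  }
  invisible()
}

#' @keywords internal
#' @export
ag_zero_grads <- function(params) {
  for (p in params) p$g <- NULL
  invisible()
}

# ---- elementwise arithmetic ------------------------------------------------

#' @keywords internal
#' @export
ag_add <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  ag_make(av + bv, list(a, b), function(g) list(g, g))
}

#' @keywords internal
#' @export
ag_sub <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  ag_make(av - bv, list(a, b), function(g) list(g, -g))
}

#' @keywords internal
#' @export
ag_mul <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  ag_make(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

#' @keywords internal
#' @export
ag_div <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  ag_make(av / bv, list(a, b), function(g) list(g / bv, -g * av / (bv * bv)))
}

#' @keywords internal
#' @export
ag_scale <- function(a, s) {
  av <- ag_value(a)
  ag_make(av * s, list(a), function(g) list(g * s))
}

#' @keywords internal
#' @export
ag_pmax2 <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  sel <- av >= bv
  ag_make(pmax(av, bv), list(a, b),
          function(g) list(g * sel, g * (!sel)))
}

#' @keywords internal
#' @export
ag_pmin2 <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  sel <- av <= bv
  ag_make(pmin(av, bv), list(a, b),
          function(g) list(g * sel, g * (!sel)))
}

#' @keywords internal
#' @export
ag_abs <- function(a) {
  av <- ag_value(a)
  ag_make(abs(av), list(a), function(g) list(g * sign(av)))
}

#' @keywords internal
#' @export
ag_exp <- function(a) {
  v <- exp(ag_value(a))
  ag_make(v, list(a), function(g) list(g * v))
}

#' @keywords internal
#' @export
ag_log <- function(a) {
  av <- ag_value(a)
  ag_make(log(av), list(a), function(g) list(g / av))
}

#' @keywords internal
#' @export
ag_sum <- function(a) {
  av <- ag_value(a)
  ag_make(sum(av), list(a), function(g) list(array(g, dim = dim(av) %||% length(av))))
}

#' @keywords internal
#' @export
ag_mean <- function(a) {
  av <- ag_value(a)
  n <- length(av)
  ag_make(mean(av), list(a), function(g) list(array(g / n, dim = dim(av) %||% n)))
}

# ---- activations -----------------------------------------------------------

#' @keywords internal
#' @export
ag_relu <- function(a) {
  av <- ag_value(a)
  meter_add("elementwise", length(av))
  ag_make(pmax(av, 0) * 1, list(a), function(g) list(g * (av > 0)))
}

#' @keywords internal
#' @export
ag_sigmoid <- function(a) {
  v <- 1 / (1 + exp(-ag_value(a)))
  meter_add("elementwise", length(v))
  ag_make(v, list(a), function(g) list(g * v * (1 - v)))
}

#' @keywords internal
#' @export
ag_silu <- function(a) {
  av <- ag_value(a)
  s <- 1 / (1 + exp(-av))
  meter_add("elementwise", length(av))
  ag_make(av * s, list(a), function(g) list(g * s * (1 + av * (1 - s))))
}

#' @keywords internal
#' @export
ag_gelu <- function(a) {
  av <- ag_value(a)
  ph <- stats::pnorm(av)
  meter_add("elementwise", length(av))
  ag_make(av * ph, list(a), function(g) list(g * (ph + av * stats::dnorm(av))))
}

# ---- shape utilities -------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @export
ag_reshape <- function(a, d) {
  av <- ag_value(a)
  od <- dim(av) %||% length(av)
  v <- av; dim(v) <- d
  ag_make(v, list(a), function(g) { dim(g) <- od; list(g) })
}

# Concatenate feature maps (C_i, H, W) along channels.
#' @keywords internal
#' @export
ag_concat_c <- function(xs) {
  vs <- lapply(xs, ag_value)
  cs <- vapply(vs, function(v) dim(v)[1], numeric(1))
  H <- dim(vs[[1]])[2]; W <- dim(vs[[1]])[3]
  v <- array(0, c(sum(cs), H, W))
  at <- 0L
  for (i in seq_along(vs)) { v[at + seq_len(cs[i]), , ] <- vs[[i]]; at <- at + cs[i] }
  ag_make(v, xs, function(g) {
    out <- vector("list", length(xs)); at <- 0L
    for (i in seq_along(xs)) {
      out[[i]] <- g[at + seq_len(cs[i]), , , drop = FALSE]
      at <- at + cs[i]
    }
    out
  })
}

# Channel slice of a (C,H,W) map.
#' @keywords internal
#' @export
ag_slice_c <- function(a, idx) {
  av <- ag_value(a)
  v <- av[idx, , , drop = FALSE]
  ag_make(v, list(a), function(g) {
    dx <- array(0, dim(av)); dx[idx, , ] <- g; list(dx)
  })
}

# Broadcast a length-C vector to a (C,H,W) map.
#' @keywords internal
#' @export
ag_bcast_vec <- function(a, H, W) {
  av <- ag_value(a)
  v <- array(av, c(length(av), H, W))
  ag_make(v, list(a), function(g) list(rowSums(g, dims = 1)))
}

# Per-channel global average pool: (C,H,W) -> length-C vector.
#' @keywords internal
#' @export
ag_gap <- function(a) {
  av <- ag_value(a)
  n <- dim(av)[2] * dim(av)[3]
  ag_make(rowMeans(av, dims = 1), list(a),
          function(g) list(array(rep(g / n, n), dim(av))))
}

# Multiply a (C,H,W) map by a per-channel vector.
#' @keywords internal
#' @export
ag_cmul_vec <- function(x, vec) {
  xv <- ag_value(x); vv <- ag_value(vec)
  d <- dim(xv)
  v <- xv * array(vv, d)
  ag_make(v, list(x, vec), function(g)
    list(g * array(vv, d), rowSums(g * xv, dims = 1)))
}

# Batch normalization over a (C,H,W) map. In inference mode this is the
# per-channel affine with stored running statistics; in training mode the
# statistics come from the current map (population moments over H*W) and the
# running buffers are updated in place with momentum.
#' @keywords internal
#' @export
ag_bn <- function(x, gamma, beta, buf, momentum = 0.1) {
  if (!.bd_mode$train)
    return(ag_bn_eval(x, gamma, beta, buf$mean, buf$var, buf$eps))
  xv <- ag_value(x); gv <- ag_value(gamma); bv <- ag_value(beta)
  d <- dim(xv); n <- d[2] * d[3]
  mu <- rowMeans(xv, dims = 1)
  xc <- xv - array(mu, d)
  va <- rowSums(xc * xc, dims = 1) / n
  buf$mean <- (1 - momentum) * buf$mean + momentum * mu
  buf$var <- (1 - momentum) * buf$var + momentum * pmax(va, 1e-12)
  inv <- 1 / sqrt(va + buf$eps)
  xh <- xc * array(inv, d)
  v <- xh * array(gv, d) + array(bv, d)
  meter_add("elementwise", 2 * length(v))
  ag_make(v, list(x, gamma, beta), function(g) {
    gxh <- g * array(gv, d)
    s1 <- rowSums(gxh, dims = 1) / n
    s2 <- rowSums(gxh * xh, dims = 1) / n
    dx <- (gxh - array(s1, d) - xh * array(s2, d)) * array(inv, d)
    list(dx, rowSums(g * xh, dims = 1), rowSums(g, dims = 1))
  })
}

# Per-channel affine used for inference-mode batch normalization.
#' @keywords internal
#' @export
ag_bn_eval <- function(x, gamma, beta, mean, var, eps) {
  xv <- ag_value(x); gv <- ag_value(gamma); bv <- ag_value(beta)
  if (any(var + eps <= 0)) stop("bn: non-positive variance + eps")
  a <- gv / sqrt(var + eps)
  d <- dim(xv)
  xc <- xv - array(mean, d)
  v <- xc * array(a, d) + array(bv, d)
  meter_add("elementwise", 2 * length(v))
  ag_make(v, list(x, gamma, beta), function(g) list(
    g * array(a, d),
    rowSums(g * xc, dims = 1) / sqrt(var + eps),
    rowSums(g, dims = 1)
  ))
}

# ---- matrix ops (token sequences) -----------------------------------------

#' @keywords internal
#' @export
ag_matmul <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  meter_add("linear_macs", as.numeric(nrow(av)) * ncol(av) * ncol(bv))
  ag_make(av %*% bv, list(a, b), function(g)
    list(g %*% t(bv), t(av) %*% g))
}

#' @keywords internal
#' @export
ag_t <- function(a) {
  av <- ag_value(a)
  ag_make(t(av), list(a), function(g) list(t(g)))
}

# x: (n x din), w: (din x dout), b: length dout or NULL
#' @keywords internal
#' @export
ag_linear <- function(x, w, b = NULL) {
  xv <- ag_value(x); wv <- ag_value(w)
  v <- xv %*% wv
  if (!is.null(b)) v <- sweep(v, 2, ag_value(b), "+")
  meter_add("linear_macs", as.numeric(nrow(v)) * nrow(wv) * ncol(wv))
  parents <- list(x, w, b)
  ag_make(v, parents, function(g) list(
    g %*% t(wv), t(xv) %*% g, if (is.null(b)) NULL else colSums(g)))
}

# Row-wise softmax of a matrix.
#' @keywords internal
#' @export
ag_softmax_rows <- function(a) {
  av <- ag_value(a)
  m <- av - apply(av, 1, max)
  e <- exp(m)
  v <- e / rowSums(e)
  ag_make(v, list(a), function(g) list(v * (g - rowSums(g * v))))
}

# Row-wise layer normalization with learnable gain/shift (length = ncol).
#' @keywords internal
#' @export
ag_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- ag_value(x); gv <- ag_value(gamma); bv <- ag_value(beta)
  d <- ncol(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  va <- rowSums(xc * xc) / d
  inv <- 1 / sqrt(va + eps)
  xh <- xc * inv
  v <- sweep(sweep(xh, 2, gv, "*"), 2, bv, "+")
  ag_make(v, list(x, gamma, beta), function(g) {
    dxh <- sweep(g, 2, gv, "*")
    dx <- inv * (dxh - rowMeans(dxh) - xh * rowMeans(dxh * xh))
    list(dx, colSums(g * xh), colSums(g))
  })
}

#' @keywords internal
#' @export
ag_rows <- function(a, idx) {
  av <- ag_value(a)
  ag_make(av[idx, , drop = FALSE], list(a), function(g) {
    dx <- matrix(0, nrow(av), ncol(av))
    if (anyDuplicated(idx)) {
      for (i in seq_along(idx)) dx[idx[i], ] <- dx[idx[i], ] + g[i, ]
    } else {
      dx[idx, ] <- g
    }
    list(dx)
  })
}

#' @keywords internal
#' @export
ag_cols <- function(a, idx) {
  av <- ag_value(a)
  ag_make(av[, idx, drop = FALSE], list(a), function(g) {
    dx <- matrix(0, nrow(av), ncol(av)); dx[, idx] <- g; list(dx)
  })
}

#' @keywords internal
#' @export
ag_cbind <- function(xs) {
  vs <- lapply(xs, ag_value)
  ks <- vapply(vs, ncol, numeric(1))
  ag_make(do.call(cbind, vs), xs, function(g) {
    out <- vector("list", length(xs)); at <- 0L
    for (i in seq_along(xs)) {
      out[[i]] <- g[, at + seq_len(ks[i]), drop = FALSE]; at <- at + ks[i]
    }
    out
  })
}

#' @keywords internal
#' @export
ag_rbind <- function(xs) {
  vs <- lapply(xs, ag_value)
  ns <- vapply(vs, nrow, numeric(1))
  ag_make(do.call(rbind, vs), xs, function(g) {
    out <- vector("list", length(xs)); at <- 0L
    for (i in seq_along(xs)) {
      out[[i]] <- g[at + seq_len(ns[i]), , drop = FALSE]; at <- at + ns[i]
    }
    out
  })
}

# Fused binary cross-entropy with logits (mean over elements, optional
# elementwise weights); numerically stable.
#' @keywords internal
#' @export
ag_bce_logits <- function(z, target, weight = NULL) {
  zv <- ag_value(z)
  w <- weight %||% 1
  l <- pmax(zv, 0) - zv * target + log1p(exp(-abs(zv)))
  n <- length(zv)
  ag_make(sum(w * l) / n, list(z), function(g) {
    p <- 1 / (1 + exp(-zv))
    list(g * w * (p - target) / n)
  })
}
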