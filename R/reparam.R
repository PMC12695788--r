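# Reparameterized convolution (RepConv).
#
# Training-time form: three parallel branches — a 3x3 convolution, a 1x1
# convolution and (when channels and stride permit) an identity path realized
# purely as batch normalization of the input. Each branch carries its own
# normalization; the branch outputs are summed and passed through SiLU.
#
# Inference-time form: the three branches collapse exactly into one 3x3
# convolution. Normalization folds into kernel and bias per output channel,
# the 1x1 kernel zero-pads to 3x3, and the identity path becomes a
# "diagonal unit" kernel (centre tap 1 on the channel's own input) before
# folding. Fusion is exact pre-activation, so outputs agree to numerical
# precision.

#' Create a RepConv module
#'
#' @param cin,cout channel counts; the identity branch exists only when
#'   `cin == cout` and `stride == 1`.
#' @param stride convolution stride.
#' @param identity include the identity (norm-only) branch when permitted;
#'   requesting it with `cin != cout` or `stride != 1` is an error.
#' @return a `bd_module` of kind `repconv`.
#' @export
mk_repconv <- function(cin, cout, stride = 1, identity = (cin == cout && stride == 1)) {
  if (identity && (cin != cout || stride != 1))
    stop("repconv: identity branch requires cin == cout and stride 1")
  params <- list(
    w3 = init_kernel(cout, cin, 3, 3), b3 = numeric(cout),
    w1 = init_kernel(cout, cin, 1, 1), b1 = numeric(cout),
    g_main = rep(1, cout), be_main = numeric(cout),
    g_aux = rep(1, cout), be_aux = numeric(cout))
  buffers <- list(bn_main = list2env(list(mean = numeric(cout), var = rep(1, cout), eps = 1e-5)),
                  bn_aux = list2env(list(mean = numeric(cout), var = rep(1, cout), eps = 1e-5)))
  if (identity) {
    params$g_id <- rep(1, cout); params$be_id <- numeric(cout)
    buffers$bn_id <- list2env(list(mean = numeric(cout), var = rep(1, cout), eps = 1e-5))
  }
  new_module("repconv", params, buffers,
             cfg = list(cin = cin, cout = cout, stride = stride, identity = identity))
}

#' @export
bd_forward.repconv <- function(m, x, ...) {
  p <- m$params; bf <- m$buffers; cfg <- m$cfg
  if (dim(ag_value(x))[1] != cfg$cin)
    stop(sprintf("repconv: input has %d channels, expected %d",
                 dim(ag_value(x))[1], cfg$cin))
  y <- ag_bn(ag_conv2d(x, p$w3, p$b3, stride = cfg$stride, pad = 1),
             p$g_main, p$be_main, bf$bn_main)
  y <- ag_add(y, ag_bn(ag_conv2d(x, p$w1, p$b1, stride = cfg$stride, pad = 0),
                       p$g_aux, p$be_aux, bf$bn_aux))
  if (cfg$identity)
    y <- ag_add(y, ag_bn(x, p$g_id, p$be_id, bf$bn_id))
  ag_silu(y)
}

#' Fold batch-normalization statistics into convolution parameters
#'
#' Returns the kernel and bias of the single convolution equivalent to
#' convolve-then-normalize: `W' = W * gamma / sqrt(var + eps)` per output
#' channel and `b' = beta + (b - mean) * gamma / sqrt(var + eps)`.
#'
#' @param w kernel array `c(Cout, Cin, kh, kw)`.
#' @param gamma,beta,mean,var,eps normalization statistics (length `Cout`).
#' @param b convolution bias folded alongside (default zero).
#' @return list with elements `w` and `b`.
#' @export
fold_bn <- function(w, gamma, beta, mean, var, eps, b = numeric(dim(w)[1])) {
  if (any(var + eps <= 0)) stop("fold_bn: non-positive variance + eps")
  s <- gamma / sqrt(var + eps)
  list(w = w * s, b = beta + (b - mean) * s) # s recycles over the first dim
}

# Zero-pad a (Cout, Cin, 1, 1) kernel to 3x3 (value lands on the centre tap).
pad_1x1_to_3x3 <- function(w1) {
  d <- dim(w1)
  w <- array(0, c(d[1], d[2], 3, 3))
  w[, , 2, 2] <- w1[, , 1, 1]
  w
}

# The identity map as a 3x3 kernel: centre tap 1 on each channel's own input.
identity_kernel_3x3 <- function(c) {
  w <- array(0, c(c, c, 3, 3))
  for (i in seq_len(c)) w[i, i, 2, 2] <- 1
  w
}

#' Fuse a RepConv module into a single 3x3 convolution
#'
#' Folds each branch's normalization, zero-pads the 1x1 kernel, expresses the
#' identity branch as a diagonal-unit 3x3 kernel, and sums kernels and biases.
#' For every input, `silu(conv3x3(x, w, b))` equals the training-time forward.
#'
#' @param m a `repconv` module.
#' @return list with the equivalent `w` (`c(Cout, Cin, 3, 3)`) and `b`.
#' @export
rep_fuse <- function(m) {
  stopifnot(inherits(m, "repconv"))
  p <- lapply(m$params, ag_value); bf <- m$buffers
  f3 <- fold_bn(p$w3, p$g_main, p$be_main, bf$bn_main$mean, bf$bn_main$var,
                bf$bn_main$eps, p$b3)
  f1 <- fold_bn(p$w1, p$g_aux, p$be_aux, bf$bn_aux$mean, bf$bn_aux$var,
                bf$bn_aux$eps, p$b1)
  w <- f3$w + pad_1x1_to_3x3(f1$w)
  b <- f3$b + f1$b
  if (m$cfg$identity) {
    fid <- fold_bn(identity_kernel_3x3(m$cfg$cout), p$g_id, p$be_id,
                   bf$bn_id$mean, bf$bn_id$var, bf$bn_id$eps)
    w <- w + fid$w
    b <- b + fid$b
  }
  list(w = w, b = b)
}

#' Convert a RepConv module to its fused inference form
#'
#' @param m a `repconv` module.
#' @return a `conv_unit` module (3x3, bias, SiLU, no norm) with identical
#'   input/output behaviour.
#' @export
rep_to_deploy <- function(m) {
  f <- rep_fuse(m)
  out <- mk_conv(m$cfg$cin, m$cfg$cout, 3, stride = m$cfg$stride,
                 norm = FALSE, act = "silu", bias = TRUE)
  out$params$w <- f$w
  out$params$b <- f$b
  out
}

#' Fuse every RepConv in a module tree (checkpoint conversion)
#'
#' Walks a model and replaces each multi-branch RepConv with its single-kernel
#' equivalent, leaving all other modules untouched. Use with
#' [bd_flat_params()] / [bd_set_flat()] to convert saved weights.
#'
#' @param m any `bd_module`.
#' @return the converted module tree.
#' @export
fuse_model <- function(m) {
  if (inherits(m, "repconv")) return(rep_to_deploy(m))
  if (length(m$sub)) m$sub <- lapply(m$sub, fuse_model)
  m
}
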