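# Independent oracles used across tests. These deliberately re-derive the
# operations with the most literal possible code (nested loops, dense DFT
# matrices) so they share nothing with the implementation paths they check.

# plain sliding-window convolution, stride/pad, no groups
conv_oracle <- function(x, w, b = NULL, stride = 1, pad = 0) {
  C <- dim(x)[1]; H <- dim(x)[2]; W <- dim(x)[3]
  Co <- dim(w)[1]; kh <- dim(w)[3]; kw <- dim(w)[4]
  s <- rep(stride, length.out = 2); p <- rep(pad, length.out = 2)
  if (is.null(b)) b <- numeric(Co)
  Ho <- (H + 2 * p[1] - kh) %/% s[1] + 1
  Wo <- (W + 2 * p[2] - kw) %/% s[2] + 1
  xp <- array(0, c(C, H + 2 * p[1], W + 2 * p[2]))
  xp[, p[1] + seq_len(H), p[2] + seq_len(W)] <- x
  y <- array(0, c(Co, Ho, Wo))
  for (o in seq_len(Co)) for (i in seq_len(Ho)) for (j in seq_len(Wo)) {
    acc <- b[o]
    for (c in seq_len(C)) for (u in seq_len(kh)) for (v in seq_len(kw))
      acc <- acc + w[o, c, u, v] * xp[c, (i - 1) * s[1] + u, (j - 1) * s[2] + v]
    y[o, i, j] <- acc
  }
  y
}

# per-channel (depthwise) sliding-window convolution
dw_conv_oracle <- function(x, w, pad) {
  C <- dim(x)[1]
  out <- array(0, dim(x))
  for (c in seq_len(C))
    out[c, , ] <- conv_oracle(x[c, , , drop = FALSE],
                              array(w[c, , , ], c(1, 1, dim(w)[3], dim(w)[4])),
                              pad = pad)
  out
}

# dense 2-D DFT of one channel matrix (unnormalized forward)
dft2 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  Fh <- outer(0:(H - 1), 0:(H - 1), function(j, k) exp(-2i * pi * j * k / H))
  Fw <- outer(0:(W - 1), 0:(W - 1), function(j, k) exp(-2i * pi * j * k / W))
  Fh %*% m %*% Fw
}

idft2 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  Fh <- outer(0:(H - 1), 0:(H - 1), function(j, k) exp(2i * pi * j * k / H))
  Fw <- outer(0:(W - 1), 0:(W - 1), function(j, k) exp(2i * pi * j * k / W))
  (Fh %*% m %*% Fw) / (H * W)
}

# a RepConv with fully randomized parameters and statistics
rand_repconv <- function(cin, cout, identity = (cin == cout)) {
  m <- mk_repconv(cin, cout, identity = identity)
  for (nm in c("w3", "w1")) m$params[[nm]][] <- stats::rnorm(length(m$params[[nm]])) * 0.4
  for (nm in c("b3", "b1", "be_main", "be_aux")) m$params[[nm]][] <- stats::rnorm(cout) * 0.3
  for (nm in c("g_main", "g_aux")) m$params[[nm]][] <- stats::runif(cout, 0.5, 1.5)
  for (bn in c("bn_main", "bn_aux")) {
    m$buffers[[bn]]$mean <- stats::rnorm(cout) * 0.3
    m$buffers[[bn]]$var <- stats::runif(cout, 0.4, 2)
  }
  if (identity) {
    m$params$g_id[] <- stats::runif(cout, 0.5, 1.5)
    m$params$be_id[] <- stats::rnorm(cout) * 0.3
    m$buffers$bn_id$mean <- stats::rnorm(cout) * 0.3
    m$buffers$bn_id$var <- stats::runif(cout, 0.4, 2)
  }
  m
}

silu_ref <- function(x) x / (1 + exp(-x))

rand_map <- function(C, H, W) array(stats::rnorm(C * H * W), c(C, H, W))
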