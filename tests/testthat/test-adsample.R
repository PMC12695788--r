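test_that("offset prediction is a strided convolution with 2N channels", {
  set.seed(1)
  m <- mk_adsample(64, 64, stride = 2L, N = 4L)
  # zero initialization: offsets are exactly zero
  x <- rand_map(64, 8, 8)
  delta <- ag_conv2d(x, m$params$w_off, m$params$b_off, stride = 2, pad = 1)
  expect_equal(dim(delta), c(8, 4, 4))
  expect_equal(max(abs(delta)), 0)
  # randomized offset conv matches the direct sliding-window oracle
  m$params$w_off[] <- rnorm(length(m$params$w_off)) * 0.2
  m$params$b_off[] <- rnorm(8) * 0.1
  d2 <- ag_conv2d(x, m$params$w_off, m$params$b_off, stride = 2, pad = 1)
  expect_lt(max(abs(d2 - conv_oracle(x, m$params$w_off, m$params$b_off,
                                     stride = 2, pad = 1))), 1e-10)
})

test_that("sampling coordinates are base grid + pattern + offsets", {
  # stride 2, N = 4 on a 4x4 input: the pattern tiles the stride window so
  # zero-offset sampling covers every input pixel exactly once
  pn <- adsample_pattern(4, 2)
  expect_equal(pn, c(0, 0, 1, 0, 0, 1, 1, 1))
  p0 <- adsample_base_grid(2, 2, 2, 4)
  P <- build_coords(p0, pn, array(0, c(8, 2, 2)))
  pts <- NULL
  for (k in 1:4) pts <- rbind(pts, cbind(as.numeric(P[2 * k - 1, , ]),
                                         as.numeric(P[2 * k, , ])))
  expect_equal(nrow(unique(pts)), 16)
  expect_setequal(pts[, 1], c(0, 1, 2, 3))
  # a constant offset translates every sampling coordinate
  d <- array(0, c(8, 2, 2)); d[seq(1, 8, by = 2), , ] <- 1  # x channels
  P2 <- build_coords(p0, pn, d)
  for (k in 1:4) {
    expect_equal(P2[2 * k - 1, , ], P[2 * k - 1, , ] + 1)
    expect_equal(P2[2 * k, , ], P[2 * k, , ])
  }
  expect_error(adsample_pattern(5, 2), "perfect square")
})

test_that("bilinear stencils form a partition of unity", {
  # lattice point: all weight on the top-left neighbour
  w <- bilinear_weights(3, 5)
  expect_equal(unname(w$w), c(1, 0, 0, 0))
  # cell centre: symmetric quarters
  expect_equal(unname(bilinear_weights(0.5, 0.5)$w), rep(0.25, 4))
  set.seed(2)
  for (i in 1:1000) {
    w <- bilinear_weights(runif(1, 0, 10), runif(1, 0, 10))
    expect_lt(abs(sum(w$w) - 1), 1e-12)
    expect_true(all(w$w >= 0 & w$w <= 1))
  }
})

test_that("resampling is exact on lattice points, affine maps and constants", {
  set.seed(3)
  x <- rand_map(2, 6, 6)
  # integer coordinates: exact gather
  y <- ag_bilinear(x, c(2, 4), c(1, 3))
  expect_equal(y[, 1], x[, 2, 3])
  expect_equal(y[, 2], x[, 4, 5])
  # bilinear interpolation reproduces affine images exactly
  ramp <- array(0, c(1, 6, 6))
  for (i in 1:6) for (j in 1:6) ramp[1, i, j] <- (i - 1) + 2 * (j - 1)
  px <- runif(20, 0, 4.9); py <- runif(20, 0, 4.9)
  expect_lt(max(abs(ag_bilinear(ramp, px, py)[1, ] - (py + 2 * px))), 1e-12)
  # constant images stay constant at any in-bounds coordinates
  cst <- array(0.7, c(3, 5, 5))
  expect_lt(max(abs(ag_bilinear(cst, px / 2, py / 2) - 0.7)), 1e-12)
  expect_error(ag_bilinear(x, c(NA, 1), c(1, 1)), "non-finite")
})

test_that("the module downsamples by its stride with SiLU aggregation", {
  set.seed(4)
  m <- mk_adsample(64, 128, stride = 2L, N = 4L)
  y <- bd_forward(m, rand_map(64, 32, 32))
  expect_equal(dim(y), c(128, 16, 16))
  expect_error(bd_forward(m, rand_map(64, 15, 16)), "stride")
  # zero column weights: a constant SiLU(bias) map
  m0 <- mk_adsample(2, 3, stride = 2L, N = 4L)
  m0$params$w_col[] <- 0
  m0$params$b_col <- c(-1, 0.5, 2)
  y0 <- bd_forward(m0, rand_map(2, 8, 8))
  for (o in 1:3)
    expect_equal(max(abs(y0[o, , ] - silu_ref(m0$params$b_col[o]))), 0)
  # uniform column weights on one channel: SiLU of 2x2 average pooling
  m1 <- mk_adsample(1, 1, stride = 2L, N = 4L)
  m1$params$w_col[] <- 0.25; m1$params$b_col[] <- 0
  xa <- rand_map(1, 6, 6)
  ya <- bd_forward(m1, xa)
  for (i in 1:3) for (j in 1:3)
    expect_equal(ya[1, i, j],
                 silu_ref(mean(xa[1, 2 * i - (1:0) - 0, 2 * j - (1:0) - 0])),
                 tolerance = 1e-12)
})

test_that("zero offsets reduce the module to a patterned strided convolution", {
  set.seed(5)
  m <- mk_adsample(3, 5, stride = 2L, N = 4L)
  x <- rand_map(3, 12, 12)
  # independent oracle: a 2x2 stride-2 convolution whose kernel rearranges
  # the column weights along the pattern layout
  weq <- array(0, c(5, 3, 2, 2))
  pn <- matrix(adsample_pattern(4, 2), nrow = 2)  # (x, y) per point
  for (k in 1:4) weq[, , pn[2, k] + 1, pn[1, k] + 1] <- m$params$w_col[, , k, 1]
  yo <- silu_ref(conv_oracle(x, weq, m$params$b_col, stride = 2, pad = 0))
  expect_lt(max(abs(bd_forward(m, x) - yo)), 1e-5)
})

test_that("the zero-offset output is translation-consistent", {
  set.seed(6)
  m <- mk_adsample(2, 4, stride = 2L, N = 4L)
  x <- rand_map(2, 12, 12)
  xs <- x[, c(3:12, 1:2), c(3:12, 1:2)]  # shift up-left by one stride
  y <- bd_forward(m, x)
  ys <- bd_forward(m, xs)
  expect_lt(max(abs(ys[, 1:4, 1:4] - y[, 2:5, 2:5])), 1e-10)
})

test_that("gradients reach the predicted offsets", {
  set.seed(7)
  m <- mk_adsample(2, 2, stride = 2L, N = 4L)
  x <- rand_map(2, 8, 8)
  # off-lattice offsets (at exactly zero the bilinear weights sit on their
  # kink and one-sided derivatives differ)
  m$params$w_off[] <- rnorm(length(m$params$w_off)) * 0.1
  m$params$b_off[] <- rnorm(length(m$params$b_off)) * 0.1
  f <- function(b) {
    mm <- m
    mm$params$b_off <- b
    sum(bd_forward(mm, x)^2)
  }
  b0 <- m$params$b_off
  eps <- 1e-6
  grads <- vapply(seq_along(b0), function(i) {
    bp <- b0; bp[i] <- bp[i] + eps
    bm <- b0; bm[i] <- bm[i] - eps
    (f(bp) - f(bm)) / (2 * eps)
  }, numeric(1))
  expect_gt(max(abs(grads)), 1e-6)
  # and the tape agrees with the finite differences
  bound <- bd_bind(m)
  loss <- ag_with_tape({
    y <- bd_forward(bound$module, x)
    ag_sum(ag_mul(y, y))
  })
  ag_backward(loss)
  expect_equal(bound$nodes[["b_off"]]$g, grads, tolerance = 1e-5)
})
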