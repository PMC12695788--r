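test_that("training-time forward matches the three-branch oracle", {
  set.seed(1)
  # zero input with neutral statistics gives zero output
  m0 <- mk_repconv(2, 2)
  m0$params$w3[] <- stats::rnorm(length(m0$params$w3))
  m0$params$w1[] <- stats::rnorm(length(m0$params$w1))
  y0 <- bd_forward(m0, array(0, c(2, 5, 5)))
  expect_equal(max(abs(y0)), 0)

  # zeroed convolution branches with unit identity statistics give silu(x)
  mi <- mk_repconv(3, 3)
  mi$params$w3[] <- 0; mi$params$w1[] <- 0
  mi$buffers$bn_id$eps <- 0
  x <- rand_map(3, 6, 6)
  expect_equal(bd_forward(mi, x), silu_ref(x), tolerance = 1e-12)

  # random branches equal the sum of three independently evaluated paths
  m <- rand_repconv(1, 2, identity = FALSE)
  x <- rand_map(1, 5, 5)
  bn <- function(y, g, be, mu, va, eps) {
    for (c in seq_len(dim(y)[1]))
      y[c, , ] <- (y[c, , ] - mu[c]) / sqrt(va[c] + eps) * g[c] + be[c]
    y
  }
  path3 <- bn(conv_oracle(x, m$params$w3, m$params$b3, pad = 1),
              m$params$g_main, m$params$be_main,
              m$buffers$bn_main$mean, m$buffers$bn_main$var, m$buffers$bn_main$eps)
  path1 <- bn(conv_oracle(x, m$params$w1, m$params$b1, pad = 0),
              m$params$g_aux, m$params$be_aux,
              m$buffers$bn_aux$mean, m$buffers$bn_aux$var, m$buffers$bn_aux$eps)
  expect_lt(max(abs(bd_forward(m, x) - silu_ref(path3 + path1))), 1e-5)
})

test_that("repconv rejects invalid configurations", {
  expect_error(mk_repconv(2, 3, identity = TRUE), "identity")
  m <- mk_repconv(2, 2)
  expect_error(bd_forward(m, array(0, c(3, 4, 4))), "channels")
})

test_that("norm folding matches convolve-then-normalize on any input", {
  set.seed(2)
  # neutral statistics leave parameters unchanged
  w <- init_kernel(2, 3, 3, 3)
  f <- fold_bn(w, gamma = rep(1, 2), beta = numeric(2), mean = numeric(2),
               var = rep(1, 2), eps = 0)
  expect_equal(f$w, w)
  expect_equal(f$b, numeric(2))
  expect_error(fold_bn(w, rep(1, 2), numeric(2), numeric(2), rep(-2, 2), 0),
               "variance")

  # identity branch folds to the scaled diagonal-unit kernel
  g <- runif(3, 0.5, 1.5); va <- runif(3, 0.5, 2); mu <- rnorm(3); be <- rnorm(3)
  fid <- fold_bn(berrydetr:::identity_kernel_3x3(3), g, be, mu, va, 1e-5)
  for (i in 1:3) for (j in 1:3)
    expect_equal(fid$w[i, j, 2, 2], if (i == j) g[i] / sqrt(va[i] + 1e-5) else 0)

  # random kernel and statistics: folded conv equals conv-then-normalize
  for (rep in 1:5) {
    w <- init_kernel(2, 2, 3, 3)
    g <- runif(2, 0.5, 1.5); va <- runif(2, 0.5, 2); mu <- rnorm(2); be <- rnorm(2)
    x <- rand_map(2, 4, 4)
    f <- fold_bn(w, g, be, mu, va, 1e-5)
    y1 <- conv_oracle(x, w, pad = 1)
    for (c in 1:2) y1[c, , ] <- (y1[c, , ] - mu[c]) / sqrt(va[c] + 1e-5) * g[c] + be[c]
    y2 <- conv_oracle(x, f$w, f$b, pad = 1)
    expect_lt(max(abs(y1 - y2)), 1e-5)
  }
})

test_that("padding a 1x1 kernel places its value on the centre tap", {
  m <- mk_repconv(1, 1, identity = FALSE)
  m$params$w3[] <- 0; m$params$b3[] <- 0; m$params$b1[] <- 0
  m$params$w1[1, 1, 1, 1] <- 0.7
  m$buffers$bn_main$eps <- 0; m$buffers$bn_aux$eps <- 0
  f <- rep_fuse(m)
  expect_equal(f$w[1, 1, 2, 2], 0.7)
  expect_equal(sum(abs(f$w)) - abs(f$w[1, 1, 2, 2]), 0)
  # all branches zero
  m$params$w1[] <- 0
  f0 <- rep_fuse(m)
  expect_equal(max(abs(f0$w)), 0)
  expect_equal(max(abs(f0$b)), 0)
})

test_that("fusion is exact over 100 random configurations", {
  set.seed(3)
  worst <- 0
  for (k in 1:100) {
    cin <- sample(1:3, 1)
    ident <- sample(c(TRUE, FALSE), 1)
    cout <- if (ident) cin else sample(1:3, 1)
    m <- rand_repconv(cin, cout, identity = ident)
    x <- rand_map(cin, 8, 8) * 2
    f <- rep_fuse(m)
    y_fused <- silu_ref(conv_oracle(x, f$w, f$b, pad = 1))
    dev <- max(abs(bd_forward(m, x) - y_fused))
    worst <- max(worst, dev)
  }
  expect_lt(worst, 1e-5)
})

test_that("fused parameter count is out*in*9 + out regardless of branches", {
  m <- rand_repconv(3, 3)
  d <- rep_to_deploy(m)
  expect_equal(bd_n_params(d), 3 * 3 * 9 + 3)
  expect_lt(bd_n_params(d), bd_n_params(m))
})

test_that("checkpoint conversion emits a fused state that reproduces outputs", {
  set.seed(4)
  model <- mk_seq(mk_conv(2, 3, 3), mk_repconv(3, 3), mk_conv(3, 2, 1))
  f_in <- tempfile(fileext = ".rds"); f_out <- tempfile(fileext = ".rds")
  save_weights(model, f_in)
  fused <- convert_checkpoint(model, f_in, f_out)
  fused2 <- load_weights(fuse_model(model), f_out)
  x <- rand_map(2, 6, 6)
  expect_lt(max(abs(bd_forward(model, x) - bd_forward(fused, x))), 1e-6)
  expect_lt(max(abs(bd_forward(fused, x) - bd_forward(fused2, x))), 1e-12)
})
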