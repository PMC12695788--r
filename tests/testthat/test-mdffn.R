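test_that("space-to-depth follows the documented sub-map ordering", {
  set.seed(1)
  x <- rand_map(2, 4, 4)
  y <- ag_space_to_depth(x)
  expect_equal(dim(y), c(8, 2, 2))
  # third channel group = rows 0,2 and columns 1,3 (0-based): offsets (0,1)
  expect_equal(y[5:6, , ], x[, c(1, 3), c(2, 4)])
  # first group (0,0), second (1,0), fourth (1,1)
  expect_equal(y[1:2, , ], x[, c(1, 3), c(1, 3)])
  expect_equal(y[3:4, , ], x[, c(2, 4), c(1, 3)])
  expect_equal(y[7:8, , ], x[, c(2, 4), c(2, 4)])
  # constant input: every sub-map equals the constant
  cst <- array(0.37, c(1, 6, 6))
  expect_true(all(ag_space_to_depth(cst) == 0.37))
  # bijectivity and mass conservation
  expect_identical(ag_depth_to_space(y), x)
  expect_equal(sum(y), sum(x))
  expect_error(ag_space_to_depth(rand_map(1, 5, 4)), "even")
})

test_that("spdconv equals convolution after rearrangement", {
  set.seed(2)
  # kernel shape: Cout x 4C x 3 x 3
  w <- init_kernel(16, 12, 3, 3)
  expect_equal(dim(w), c(16, 12, 3, 3))
  x <- rand_map(3, 8, 8)
  b <- rnorm(16)
  y <- spdconv(x, w, b)
  expect_equal(dim(y), c(16, 4, 4))
  expect_lt(max(abs(y - conv_oracle(ag_space_to_depth(x), w, b, pad = 1))), 1e-10)
  # selector kernel: centre tap on group 0 reproduces the top-left subsample
  wsel <- array(0, c(1, 4, 3, 3)); wsel[1, 1, 2, 2] <- 1
  x1 <- rand_map(1, 6, 6)
  ysel <- spdconv(x1, wsel, 0)
  expect_equal(array(ysel, c(3, 3)), x1[1, c(1, 3, 5), c(1, 3, 5)])
  expect_error(spdconv(x, init_kernel(4, 8, 3, 3), numeric(4)), "channels")
})

test_that("MDCM is the residual sum of four depthwise kernels plus attention", {
  set.seed(3)
  m <- mk_mdcm(4, strip = 31L)
  expect_equal(length(m$params$w_pt), 4)        # 1x1 per channel
  expect_equal(dim(m$params$w_h), c(4, 1, 1, 31))
  expect_equal(dim(m$params$w_v), c(4, 1, 31, 1))
  expect_equal(dim(m$params$w_sq), c(4, 1, 31, 31))
  x <- rand_map(4, 8, 8)
  # all kernels zero and the attention branch forced to zero -> ReLU(x)
  m0 <- m
  for (nm in c("w_pt", "w_h", "w_v", "w_sq")) m0$params[[nm]][] <- 0
  m0$sub$ddam$params$wf[] <- 0; m0$sub$ddam$params$bf[] <- 0
  m0$sub$ddam$params$ws[] <- 0; m0$sub$ddam$params$bs[] <- 0
  expect_equal(bd_forward(m0, x), pmax(x, 0) * 1, tolerance = 1e-12)
  # full module against the direct per-channel sliding-window oracle
  fin <- ag_gelu(ag_conv2d(x, m$params$w_in, m$params$b_in))
  acc <- x + dw_conv_oracle(fin, m$params$w_pt, pad = 0)
  acc <- acc + dw_conv_oracle(fin, m$params$w_h, pad = c(0, 15))
  acc <- acc + dw_conv_oracle(fin, m$params$w_v, pad = c(15, 0))
  acc <- acc + dw_conv_oracle(fin, m$params$w_sq, pad = c(15, 15))
  att <- bd_forward(m$sub$fmb, bd_forward(m$sub$ddam, fin))
  expect_lt(max(abs(bd_forward(m, x) - pmax(acc + att, 0))), 1e-8)
  expect_error(mk_mdcm(4, strip = 30L), "odd")
})

test_that("dual-domain attention matches a dense DFT oracle", {
  set.seed(4)
  m <- mk_ddam(1)
  m$params$ws[] <- rnorm(1)  # zero-initialized by construction; randomize
  x <- rand_map(1, 4, 4)
  y <- bd_forward(m, x)
  # oracle with explicit DFT matrices
  g <- as.numeric(m$params$wf) * mean(x) + m$params$bf
  fca <- abs(idft2(g * dft2(x[1, , ])))
  sv <- as.numeric(m$params$ws) * mean(fca) + m$params$bs
  expect_lt(max(abs(y[1, , ] - sv * fca)), 1e-5)
})

test_that("frequency gating with unit weights is the identity on x >= 0", {
  set.seed(5)
  x <- array(runif(2 * 4 * 4), c(2, 4, 4))
  ones <- array(1, dim(x))
  expect_lt(max(abs(ag_freq_gate(ones, x) - x)), 1e-10)
  # pooling identity: GAP of a constant map is the constant
  expect_equal(as.numeric(ag_gap(array(0.4, c(3, 5, 5)))), rep(0.4, 3))
  # FFT round trip preserves magnitudes for any real input
  xr <- rand_map(1, 8, 8)
  expect_lt(max(abs(ag_freq_gate(array(1, dim(xr)), xr) - abs(xr))), 1e-6)
})

test_that("frequency-modulation block matches the dense DFT oracle", {
  set.seed(6)
  m <- mk_fmb(2)
  m$params$alpha[] <- rnorm(2); m$params$beta[] <- rnorm(2)
  x <- rand_map(2, 4, 4)
  y <- bd_forward(m, x)
  W1 <- m$params$w1[, , 1, 1]; W2 <- m$params$w2[, , 1, 1]
  f1 <- array(0, dim(x)); f2 <- array(0, dim(x))
  for (i in 1:4) for (j in 1:4) {
    f1[, i, j] <- W1 %*% x[, i, j]
    f2[, i, j] <- W2 %*% x[, i, j]
  }
  for (c in 1:2) {
    mod <- abs(idft2(f1[c, , ] * dft2(f2[c, , ])))
    expect_lt(max(abs(y[c, , ] - (m$params$alpha[c] * mod + m$params$beta[c] * x[c, , ]))), 1e-5)
  }
  # alpha = 0, beta = 1 passes the input through; alpha = beta = 0 gives zero
  m$params$alpha[] <- 0; m$params$beta[] <- 1
  expect_equal(bd_forward(m, x), x, tolerance = 1e-12)
  m$params$beta[] <- 0
  expect_equal(max(abs(bd_forward(m, x))), 0)
})

test_that("CMKBlock splits 25% of channels through MDCM", {
  set.seed(7)
  m <- mk_cmkblock(64, 64, strip = 7L)
  expect_equal(m$cfg$cp, 16)
  expect_equal(m$sub$mdcm1$cfg$c, 16)
  expect_error(mk_cmkblock(8, 2), "channels")
  # identity channels pass through unchanged before fusion
  m2 <- mk_cmkblock(8, 8, strip = 7L)
  x <- rand_map(8, 6, 6)
  pre <- bd_forward(m2$sub$pre, x)
  keep <- pre[3:8, , , drop = FALSE]
  proc0 <- bd_forward(m2$sub$mdcm1, pre[1:2, , , drop = FALSE])
  ref <- bd_forward(m2$sub$fuse, ag_concat_c(list(proc0, keep)))
  expect_equal(bd_forward(m2, x), ref, tolerance = 1e-12)
  # analytic parameter count: two 1x1 conv units + MDCM kernels
  cp <- 2; c <- 8; s <- 7
  mdcm_p <- (cp * cp + cp) + cp * (1 + s + s + s * s) +
    2 * (cp * cp + cp) + 2 * cp * cp + 2 * cp
  expect_equal(bd_n_params(m2),
               (8 * 8 + 2 * 8) + mdcm_p + (8 * 8 + 2 * 8))
})

test_that("the fused pyramid emits decoder-ready scales and stays connected", {
  set.seed(8)
  # feature sizes as they arise from a 640 x 640 image, at reduced width
  nk <- mk_neck("mdffn", fw = 16L, p2_channels = 8L, strip = 7L,
                spd_reduce = 8L, p2_width = 16L)
  feats <- list(p2 = rand_map(8, 160, 160), f3 = rand_map(16, 80, 80),
                f4 = rand_map(16, 40, 40), f5 = rand_map(16, 20, 20))
  out <- bd_forward(nk, feats)
  expect_equal(sapply(out, function(f) dim(f)[2]), c(n3 = 80, n4 = 40, n5 = 20))
  expect_true(all(sapply(out, function(f) dim(f)[1] == 16)))
  # all weights zero -> all outputs zero (connectivity sanity)
  flat <- bd_flat_params(nk)
  nk0 <- bd_set_flat(nk, lapply(flat, function(p) p * 0))
  out0 <- bd_forward(nk0, feats)
  expect_true(all(sapply(out0, function(f) max(abs(f)) == 0)))
  # a missing P2 input is a configuration error
  expect_error(bd_forward(nk, feats[-1]), "P2")
})

test_that("the multi-domain neck adds parameters over the baseline neck", {
  set.seed(9)
  nc <- neck_default_config()
  mdffn <- mk_neck("mdffn", fw = 256L, p2_channels = 64L,
                   spd_reduce = nc$spd_reduce, cmk_repeats = nc$cmk_repeats,
                   p2_width = nc$p2_width)
  ccfm <- mk_neck("ccfm", fw = 256L)
  expect_gt(bd_n_params(mdffn), bd_n_params(ccfm))
})
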