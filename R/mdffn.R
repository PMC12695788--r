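# MDFFN: multi-domain feature-fusion neck, plus the baseline
# concatenation-convolution (CCFM-style) neck it replaces.
#
# Components:
#   SPDConv   lossless space-to-depth rearrangement followed by a 3x3
#             convolution on the 4x channels.
#   MDCM      omnidirectional depthwise kernels (1x1 point, 1x31 and 31x1
#             strips, 31x31 square) on a GELU-preprocessed map, summed
#             residually with a dual-domain attention branch, ReLU output.
#   DDAM      frequency-channel attention (spectrum gated by weights from
#             global average pooling) cascaded with spatial channel attention.
#   FMB       frequency-modulation block: complex-domain product of two 1x1
#             convolution branches with learnable per-channel mixing.
#   CMKBlock  cross-stage split: 25% of channels through MDCM, 75% identity,
#             fused by 1x1 convolutions.
#
# The neck fuses P3..P5 (and, for the multi-domain variant, P2) at a common
# fusion width in a top-down + bottom-up pyramid; fusion nodes are CMKBlocks
# (multi-domain) or CSP blocks of reparameterized convolutions (baseline),
# and bottom-up downsampling is SPDConv (multi-domain) or strided 3x3
# convolution (baseline).

#' Space-to-depth convolution (functional form)
#'
#' Rearranges 2x2 neighbourhoods into channels (see [ag_space_to_depth()])
#' and applies a stride-1, padding-1 3x3 convolution with bias.
#'
#' @param x map `c(C, H, W)` with even spatial dims.
#' @param w kernel `c(Cout, 4C, 3, 3)`.
#' @param b bias, length `Cout`.
#' @return map `c(Cout, H/2, W/2)`.
#' @export
spdconv <- function(x, w, b) {
  xr <- ag_space_to_depth(x)
  if (dim(ag_value(xr))[1] != dim(ag_value(w))[2])
    stop(sprintf("spdconv: kernel expects %d channels, rearranged input has %d",
                 dim(ag_value(w))[2], dim(ag_value(xr))[1]))
  ag_conv2d(xr, w, b, stride = 1, pad = 1)
}

#' Space-to-depth downsampling unit
#'
#' Module form of SPDConv used in the neck's bottom-up path: an optional 1x1
#' reduction, the space-to-depth rearrangement, then a 3x3 convolution unit.
#'
#' @param cin,cout channel counts.
#' @param reduce channel count after the 1x1 pre-reduction (`NULL` to skip).
#' @export
mk_spd_down <- function(cin, cout, reduce = NULL) {
  sub <- list()
  c0 <- cin
  if (!is.null(reduce)) {
    sub$red <- mk_conv(cin, reduce, 1)
    c0 <- reduce
  }
  sub$conv <- mk_conv(4L * c0, cout, 3)
  new_module("spd_down", sub = sub, cfg = list(cin = cin, cout = cout, reduce = reduce))
}

#' @export
bd_forward.spd_down <- function(m, x, ...) {
  if (!is.null(m$cfg$reduce)) x <- bd_forward(m$sub$red, x)
  bd_forward(m$sub$conv, ag_space_to_depth(x))
}

#' Dual-domain attention module
#'
#' Frequency-channel attention first: per-channel weights from global average
#' pooling through a linear map gate the channel spectra, and the magnitude
#' of the inverse transform is taken. Spatial-channel attention then rescales
#' channels by weights pooled from the intermediate result.
#'
#' @param c channel count.
#' @export
mk_ddam <- function(c) {
  # spatial-channel gate starts at zero so the (multiplicative) attention
  # branch grows from an identity-like state during training
  new_module("ddam",
             params = list(wf = init_mat(c, c), bf = numeric(c),
                           ws = matrix(0, c, c), bs = numeric(c)),
             cfg = list(c = c))
}

#' @export
bd_forward.ddam <- function(m, x, ...) {
  d <- dim(ag_value(x))
  gvec <- ag_reshape(ag_linear(ag_reshape(ag_gap(x), c(1L, d[1])),
                               m$params$wf, m$params$bf), d[1])
  fca <- ag_freq_gate(ag_bcast_vec(gvec, d[2], d[3]), x)
  svec <- ag_reshape(ag_linear(ag_reshape(ag_gap(fca), c(1L, d[1])),
                               m$params$ws, m$params$bs), d[1])
  ag_cmul_vec(fca, svec)
}

#' Frequency-modulation block
#'
#' Two parallel 1x1 convolution branches; the spectrum of one is gated
#' elementwise by the other in the complex domain, and the magnitude of the
#' inverse transform is mixed with the input through learnable per-channel
#' coefficients alpha and beta. Initialized at alpha = 0, beta = 1 (identity).
#'
#' @param c channel count.
#' @export
mk_fmb <- function(c) {
  new_module("fmb",
             params = list(w1 = init_kernel(c, c, 1, 1),
                           w2 = init_kernel(c, c, 1, 1),
                           alpha = numeric(c), beta = rep(1, c)),
             cfg = list(c = c))
}

#' @export
bd_forward.fmb <- function(m, x, ...) {
  f1 <- ag_conv2d(x, m$params$w1)
  f2 <- ag_conv2d(x, m$params$w2)
  mod <- ag_freq_gate(f1, f2)
  ag_add(ag_cmul_vec(mod, m$params$alpha), ag_cmul_vec(x, m$params$beta))
}

#' Multi-directional convolution module
#'
#' @param c channel count.
#' @param strip odd strip length for the 1xk / kx1 / kxk depthwise kernels.
#' @export
mk_mdcm <- function(c, strip = 31L) {
  if (strip %% 2L != 1L) stop("mdcm: strip length must be odd")
  new_module("mdcm",
             params = list(
               w_in = init_kernel(c, c, 1, 1), b_in = numeric(c),
               w_pt = init_kernel(c, 1, 1, 1),
               w_h = init_kernel(c, 1, 1, strip),
               w_v = init_kernel(c, 1, strip, 1),
               w_sq = init_kernel(c, 1, strip, strip)),
             sub = list(ddam = mk_ddam(c), fmb = mk_fmb(c)),
             cfg = list(c = c, strip = as.integer(strip)))
}

#' @export
bd_forward.mdcm <- function(m, x, ...) {
  c <- m$cfg$c; hs <- (m$cfg$strip - 1L) %/% 2L
  if (dim(ag_value(x))[1] != c)
    stop(sprintf("mdcm: input has %d channels, expected %d", dim(ag_value(x))[1], c))
  fin <- ag_gelu(ag_conv2d(x, m$params$w_in, m$params$b_in))
  acc <- ag_add(x, ag_conv2d(fin, m$params$w_pt, groups = c))
  acc <- ag_add(acc, ag_conv2d(fin, m$params$w_h, pad = c(0L, hs), groups = c))
  acc <- ag_add(acc, ag_conv2d(fin, m$params$w_v, pad = c(hs, 0L), groups = c))
  acc <- ag_add(acc, ag_conv2d(fin, m$params$w_sq, pad = hs, groups = c))
  att <- bd_forward(m$sub$fmb, bd_forward(m$sub$ddam, fin))
  ag_relu(ag_add(acc, att))
}

#' Cross-stage multi-kernel block
#'
#' @param cin,cout channel counts.
#' @param split_fraction fraction of channels routed through MDCM.
#' @param strip strip length for the MDCM kernels.
#' @param repeats number of cascaded MDCM modules on the processing branch.
#' @export
mk_cmkblock <- function(cin, cout, split_fraction = 0.25, strip = 31L, repeats = 1L) {
  if (cout < 4L) stop("cmkblock: too few channels to split")
  cp <- as.integer(round(cout * split_fraction))
  if (cp < 1L || cp >= cout) stop("cmkblock: split produces an empty branch")
  sub <- list(pre = mk_conv(cin, cout, 1))
  for (r in seq_len(repeats)) sub[[paste0("mdcm", r)]] <- mk_mdcm(cp, strip)
  sub$fuse <- mk_conv(cout, cout, 1)
  new_module("cmkblock", sub = sub,
             cfg = list(cin = cin, cout = cout, cp = cp,
                        split_fraction = split_fraction,
                        strip = as.integer(strip), repeats = as.integer(repeats)))
}

#' @export
bd_forward.cmkblock <- function(m, x, ...) {
  cfg <- m$cfg
  y <- bd_forward(m$sub$pre, x)
  proc <- ag_slice_c(y, seq_len(cfg$cp))
  keep <- ag_slice_c(y, (cfg$cp + 1L):cfg$cout)
  for (r in seq_len(cfg$repeats))
    proc <- bd_forward(m$sub[[paste0("mdcm", r)]], proc)
  bd_forward(m$sub$fuse, ag_concat_c(list(proc, keep)))
}

# ---- baseline CSP fusion block (reparameterized bottleneck) ----------------

#' Cross-stage partial block of reparameterized convolutions (baseline neck)
#'
#' @param cin,cout channel counts.
#' @param n number of RepConv bottlenecks.
#' @param expansion hidden width fraction.
#' @export
mk_csprep <- function(cin, cout, n = 3L, expansion = 0.5) {
  h <- as.integer(round(cout * expansion))
  sub <- list(conv1 = mk_conv(cin, h, 1), conv2 = mk_conv(cin, h, 1))
  for (i in seq_len(n))
    sub[[paste0("rep", i)]] <- mk_repconv(h, h, identity = FALSE)
  sub$conv3 <- mk_conv(h, cout, 1)
  new_module("csprep", sub = sub, cfg = list(cin = cin, cout = cout, n = n, h = h))
}

#' @export
bd_forward.csprep <- function(m, x, ...) {
  a <- bd_forward(m$sub$conv1, x)
  for (i in seq_len(m$cfg$n)) a <- bd_forward(m$sub[[paste0("rep", i)]], a)
  b <- bd_forward(m$sub$conv2, x)
  bd_forward(m$sub$conv3, ag_add(a, b))
}

# ---- neck ------------------------------------------------------------------

#' Build the fusion neck
#'
#' Both variants share the same pyramid skeleton: lateral 1x1 units on the
#' upper feature before 2x nearest upsampling, concatenation with the level
#' below, and a fusion block per node on the way down; then downsampling,
#' concatenation and a fusion block per node on the way up. The multi-domain
#' variant swaps fusion blocks for CMKBlocks, strided convolutions for
#' SPDConv downsampling, and extends the pyramid down to P2 (P2 is fused
#' back downward, not handed to the decoder).
#'
#' @param kind `"mdffn"` or `"ccfm"`.
#' @param fw fusion width (channels at every node).
#' @param p2_channels backbone P2 width (mdffn only).
#' @param use_p2 include the P2 entry node (mdffn default TRUE).
#' @param csp_n bottlenecks per baseline fusion block.
#' @param cmk_repeats MDCM repeats per CMKBlock.
#' @param split_fraction,strip CMKBlock settings.
#' @param spd_reduce channel reduction before space-to-depth (see
#'   [mk_spd_down()]).
#' @param downsample `"spd"` or `"adsample"` for the bottom-up path of the
#'   multi-domain variant (the baseline always uses strided convolution
#'   unless `"adsample"` is requested).
#' @return a `bd_module` of kind `neck`; forward takes
#'   `list(p2 = <raw P2 map or NULL>, f3, f4, f5)` (f maps at width `fw`)
#'   and returns `list(n3, n4, n5)` at strides 8/16/32.
#' @export
mk_neck <- function(kind = c("mdffn", "ccfm"), fw = 256L, p2_channels = 64L,
                    use_p2 = kind == "mdffn", csp_n = 3L, cmk_repeats = 1L,
                    split_fraction = 0.25, strip = 31L, spd_reduce = NULL,
                    downsample = NULL, p2_width = fw) {
  kind <- match.arg(kind)
  if (is.null(downsample)) downsample <- if (kind == "mdffn") "spd" else "conv"
  # per-node settings: scalars broadcast, or named vectors/lists
  rep_of <- function(node) {
    if (length(cmk_repeats) == 1L && is.null(names(cmk_repeats))) return(as.integer(cmk_repeats))
    as.integer(cmk_repeats[[node]] %||% 1L)
  }
  red_of <- function(node) {
    if (is.null(spd_reduce)) return(NULL)
    if (length(spd_reduce) == 1L && is.null(names(spd_reduce))) return(as.integer(spd_reduce))
    r <- spd_reduce[[node]]
    if (is.null(r) || is.na(r)) NULL else as.integer(r)
  }
  fuse_block <- function(cin, node, width = fw)
    if (kind == "mdffn") mk_cmkblock(cin, width, split_fraction, strip, rep_of(node))
    else mk_csprep(cin, width, csp_n)
  down_unit <- function(node, cin = fw)
    switch(downsample,
           spd = mk_spd_down(cin, fw, reduce = red_of(node)),
           conv = mk_conv(cin, fw, 3, stride = 2),
           adsample = mk_adsample(cin, fw, stride = 2L, N = 4L))
  sub <- list(
    lat5 = mk_conv(fw, fw, 1), fpn4 = fuse_block(2L * fw, "fpn4"),
    lat4 = mk_conv(fw, fw, 1), fpn3 = fuse_block(2L * fw, "fpn3"),
    down3 = down_unit("down3"), pan4 = fuse_block(2L * fw, "pan4"),
    down4 = down_unit("down4"), pan5 = fuse_block(2L * fw, "pan5"))
  if (use_p2) {
    p2w <- as.integer(p2_width)
    sub$lat3 <- mk_conv(fw, p2w, 1)
    sub$lat2 <- mk_conv(p2_channels, p2w, 1)
    sub$fpn2 <- fuse_block(2L * p2w, "fpn2", p2w)
    sub$down2 <- down_unit("down2", p2w)
    sub$pan3 <- fuse_block(2L * fw, "pan3")
  }
  new_module("neck", sub = sub,
             cfg = list(kind = kind, fw = fw, use_p2 = use_p2,
                        p2_channels = p2_channels, downsample = downsample,
                        p2_width = as.integer(p2_width)))
}

#' @export
bd_forward.neck <- function(m, x, ...) {
  s <- m$sub
  f3 <- x$f3; f4 <- x$f4; f5 <- x$f5
  l5 <- bd_forward(s$lat5, f5)
  n4 <- bd_forward(s$fpn4, ag_concat_c(list(ag_upsample2(l5), f4)))
  l4 <- bd_forward(s$lat4, n4)
  n3 <- bd_forward(s$fpn3, ag_concat_c(list(ag_upsample2(l4), f3)))
  if (m$cfg$use_p2) {
    if (is.null(x$p2)) stop("neck: configured with a P2 entry but no p2 input given")
    l3 <- bd_forward(s$lat3, n3)
    p2l <- bd_forward(s$lat2, x$p2)
    n2 <- bd_forward(s$fpn2, ag_concat_c(list(ag_upsample2(l3), p2l)))
    n3 <- bd_forward(s$pan3, ag_concat_c(list(bd_forward(s$down2, n2), n3)))
  }
  o4 <- bd_forward(s$pan4, ag_concat_c(list(bd_forward(s$down3, n3), n4)))
  o5 <- bd_forward(s$pan5, ag_concat_c(list(bd_forward(s$down4, o4), l5)))
  list(n3 = n3, n4 = o4, n5 = o5)
}
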