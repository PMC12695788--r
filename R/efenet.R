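# EFENet: enhanced feature-extraction backbone.
#
# Stem (stride 4 after the first stage's downsample) + four stages of MFEM
# blocks emitting a P2/P3/P4/P5 pyramid at strides 4/8/16/32.
#
# MFEM (multi-path feature enhancement module): an expanding 1x1 convolution
# splits features into an untouched branch F1 and a processing branch F2;
# F2 passes through a RepConv, then n-1 cascaded 3x3 convolutions, then a
# closing 1x1 adjustment; all intermediate branch outputs are concatenated
# and fused by a final 1x1 convolution. With branch width h the concatenation
# carries (n + 2) * h channels: F1, Frep, Fm_1..Fm_{n-1}, Fcv4.

#' Create an MFEM block
#'
#' @param cin,cout channel counts (spatial size is preserved).
#' @param n number of convolutions on the processing branch after the
#'   RepConv (the cascade has `n - 1` members), `n >= 1`.
#' @param hidden per-branch width after the expanding 1x1 convolution.
#' @return a `bd_module` of kind `mfem`.
#' @export
mk_mfem <- function(cin, cout, n, hidden) {
  if (n < 1) stop("mfem: n must be >= 1")
  if (hidden < 1) stop("mfem: hidden must be >= 1")
  sub <- list(
    open = mk_conv(cin, 2L * hidden, 1),
    rep = mk_repconv(hidden, hidden))
  if (n > 1)
    for (i in seq_len(n - 1L))
      sub[[paste0("casc", i)]] <- mk_conv(hidden, hidden, 3)
  sub$cv4 <- mk_conv(hidden, hidden, 1, norm = FALSE, act = "none", bias = TRUE)
  sub$close <- mk_conv((n + 2L) * hidden, cout, 1)
  new_module("mfem", sub = sub,
             cfg = list(cin = cin, cout = cout, n = n, hidden = hidden))
}

#' @export
bd_forward.mfem <- function(m, x, ...) {
  cfg <- m$cfg
  if (dim(ag_value(x))[1] != cfg$cin)
    stop(sprintf("mfem: input has %d channels, expected %d",
                 dim(ag_value(x))[1], cfg$cin))
  h <- cfg$hidden
  e <- bd_forward(m$sub$open, x)
  f1 <- ag_slice_c(e, seq_len(h))
  f2 <- ag_slice_c(e, h + seq_len(h))
  branches <- vector("list", cfg$n + 2L)
  branches[[1]] <- f1
  cur <- bd_forward(m$sub$rep, f2)
  branches[[2]] <- cur
  if (cfg$n > 1)
    for (i in seq_len(cfg$n - 1L)) {
      cur <- bd_forward(m$sub[[paste0("casc", i)]], cur)
      branches[[2L + i]] <- cur
    }
  branches[[cfg$n + 2L]] <- bd_forward(m$sub$cv4, cur)
  bd_forward(m$sub$close, ag_concat_c(branches))
}

#' Build the EFENet backbone
#'
#' @param cfg list with fields `stem_width`, `stage_widths` (4 increasing
#'   ints, channels of P2..P5), `stage_depths` (4 ints, MFEM blocks per
#'   stage), `n` (length-4, cascade setting per stage), `hidden_frac`
#'   (branch width as a fraction of the stage width, default 0.5).
#' @param downsample `"conv"` for strided 3x3 convolutions between stages or
#'   `"adsample"` for adaptive deformable downsampling.
#' @return a `bd_module` of kind `efenet`; its forward maps a `c(3, H, W)`
#'   image (H, W divisible by 32) to a list of four maps at strides
#'   4/8/16/32.
#' @export
mk_efenet <- function(cfg = efenet_default_config(), downsample = c("conv", "adsample"),
                      adsample_sites = c(2L, 3L)) {
  downsample <- match.arg(downsample)
  sw <- cfg$stage_widths
  if (length(sw) != 4L || any(diff(sw) <= 0)) stop("efenet: need 4 strictly increasing stage widths")
  sd <- cfg$stage_depths
  nn <- rep(cfg$n, length.out = 4)
  hf <- cfg$hidden_frac %||% 0.5
  mkdown <- function(cin, cout, site)
    if (downsample == "adsample" && site %in% adsample_sites)
      mk_adsample(cin, cout, stride = 2L, N = 4L)
    else mk_conv(cin, cout, 3, stride = 2)
  sub <- list(
    stem1 = mk_conv(3, cfg$stem_width, 3, stride = 2),
    stem2 = mk_conv(cfg$stem_width, cfg$stem_width, 3))
  prev <- cfg$stem_width
  for (s in 1:4) {
    sub[[paste0("down", s)]] <- mkdown(prev, sw[s], s)
    if (sd[s] > 0)
      for (b in seq_len(sd[s]))
        sub[[paste0("s", s, "b", b)]] <-
          mk_mfem(sw[s], sw[s], nn[s], max(1L, round(sw[s] * hf)))
    prev <- sw[s]
  }
  new_module("efenet", sub = sub,
             cfg = c(cfg, list(downsample = downsample,
                               adsample_sites = adsample_sites)))
}

#' @export
bd_forward.efenet <- function(m, x, ...) {
  d <- dim(ag_value(x))
  if (d[2] %% 32L != 0L || d[3] %% 32L != 0L)
    stop(sprintf("efenet: input %d x %d not divisible by 32", d[2], d[3]))
  cur <- bd_forward(m$sub$stem2, bd_forward(m$sub$stem1, x))
  out <- vector("list", 4)
  sd <- m$cfg$stage_depths
  for (s in 1:4) {
    cur <- bd_forward(m$sub[[paste0("down", s)]], cur)
    if (sd[s] > 0)
      for (b in seq_len(sd[s]))
        cur <- bd_forward(m$sub[[paste0("s", s, "b", b)]], cur)
    out[[s]] <- cur
  }
  names(out) <- c("p2", "p3", "p4", "p5")
  out
}
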