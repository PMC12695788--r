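# ResNet-18 backbone (baseline feature extractor).
#
# Standard configuration: 7x7/2 stem + 3x3/2 max pool, four stages of two
# basic blocks at widths 64/128/256/512, 1x1 projection shortcuts at stage
# entries. Emits C2..C5 at strides 4/8/16/32. The stride-2 3x3 convolution
# opening stages 2-4 can be swapped for ADSample (downsampling ablation).

mk_basic_block <- function(cin, cout, stride = 1, down_kind = "conv") {
  sub <- list()
  if (stride == 2 && down_kind == "adsample") {
    sub$conv1 <- mk_adsample(cin, cout, stride = 2L, N = 4L)
  } else {
    sub$conv1 <- mk_conv(cin, cout, 3, stride = stride, act = "relu")
  }
  sub$conv2 <- mk_conv(cout, cout, 3, act = "none")
  if (stride != 1 || cin != cout)
    sub$short <- mk_conv(cin, cout, 1, stride = stride, act = "none")
  new_module("basic_block", sub = sub,
             cfg = list(cin = cin, cout = cout, stride = stride))
}

#' @export
bd_forward.basic_block <- function(m, x, ...) {
  y <- bd_forward(m$sub$conv2, bd_forward(m$sub$conv1, x))
  sh <- if (!is.null(m$sub$short)) bd_forward(m$sub$short, x) else x
  ag_relu(ag_add(y, sh))
}

#' Build the ResNet-18 backbone
#'
#' @param downsample `"conv"` for the standard strided convolutions or
#'   `"adsample"` to replace the stage-entry stride-2 convolutions with
#'   adaptive deformable downsampling.
#' @return a `bd_module` of kind `resnet18`; forward maps a `c(3, H, W)`
#'   image (H, W divisible by 32) to `list(p2, p3, p4, p5)` at widths
#'   64/128/256/512 and strides 4/8/16/32.
#' @export
mk_resnet18 <- function(downsample = c("conv", "adsample"),
                        adsample_sites = c(2L, 3L)) {
  downsample <- match.arg(downsample)
  widths <- c(64L, 128L, 256L, 512L)
  sub <- list(stem = mk_conv(3, 64, 7, stride = 2, pad = 3, act = "relu"))
  prev <- 64L
  for (s in 1:4) {
    st <- if (s == 1) 1 else 2
    dk <- if (downsample == "adsample" && s %in% adsample_sites) "adsample" else "conv"
    sub[[paste0("l", s, "b1")]] <- mk_basic_block(prev, widths[s], st, dk)
    sub[[paste0("l", s, "b2")]] <- mk_basic_block(widths[s], widths[s], 1)
    prev <- widths[s]
  }
  new_module("resnet18", sub = sub,
             cfg = list(widths = widths, downsample = downsample,
                        adsample_sites = adsample_sites))
}

#' @export
bd_forward.resnet18 <- function(m, x, ...) {
  d <- dim(ag_value(x))
  if (d[2] %% 32L != 0L || d[3] %% 32L != 0L)
    stop(sprintf("resnet18: input %d x %d not divisible by 32", d[2], d[3]))
  cur <- ag_maxpool(bd_forward(m$sub$stem, x), 3, 2, pad = 1)
  out <- vector("list", 4)
  for (s in 1:4) {
    cur <- bd_forward(m$sub[[paste0("l", s, "b1")]], cur)
    cur <- bd_forward(m$sub[[paste0("l", s, "b2")]], cur)
    out[[s]] <- cur
  }
  names(out) <- c("p2", "p3", "p4", "p5")
  out
}
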