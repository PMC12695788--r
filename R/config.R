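# Default configurations.

#' Default EFENet configuration
#'
#' Stage widths follow the familiar 64/128/256/512 pyramid with a 32-channel
#' stem; depths and cascade settings are fixed once against the analytic
#' parameter counter so that the backbone slots into the standard detector
#' head at the published model scale.
#'
#' @return a config list for [mk_efenet()].
#' @export
efenet_default_config <- function() {
  list(stem_width = 32L,
       stage_widths = c(64L, 128L, 256L, 512L),
       stage_depths = c(1L, 2L, 1L, 2L),
       n = c(2L, 2L, 2L, 1L),
       hidden_frac = 0.5)
}

#' Default neck configuration
#'
#' Per-node channel reductions ahead of the space-to-depth downsamplers and
#' MDCM repeat counts per fusion node, fixed once against the analytic
#' parameter and FLOP counters alongside the backbone defaults.
#'
#' @return a list with `spd_reduce` and `cmk_repeats`.
#' @export
neck_default_config <- function() {
  list(spd_reduce = c(down2 = 64L, down3 = 96L, down4 = 192L),
       cmk_repeats = 1L,
       p2_width = 160L)
}
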