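# Operation meter: counts work performed by the core ops during a forward
# pass, split by category so the reporting convention can be pinned once and
# stated explicitly.
#
# Categories (all counted per scalar output unless noted):
#   conv_macs    multiply-accumulates of convolutions
#   linear_macs  multiply-accumulates of dense layers and attention matmuls
#   elementwise  adds/multiplies of activations, normalizations, residuals
#   fft          complex butterfly flops of FFT-based blocks (5 N log2 N)
#   resample     multiply-accumulates of bilinear sampling / pooling

.bd_meter <- new.env(parent = emptyenv())
.bd_meter$on <- FALSE
.bd_meter$c <- c(conv_macs = 0, linear_macs = 0, elementwise = 0, fft = 0, resample = 0)

meter_reset <- function() {
  .bd_meter$c[] <- 0
  invisible()
}

meter_start <- function() { meter_reset(); .bd_meter$on <- TRUE; invisible() }
meter_stop <- function() { .bd_meter$on <- FALSE; invisible() }
meter_read <- function() .bd_meter$c

meter_add <- function(cat, n) {
  if (.bd_meter$on) .bd_meter$c[cat] <- .bd_meter$c[cat] + n
  invisible()
}
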