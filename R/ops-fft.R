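# Frequency-domain primitives.
#
# Convention (pinned, observable through magnitudes): unnormalized forward
# 2-D DFT, 1/(H*W) inverse. In R, `fft(m)` of a matrix is the unnormalized
# forward 2-D transform and `fft(m, inverse = TRUE)` the unnormalized inverse,
# so the inverse here divides by H*W.

fft2_map <- function(x) {
  d <- dim(x)
  z <- array(complex(real = 0), d)
  for (c in seq_len(d[1])) z[c, , ] <- stats::fft(array(x[c, , ], d[2:3]))
  z
}

ifft2_map <- function(z) {
  d <- dim(z)
  out <- array(complex(real = 0), d)
  for (c in seq_len(d[1])) out[c, , ] <- stats::fft(array(z[c, , ], d[2:3]), inverse = TRUE)
  out / (d[2] * d[3])
}

# Unnormalized inverse (conjugate-transpose of the forward map); used in
# backward passes.
ifft2_un <- function(z) {
  d <- dim(z)
  out <- array(complex(real = 0), d)
  for (c in seq_len(d[1])) out[c, , ] <- stats::fft(array(z[c, , ], d[2:3]), inverse = TRUE)
  out
}

#' Frequency-domain gating: `|F^-1(a * F(b))|`
#'
#' Multiplies the spectrum of `b` elementwise by the real map `a` and returns
#' the magnitude of the inverse transform. This is the core primitive of both
#' the frequency-modulation block and the frequency-channel attention: with
#' `a` constant 1 and `b >= 0` it reduces to the identity.
#'
#' Differentiable in both arguments; the gradient of the magnitude uses
#' `z/|z|` with a small floor to stay defined at zeros.
#'
#' @param a real gate map `c(C, H, W)` (spatial values applied in frequency space).
#' @param b real input map `c(C, H, W)`.
#' @return real map `c(C, H, W)`.
#' @export
ag_freq_gate <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  stopifnot(identical(dim(av), dim(bv)))
  d <- dim(av)
  S <- fft2_map(bv)
  G <- av * S
  z <- ifft2_map(G)
  y <- Mod(z)
  if (.bd_meter$on) {
    hw <- d[2] * d[3]
    meter_add("fft", 2 * d[1] * 5 * hw * log2(hw))
    meter_add("elementwise", 8 * length(y))
  }
  ag_make(y, list(a, b), function(g) {
    # dL/dz as a complex pair; |z| floor keeps the zero case finite
    ysafe <- pmax(y, 1e-12)
    gz <- complex(real = g * Re(z) / ysafe, imaginary = g * Im(z) / ysafe)
    dim(gz) <- d
    dG <- fft2_map(Re(gz)) + complex(imaginary = 1) * fft2_map(Im(gz))
    dG <- dG / (d[2] * d[3])
    da <- Re(dG * Conj(S))
    dS <- av * dG
    db <- Re(ifft2_un(dS))
    list(if (ag_is(a)) da else NULL, if (ag_is(b)) db else NULL)
  })
}
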