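#' Gaussian-tuned curve matrix (planted ensemble)
#'
#' Builds an N x F matrix of Gaussian tuning curves on the octave axis,
#' used for controlled tests of the Fisher-information and decoding
#' machinery where the true curve family is known.
#'
#' @param n number of neurons.
#' @param x log2-frequency axis.
#' @param bf_range BF interval (octaves) sampled uniformly.
#' @param width_oct Gaussian sd in octaves (scalar or range sampled
#'   uniformly).
#' @param peak_count peak mean count per window.
#' @param base_count baseline count added everywhere.
#' @param seed RNG seed.
#' @return N x F matrix of mean counts.
#' @export
gaussian_curves <- function(n, x, bf_range = range(x), width_oct = 0.5,
                            peak_count = 4, base_count = 0.05, seed = 1) {
  stopifnot(n >= 1, length(x) >= 2, peak_count >= 0, base_count >= 0)
  set.seed(seed)
  bf <- runif(n, bf_range[1], bf_range[2])
  w <- if (length(width_oct) == 2) runif(n, width_oct[1], width_oct[2])
       else rep(width_oct, n)
  t(vapply(seq_len(n), function(i)
    base_count + peak_count * exp(-0.5 * ((x - bf[i]) / w[i]) ^ 2),
    numeric(length(x))))
}

#' Flank-enhanced copy of a curve matrix
#'
#' Returns curves identical to the input for frequencies within the
#' training band plus a margin, and multiplied by a gain that ramps up
#' with octave distance beyond the margin. This steepens rate-curve slopes
#' on the band flanks while leaving in-band responses (and hence in-band
#' Fisher information) untouched - the planted "expert" structure used for
#' pattern-recovery checks.
#'
#' @param curves N x F matrix of mean counts.
#' @param x log2-frequency axis.
#' @param band_khz training band (kHz), default 7.1-10.
#' @param margin_oct octaves beyond the band edges left unchanged (default
#'   one grid step of the standard 18-tone grid).
#' @param gain_per_oct multiplicative gain slope per octave beyond the
#'   margin.
#' @return N x F matrix.
#' @export
flank_enhance <- function(curves, x, band_khz = c(7.1, 10),
                          margin_oct = 0.2198, gain_per_oct = 1) {
  curves <- as.matrix(curves)
  stopifnot(ncol(curves) == length(x), gain_per_oct >= 0)
  band <- log2(band_khz)
  dist <- pmax(band[1] - x, x - band[2], 0)
  gain <- 1 + gain_per_oct * pmax(dist - margin_oct, 0)
  sweep(curves, 2, gain, `*`)
}
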