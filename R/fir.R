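#' Design a narrowband Hamming-windowed sinc FIR filter
#'
#' Linear-phase band-pass design at the band's prescribed kernel length
#' (Hamming-windowed sinc, gain normalised to unity at the passband centre).
#'
#' @param band a [band_definition()].
#' @param fs sampling rate in Hz; must exceed `2 * f_high`.
#' @return numeric coefficient vector of length `band$fir_len`.
#' @export
design_band_fir <- function(band, fs) {
  stopifnot(inherits(band, "band_definition"))
  if (band$f_high >= fs / 2) stop("f_high must be below the Nyquist frequency")
  L <- band$fir_len
  h <- signal::fir1(L - 1L, c(band$f_low, band$f_high) * 2 / fs,
                    type = "pass", window = signal::hamming(L))
  as.numeric(h)
}

#' Design the broadband FIR filter
#'
#' Band-pass 0.75-65 Hz with asymmetric transition bandwidths (0.2 Hz at the
#' low edge, 5 Hz at the high edge). The kernel length follows the Hamming
#' window's transition-width rule (about 3.3/N in normalised frequency)
#' applied to the narrower, low-frequency transition; the rule keeps the low
#' edge sharp enough to suppress drift below 0.55 Hz while passing 0.75 Hz
#' and above.
#'
#' @param fs sampling rate in Hz; `fs/2` must exceed the 65 Hz cutoff.
#' @param f_low,f_high passband cutoffs in Hz.
#' @param trans_low,trans_high transition bandwidths in Hz at each edge.
#' @return numeric coefficient vector (odd length).
#' @export
design_broadband_fir <- function(fs, f_low = 0.75, f_high = 65,
                                 trans_low = 0.2, trans_high = 5) {
  if (fs / 2 <= f_high) stop("fs too low for the requested high cutoff")
  L <- ceiling(3.3 * fs / trans_low)
  if (L %% 2L == 0L) L <- L + 1L
  h <- signal::fir1(L - 1L, c(f_low, f_high) * 2 / fs,
                    type = "pass", window = signal::hamming(L))
  as.numeric(h)
}

#' Magnitude response of an FIR filter on a frequency grid
#'
#' @param coeffs FIR coefficient vector.
#' @param freqs frequencies in Hz at which to evaluate.
#' @param fs sampling rate in Hz.
#' @return numeric vector of magnitude responses (linear gain).
#' @export
fir_response <- function(coeffs, freqs, fs) {
  k <- seq_along(coeffs) - 1L
  vapply(freqs, function(f) {
    Mod(sum(coeffs * exp(-2i * pi * f * k / fs)))
  }, numeric(1))
}

#' Apply an FIR filter with zero net group delay
#'
#' Single-pass convolution with a symmetric (linear-phase) kernel, followed
#' by compensation of the constant group delay `(L-1)/2`: output peaks stay
#' aligned with input peaks, which keeps amplitude-envelope timing intact.
#' For even kernel lengths the residual half-sample delay is not compensated.
#' Forward-backward filtering is deliberately not used, as it would double
#' the effective filter order and hence the lower bound of the DFA scale
#' grid.
#'
#' The first and last `L` samples of the output are edge transients
#' (returned in the `transient` attribute) and should be excluded from
#' envelope statistics.
#'
#' @param rec a [recording()] (or plain numeric vector, returned as such).
#' @param coeffs FIR coefficients.
#' @return filtered recording (or vector) of identical length, with the
#'   transient half-width in samples attached as attribute `"transient"`.
#' @export
apply_zero_phase <- function(rec, coeffs) {
  L <- length(coeffs)
  filt1 <- function(x) {
    if (length(x) < 3L * L) stop("signal shorter than 3x filter length")
    full <- stats::convolve(x, rev(coeffs), type = "open")  # length n + L - 1
    d <- (L - 1L) %/% 2L
    full[(d + 1L):(d + length(x))]
  }
  if (is.numeric(rec) && is.null(dim(rec))) {
    out <- filt1(rec)
    attr(out, "transient") <- L
    return(out)
  }
  stopifnot(inherits(rec, "recording"))
  rec$data <- t(apply(rec$data, 1L, filt1))
  rownames(rec$data) <- rec$labels
  attr(rec, "transient") <- L
  rec
}

#' Downsample by an integer factor with anti-aliasing
#'
#' Applies a zero-phase FIR low-pass at 80% of the target Nyquist frequency,
#' then keeps every `fs/target_fs`-th sample.
#'
#' @param rec a [recording()].
#' @param target_fs target sampling rate in Hz; must divide `rec$fs`.
#' @return the downsampled recording with `fs = target_fs`.
#' @export
downsample <- function(rec, target_fs) {
  stopifnot(inherits(rec, "recording"))
  r <- rec$fs / target_fs
  if (abs(r - round(r)) > 1e-9) stop("target_fs must divide fs (integer decimation)")
  r <- as.integer(round(r))
  if (r == 1L) return(rec)
  L <- 20L * r + 1L
  h <- signal::fir1(L - 1L, 0.8 / r, type = "low", window = signal::hamming(L))
  rec <- apply_zero_phase(rec, as.numeric(h))
  rec$data <- rec$data[, seq(1L, ncol(rec$data), by = r), drop = FALSE]
  rec$fs <- target_fs
  attr(rec, "transient") <- NULL
  rec
}
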