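#' Frequency band definitions
#'
#' A band definition couples the passband cutoffs of a narrowband FIR filter
#' with the kernel length (in samples at the reference sampling rate) used to
#' design it. The kernel length matters beyond filter design: the minimum DFA
#' time-scale is tied to it (see [make_scale_grid()]), so it is carried along
#' with the band.
#'
#' @param name band name, one of `"theta"`, `"alpha"`, `"sigma"`, `"beta1"`,
#'   `"beta2"`, or any other label for custom bands.
#' @param f_low,f_high passband cutoffs in Hz; `0 < f_low < f_high`.
#' @param fir_len FIR kernel length in samples at the reference rate (250 Hz).
#' @return an object of class `band_definition`.
#' @export
band_definition <- function(name, f_low, f_high, fir_len) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!(f_low > 0 && f_high > f_low)) {
    stop("band cutoffs must satisfy 0 < f_low < f_high")
  }
  fir_len <- as.integer(fir_len)
  if (fir_len < 3L) stop("fir_len must be at least 3 samples")
  structure(
    list(name = name, f_low = f_low, f_high = f_high, fir_len = fir_len),
    class = "band_definition"
  )
}

#' @export
print.band_definition <- function(x, ...) {
  cat(sprintf("<band %s: %g-%g Hz, %d-tap FIR>\n",
              x$name, x$f_low, x$f_high, x$fir_len))
  invisible(x)
}

#' Default EEG frequency bands
#'
#' The five canonical wake resting-state bands with their FIR kernel lengths
#' at 250 Hz: theta 4-8 Hz (125 taps), alpha 8-12 Hz (63), sigma 12-15 Hz
#' (38), beta-1 15-22 Hz (31), beta-2 22-30 Hz (23). Kernel lengths shrink
#' with rising band frequency so that each filter spans a comparable number
#' of oscillation cycles.
#'
#' @param names optional subset of band names to return, in the given order.
#' @return a named list of [band_definition()] objects ordered from theta to
#'   beta-2 (the spectral adjacency chain used by TFCE).
#' @export
default_bands <- function(names = NULL) {
  all <- list(
    theta = band_definition("theta", 4, 8, 125L),
    alpha = band_definition("alpha", 8, 12, 63L),
    sigma = band_definition("sigma", 12, 15, 38L),
    beta1 = band_definition("beta1", 15, 22, 31L),
    beta2 = band_definition("beta2", 22, 30, 23L)
  )
  if (is.null(names)) return(all)
  missing <- setdiff(names, names(all))
  if (length(missing)) stop("unknown band(s): ", paste(missing, collapse = ", "))
  all[names]
}
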