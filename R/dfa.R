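#' Participants x electrodes x bands Hurst-exponent array
#'
#' @param h 3-d numeric array (participants x electrodes x bands) with
#'   dimnames (participant ids, electrode labels, band names).
#' @param condition `"EO"`, `"EC"` or `"NA"`.
#' @param montage optional [generate_montage()] result carried for adjacency.
#' @param bands optional list of [band_definition()]s.
#' @return an object of class `h_matrix` (the array, with attributes).
#' @export
h_matrix <- function(h, condition = "NA", montage = NULL, bands = NULL) {
  stopifnot(is.array(h), length(dim(h)) == 3L)
  if (!all(is.finite(h))) stop("h_matrix values must be finite")
  if (is.null(dimnames(h)) || any(vapply(dimnames(h), is.null, TRUE))) {
    stop("h_matrix needs full dimnames (participants, electrodes, bands)")
  }
  structure(h, condition = match.arg(condition, c("EO", "EC", "NA")),
            montage = montage, bands = bands, class = "h_matrix")
}

#' @export
print.h_matrix <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<h_matrix: %d participants x %d electrodes x %d bands, condition %s>\n",
              d[1], d[2], d[3], attr(x, "condition")))
  invisible(x)
}

#' Amplitude envelope via the analytic signal
#'
#' The amplitude envelope of a narrowband signal is the pointwise modulus of
#' its analytic signal (the signal plus i times its Hilbert transform),
#' computed here by the standard FFT construction: double the positive
#' frequencies, zero the negative ones, inverse transform.
#'
#' @param x single-channel numeric vector (or single-channel [recording()]).
#' @param fs sampling rate in Hz (taken from the recording if given one).
#' @param band optional [band_definition()] reference carried in the result.
#' @return an object of class `envelope_series` with fields `values`
#'   (non-negative), `fs` and `band`.
#' @export
hilbert_envelope <- function(x, fs = NULL, band = NULL) {
  if (inherits(x, "recording")) {
    if (nrow(x$data) != 1L) stop("hilbert_envelope expects a single channel")
    fs <- x$fs
    x <- as.numeric(x$data[1L, ])
  }
  if (!length(x)) stop("empty input")
  if (is.null(fs)) stop("fs is required for plain numeric input")
  n <- length(x)
  X <- stats::fft(x)
  w <- numeric(n)
  if (n %% 2L == 0L) {
    w[1L] <- 1; w[n / 2 + 1L] <- 1; w[2:(n / 2)] <- 2
  } else {
    w[1L] <- 1; w[2:((n + 1L) / 2)] <- 2
  }
  analytic <- stats::fft(X * w, inverse = TRUE) / n
  structure(list(values = Mod(analytic), fs = fs, band = band),
            class = "envelope_series")
}

#' Globally detrended cumulative profile
#'
#' Cumulatively sums the envelope over the recording and removes the global
#' least-squares linear trend. The DFA fluctuation function is computed on
#' this profile.
#'
#' @param env an `envelope_series` (or plain numeric vector).
#' @return numeric profile vector of the same length.
#' @export
build_profile <- function(env) {
  v <- if (inherits(env, "envelope_series")) env$values else as.numeric(env)
  if (length(v) < 2L) stop("envelope must have at least 2 samples")
  y <- cumsum(v)
  t <- seq_along(y)
  stats::lm.fit(cbind(1, t), y)$residuals
}

#' Mean RMS fluctuation at one scale
#'
#' Splits the profile into non-overlapping segments of `scale` samples
#' (forward from the first sample; the trailing partial segment is
#' discarded), removes a local least-squares polynomial trend of order
#' `poly_order` from each segment, and returns the average across segments
#' of the per-segment RMS of the residuals.
#'
#' @param profile numeric profile vector from [build_profile()].
#' @param scale segment length in samples.
#' @param poly_order local detrending polynomial order (cubic by default).
#' @return list with `fluctuation` (mean per-segment RMS) and `n_segments`.
#' @export
fluctuation_at_scale <- function(profile, scale, poly_order = 3L) {
  n <- length(profile)
  scale <- as.integer(scale)
  if (scale > n) stop("scale exceeds profile length")
  if (scale < poly_order + 2L) stop("scale too small for the detrending order")
  nseg <- n %/% scale
  m <- matrix(profile[seq_len(nseg * scale)], nrow = scale)
  t <- seq_len(scale)
  X <- stats::poly(t, degree = poly_order, raw = FALSE)
  Q <- qr.Q(qr(cbind(1, X)))
  resid <- m - Q %*% crossprod(Q, m)
  rms <- sqrt(colMeans(resid^2))
  list(fluctuation = mean(rms), n_segments = nseg)
}

#' Logarithmic DFA scale grid
#'
#' Twenty log-spaced time-scales between a minimum of eight times the
#' band's FIR kernel duration (below which filter-induced short-range
#' autocorrelations would bias the scaling fit) and a maximum of one
#' eighth of the record length (above which fewer than 8 segments remain).
#' Exact log-spaced values are floored to integer sample counts;
#' duplicates after rounding are collapsed with a warning.
#'
#' @param band a [band_definition()].
#' @param fs sampling rate in Hz.
#' @param n_samples record length in samples.
#' @param n_scales number of scales before deduplication.
#' @return object of class `scale_grid`: `scales` (integer samples),
#'   `min_scale` and `max_scale` (seconds).
#' @export
make_scale_grid <- function(band, fs, n_samples, n_scales = 20L) {
  stopifnot(inherits(band, "band_definition"))
  smin <- 8 * band$fir_len
  smax <- n_samples / 8
  if (smin >= smax) {
    stop(sprintf("record too short for band %s: needs > %d samples",
                 band$name, 64L * band$fir_len))
  }
  exact <- exp(seq(log(smin), log(smax), length.out = n_scales))
  scales <- as.integer(floor(exact))
  if (anyDuplicated(scales)) {
    warning("scale grid contains duplicates after integer rounding; collapsed")
    scales <- unique(scales)
  }
  structure(list(scales = scales, min_scale = smin / fs, max_scale = smax / fs,
                 exact = exact, fs = fs),
            class = "scale_grid")
}

#' @export
print.scale_grid <- function(x, ...) {
  cat(sprintf("<scale_grid: %d scales, %.3g-%.3g s>\n",
              length(x$scales), x$min_scale, x$max_scale))
  invisible(x)
}

#' Estimate the Hurst exponent of an amplitude envelope by DFA
#'
#' Computes the mean RMS fluctuation at every scale of the grid and fits an
#' unweighted least-squares line to log10(fluctuation) versus log10(scale);
#' the slope is the Hurst exponent H. H = 0.5 indicates an uncorrelated
#' (random) process, 0.5 < H < 1 persistent positive autocorrelations
#' (LRTC), H > 1 non-stationarity.
#'
#' @param env an `envelope_series` (or numeric vector).
#' @param grid a [make_scale_grid()] result.
#' @param poly_order local detrending order.
#' @return object of class `dfa_result`: `hurst`, `intercept`, `fit_r2`,
#'   `scales`, `fluctuations`, `n_segments`.
#' @export
estimate_hurst <- function(env, grid, poly_order = 3L) {
  stopifnot(inherits(grid, "scale_grid"))
  v <- if (inherits(env, "envelope_series")) env$values else as.numeric(env)
  if (stats::sd(v) == 0) stop("degenerate DFA fit: constant envelope")
  profile <- build_profile(v)
  fl <- lapply(grid$scales, function(s) fluctuation_at_scale(profile, s, poly_order))
  f <- vapply(fl, `[[`, numeric(1), "fluctuation")
  nseg <- vapply(fl, `[[`, integer(1), "n_segments")
  if (any(f <= 0)) {
    stop(sprintf("degenerate DFA fit: non-positive fluctuation at scale %d samples",
                 grid$scales[which(f <= 0)[1L]]))
  }
  lx <- log10(grid$scales)
  ly <- log10(f)
  fit <- stats::lm.fit(cbind(1, lx), ly)
  r2 <- 1 - sum(fit$residuals^2) / sum((ly - mean(ly))^2)
  structure(list(hurst = unname(fit$coefficients[2L]),
                 intercept = unname(fit$coefficients[1L]),
                 fit_r2 = r2, scales = grid$scales, fluctuations = f,
                 n_segments = nseg),
            class = "dfa_result")
}

#' @export
print.dfa_result <- function(x, ...) {
  cat(sprintf("<dfa_result: H = %.3f (R2 = %.3f, %d scales)>\n",
              x$hurst, x$fit_r2, length(x$scales)))
  invisible(x)
}

#' Hurst exponent of one channel in one band
#'
#' Convenience wrapper for the single-channel chain: band-pass filter,
#' edge-transient trim, Hilbert envelope, DFA over the band's scale grid.
#'
#' @param x numeric vector or single-channel [recording()].
#' @param band a [band_definition()].
#' @param fs sampling rate (taken from the recording if given one).
#' @param trim_edges drop the filter-length transient at each end.
#' @return a `dfa_result`.
#' @export
estimate_band_hurst <- function(x, band, fs = NULL, trim_edges = TRUE) {
  if (inherits(x, "recording")) {
    fs <- x$fs
    x <- as.numeric(x$data[1L, ])
  }
  if (is.null(fs)) stop("fs is required for plain numeric input")
  xf <- apply_zero_phase(x, design_band_fir(band, fs))
  if (trim_edges) {
    L <- band$fir_len
    xf <- xf[(L + 1L):(length(xf) - L)]
  }
  env <- hilbert_envelope(xf, fs, band = band)
  estimate_hurst(env, make_scale_grid(band, fs, length(env$values)))
}

#' Hurst exponents for a cohort of recordings
#'
#' Runs the full chain — band filter, Hilbert envelope (edge transients
#' trimmed), DFA over the band's scale grid — for every participant,
#' electrode and band.
#'
#' @param recordings named list of [recording()]s with identical `fs` and
#'   labels; names are participant ids.
#' @param bands list of [band_definition()]s.
#' @param montage optional montage carried into the result.
#' @param condition condition tag for the result (defaults to the first
#'   recording's).
#' @param trim_edges drop the filter-length transient at each end of the
#'   envelope before DFA.
#' @return an [h_matrix()] of shape participants x electrodes x bands.
#' @export
compute_h_matrix <- function(recordings, bands, montage = NULL,
                             condition = NULL, trim_edges = TRUE) {
  stopifnot(length(recordings) >= 1L)
  fs <- recordings[[1L]]$fs
  labels <- recordings[[1L]]$labels
  for (r in recordings) {
    if (r$fs != fs || !identical(r$labels, labels)) {
      stop("recordings must share fs and electrode labels")
    }
  }
  if (is.null(condition)) condition <- recordings[[1L]]$condition
  ids <- names(recordings)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_along(recordings))
  band_names <- vapply(bands, `[[`, "", "name")
  coeffs <- lapply(bands, design_band_fir, fs = fs)
  n <- ncol(recordings[[1L]]$data)
  grids <- lapply(bands, function(b) {
    ntrim <- if (trim_edges) n - 2L * b$fir_len else n
    make_scale_grid(b, fs, ntrim)
  })
  h <- array(NA_real_, dim = c(length(ids), length(labels), length(bands)),
             dimnames = list(ids, labels, band_names))
  for (p in seq_along(recordings)) {
    for (e in seq_along(labels)) {
      x <- as.numeric(recordings[[p]]$data[e, ])
      for (b in seq_along(bands)) {
        res <- tryCatch({
          xf <- apply_zero_phase(x, coeffs[[b]])
          if (trim_edges) {
            L <- bands[[b]]$fir_len
            xf <- xf[(L + 1L):(length(xf) - L)]
          }
          env <- hilbert_envelope(xf, fs, band = bands[[b]])
          estimate_hurst(env, grids[[b]])
        }, error = function(err) {
          stop(sprintf("DFA failed for participant %s, electrode %s, band %s: %s",
                       ids[p], labels[e], band_names[b], conditionMessage(err)),
               call. = FALSE)
        })
        h[p, e, b] <- res$hurst
      }
    }
  }
  h_matrix(h, condition = condition, montage = montage, bands = bands)
}

#' Grand-median Hurst exponent per participant
#'
#' Median over the whole electrode x band plane, the aggregated LRTC
#' measure used for the cohort-level general linear model.
#'
#' @param hm an [h_matrix()].
#' @return named numeric vector, one value per participant.
#' @export
grand_median_h <- function(hm) {
  stopifnot(inherits(hm, "h_matrix"))
  apply(unclass(hm), 1L, stats::median)
}

#' Per-band median Hurst exponent across electrodes
#'
#' @param hm an [h_matrix()].
#' @return participants x bands numeric matrix.
#' @export
band_median_h <- function(hm) {
  stopifnot(inherits(hm, "h_matrix"))
  apply(unclass(hm), c(1L, 3L), stats::median)
}
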