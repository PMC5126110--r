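#' Multichannel EEG recording container
#'
#' @param data numeric matrix, channels x samples.
#' @param fs sampling rate in Hz.
#' @param labels character vector of electrode labels, one per channel.
#' @param condition recording condition: `"EO"` (eyes open), `"EC"` (eyes
#'   closed) or `"NA"`.
#' @return an object of class `recording`.
#' @export
recording <- function(data, fs, labels = NULL, condition = "NA") {
  if (is.vector(data)) data <- matrix(data, nrow = 1L)
  stopifnot(is.matrix(data), is.numeric(data))
  if (!all(is.finite(data))) stop("recording data must be finite")
  if (!(is.numeric(fs) && length(fs) == 1L && fs > 0)) stop("fs must be a positive scalar")
  if (is.null(labels)) labels <- sprintf("E%03d", seq_len(nrow(data)))
  if (length(labels) != nrow(data)) stop("labels length must equal channel count")
  if (anyDuplicated(labels)) stop("labels must be unique")
  condition <- match.arg(condition, c("EO", "EC", "NA"))
  rownames(data) <- labels
  structure(list(data = data, fs = fs, labels = labels, condition = condition),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording: %d channel(s) x %d samples @ %g Hz (%.1f s), condition %s>\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs, x$condition))
  invisible(x)
}

n_samples <- function(rec) ncol(rec$data)

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' that at every sample the channel mean is zero.
#'
#' @param rec a [recording()] with at least two channels.
#' @return the re-referenced recording.
#' @export
common_average_reference <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  if (nrow(rec$data) < 2L) stop("common average reference needs >= 2 channels")
  rec$data <- sweep(rec$data, 2L, colMeans(rec$data))
  rec
}

#' Crop a time segment
#'
#' Extracts an exact sample-count slice `[start, start + duration)` from a
#' recording, preserving metadata. The analysis convention is to estimate
#' LRTC over the first 3 minutes (`start = 0`, `duration = 180`).
#'
#' @param rec a [recording()].
#' @param start segment start in seconds from the beginning.
#' @param duration segment length in seconds.
#' @return the cropped recording.
#' @export
crop_segment <- function(rec, start, duration) {
  stopifnot(inherits(rec, "recording"), start >= 0, duration > 0)
  i0 <- round(start * rec$fs) + 1L
  n <- round(duration * rec$fs)
  if (i0 + n - 1L > n_samples(rec)) {
    stop(sprintf("requested segment [%g, %g) s exceeds recording length %.3f s",
                 start, start + duration, n_samples(rec) / rec$fs))
  }
  rec$data <- rec$data[, i0:(i0 + n - 1L), drop = FALSE]
  rec
}
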