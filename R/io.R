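#' Write a recording as a delimited matrix with a JSON sidecar
#'
#' Tab-separated channels x samples matrix (one row per channel, no
#' header) plus `<path>.json` holding `fs`, `labels` and `condition`.
#'
#' @param rec a [recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording_delimited <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  utils::write.table(format(rec$data, digits = 10, trim = TRUE, scientific = TRUE),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(list(fs = rec$fs, labels = rec$labels,
                            condition = rec$condition),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a recording from EDF or a delimited matrix
#'
#' Delimited input expects a channels x samples numeric matrix and a
#' `<path>.json` sidecar with `fs`, `labels` and optionally `condition`.
#' EDF input honours the per-signal sampling rates and labels of the
#' standard 256-byte-header 16-bit format and requires all channels to
#' share one rate.
#'
#' @param path input file.
#' @param format `"delimited"` or `"edf"`; guessed from the extension by
#'   default.
#' @return a [recording()].
#' @export
read_recording <- function(path, format = c("auto", "delimited", "edf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "delimited"
  }
  if (format == "edf") return(read_edf(path))
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing sidecar metadata file: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  dat <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(dat) <- NULL
  recording(dat, fs = meta$fs, labels = meta$labels,
            condition = if (is.null(meta$condition)) "NA" else meta$condition)
}

#' Write a recording as 16-bit EDF
#'
#' Minimal single-record European Data Format writer: one data record
#' holding the whole signal, 16-bit samples scaled to each channel's
#' physical range.
#'
#' @param rec a [recording()].
#' @param path output `.edf` file.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  ns <- nrow(rec$data)
  nsamp <- ncol(rec$data)
  dur <- nsamp / rec$fs
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8), pad("synthetic", 80), pad("synthetic recording", 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(256 + 256 * ns, 8), pad("", 44), pad(1, 8),
    pad(format(dur, nsmall = 0), 8), pad(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  # integer physical limits keep the 8-character header fields exact
  phys_min <- floor(apply(rec$data, 1L, min))
  phys_max <- ceiling(apply(rec$data, 1L, max))
  same <- phys_max - phys_min < 1
  phys_max[same] <- phys_min[same] + 1
  field <- function(vals, w) paste0(vapply(vals, pad, "", w = w), collapse = "")
  writeChar(paste0(
    field(rec$labels, 16), field(rep("", ns), 80), field(rep("uV", ns), 8),
    field(format(phys_min, scientific = FALSE, trim = TRUE), 8),
    field(format(phys_max, scientific = FALSE, trim = TRUE), 8),
    field(rep(-32768L, ns), 8), field(rep(32767L, ns), 8),
    field(rep("", ns), 80), field(rep(nsamp, ns), 8), field(rep("", ns), 32)
  ), con, eos = NULL)
  for (ch in seq_len(ns)) {
    scaled <- (rec$data[ch, ] - phys_min[ch]) / (phys_max[ch] - phys_min[ch])
    dig <- as.integer(round(scaled * 65535 - 32768))
    writeBin(dig, con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read a 16-bit EDF file
#'
#' @param path an `.edf` file.
#' @param condition condition tag to attach.
#' @return a [recording()].
#' @export
read_edf <- function(path, condition = "NA") {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 256) stop("not an EDF file (too short): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                  # header bytes (recomputed below)
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L) stop("malformed EDF header: bad signal count")
  if (sz < 256 + 256 * ns) stop("truncated EDF header: ", path)
  rdv <- function(w) vapply(seq_len(ns), function(i) trimws(readChar(con, w, useBytes = TRUE)), "")
  labels <- rdv(16); rdv(80); rdv(8)
  phys_min <- as.numeric(rdv(8)); phys_max <- as.numeric(rdv(8))
  dig_min <- as.numeric(rdv(8)); dig_max <- as.numeric(rdv(8))
  rdv(80)
  nsamp <- as.integer(rdv(8)); rdv(32)
  if (length(unique(nsamp / dur)) != 1L) {
    stop("channels have inconsistent sampling rates")
  }
  need <- 256 + 256 * ns + 2 * n_rec * sum(nsamp)
  if (sz < need) stop("truncated EDF data section: ", path)
  dat <- matrix(NA_real_, nrow = ns, ncol = nsamp[1] * n_rec)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = nsamp[ch], size = 2L,
                     endian = "little", signed = TRUE)
      phys <- phys_min[ch] + (dig - dig_min[ch]) *
        (phys_max[ch] - phys_min[ch]) / (dig_max[ch] - dig_min[ch])
      dat[ch, ((r - 1) * nsamp[ch] + 1):(r * nsamp[ch])] <- phys
    }
  }
  recording(dat, fs = nsamp[1] / dur, labels = labels, condition = condition)
}

#' Write an H matrix as long-format TSV
#'
#' Columns: participant, electrode, band, condition, h.
#'
#' @param hm an [h_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_h_matrix <- function(hm, path) {
  stopifnot(inherits(hm, "h_matrix"))
  dn <- dimnames(hm)
  long <- expand.grid(participant = dn[[1]], electrode = dn[[2]],
                      band = dn[[3]], stringsAsFactors = FALSE)
  long$condition <- attr(hm, "condition")
  long$h <- as.numeric(unclass(hm))
  utils::write.table(long, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an H matrix from long-format TSV
#'
#' @param path a file written by [write_h_matrix()].
#' @return an [h_matrix()] (without montage/band attributes).
#' @export
read_h_matrix <- function(path) {
  long <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  ids <- unique(long$participant)
  electrodes <- unique(long$electrode)
  bands <- unique(long$band)
  h <- array(NA_real_, dim = c(length(ids), length(electrodes), length(bands)),
             dimnames = list(ids, electrodes, bands))
  h[cbind(match(long$participant, ids), match(long$electrode, electrodes),
          match(long$band, bands))] <- long$h
  h_matrix(h, condition = long$condition[1])
}

#' Write a cohort table as TSV
#' @param cohort cohort data frame (id, group, isi, age, sex).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort table from TSV
#' @param path a file written by [write_cohort()].
#' @return data frame with `group` as a CTRL/ID factor.
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.table(path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
  cohort$group <- factor(cohort$group, levels = c("CTRL", "ID"))
  cohort
}

#' Write a montage (positions + adjacency edge list) as TSV
#'
#' Writes `<path>` with columns label, x, y and `<path>.edges` with
#' columns from, to (each undirected edge once).
#'
#' @param montage a [generate_montage()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_montage <- function(montage, path) {
  stopifnot(inherits(montage, "sensor_montage"))
  utils::write.table(
    data.frame(label = montage$labels,
               x = montage$positions[, 1], y = montage$positions[, 2]),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  idx <- which(montage$adjacency & upper.tri(montage$adjacency), arr.ind = TRUE)
  utils::write.table(
    data.frame(from = montage$labels[idx[, 1]], to = montage$labels[idx[, 2]]),
    paste0(path, ".edges"), sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
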