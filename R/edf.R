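# Minimal European Data Format (EDF) I/O: continuous multichannel signals,
# 16-bit integer storage with per-channel physical scaling, 1-second data
# records. Covers plain EDF only (no EDF+ annotations).

edf_pad <- function(s, width) {
  s <- substr(s, 1L, width)
  paste0(s, strrep(" ", width - nchar(s)))
}

edf_num <- function(x, width) edf_pad(formatC(x, format = "fg", width = 1L, digits = 7), width)

#' Write a continuous recording to an EDF file
#'
#' Signals are stored as 16-bit integers in 1-second records; the recording is
#' zero-padded to a whole number of records.
#'
#' @param continuous numeric matrix `[n_channels x n_samples]` in microvolts.
#' @param fs sampling rate in Hz (must be a positive integer).
#' @param path output file path.
#' @param channel_names optional channel names (16 characters max each).
#' @return `path`, invisibly.
#' @export
write_edf <- function(continuous, fs, path, channel_names = NULL) {
  if (!is.matrix(continuous)) stop("`continuous` must be a channels x samples matrix")
  if (fs != round(fs) || fs <= 0) stop("`fs` must be a positive integer for EDF export")
  ns <- nrow(continuous)
  channel_names <- channel_names %||% rownames(continuous) %||% paste0("ch", seq_len(ns))
  n_rec <- ceiling(ncol(continuous) / fs)
  if (ncol(continuous) < n_rec * fs) {
    continuous <- cbind(continuous, matrix(0, ns, n_rec * fs - ncol(continuous)))
  }
  pmax_ <- apply(abs(continuous), 1L, max)
  pmax_[pmax_ < 1e-9] <- 1
  dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256L + 256L * ns
  writeChar(paste0(
    edf_pad("0", 8L), edf_pad("synthetic subject", 80L), edf_pad("mistack export", 80L),
    edf_pad("01.01.00", 8L), edf_pad("00.00.00", 8L), edf_num(hdr_bytes, 8L),
    edf_pad("", 44L), edf_num(n_rec, 8L), edf_num(1, 8L), edf_num(ns, 4L)
  ), con, eos = NULL)
  fields <- c(
    vapply(channel_names, edf_pad, "", width = 16L),
    rep(edf_pad("", 80L), ns),
    rep(edf_pad("uV", 8L), ns),
    vapply(-pmax_, edf_num, "", width = 8L),
    vapply(pmax_, edf_num, "", width = 8L),
    rep(edf_num(-dmax, 8L), ns),
    rep(edf_num(dmax, 8L), ns),
    rep(edf_pad("", 80L), ns),
    rep(edf_num(fs, 8L), ns),
    rep(edf_pad("", 32L), ns)
  )
  writeChar(paste(fields, collapse = ""), con, eos = NULL)
  gain <- dmax / pmax_
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- as.integer(round(continuous[ch, cols] * gain[ch]))
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read a continuous recording from an EDF file
#'
#' @param path EDF file path.
#' @return list with `data` (channels x samples matrix, physical units),
#'   `fs` (Hz) and `channel_names`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256L, useBytes = TRUE)
  if (nchar(hdr, type = "bytes") < 256L) stop("malformed EDF header: file too short")
  num <- function(s) {
    v <- suppressWarnings(as.numeric(trimws(s)))
    if (is.na(v)) stop("malformed EDF header field: '", trimws(s), "'")
    v
  }
  n_rec <- num(substr(hdr, 237L, 244L))
  rec_dur <- num(substr(hdr, 245L, 252L))
  ns <- as.integer(num(substr(hdr, 253L, 256L)))
  if (ns < 1L || n_rec < 1L || rec_dur <= 0) stop("malformed EDF header: bad record geometry")
  sig_hdr <- readChar(con, 256L * ns, useBytes = TRUE)
  fld <- function(offset, width) {
    start <- offset * ns
    vapply(seq_len(ns), function(i) {
      substr(sig_hdr, start + (i - 1L) * width + 1L, start + i * width)
    }, "")
  }
  labels <- trimws(fld(0L, 16L))
  pmin_ <- vapply(fld(16L + 80L + 8L, 8L), num, 0)
  pmax_ <- vapply(fld(16L + 80L + 8L + 8L, 8L), num, 0)
  dmin <- vapply(fld(16L + 80L + 8L + 16L, 8L), num, 0)
  dmax <- vapply(fld(16L + 80L + 8L + 24L, 8L), num, 0)
  nspr <- vapply(fld(216L, 8L), num, 0)
  pmin_ <- unname(pmin_); pmax_ <- unname(pmax_)
  dmin <- unname(dmin); dmax <- unname(dmax); nspr <- unname(nspr)
  if (length(unique(nspr)) != 1L) stop("channels with differing sampling rates are not supported")
  fs <- nspr[1L] / rec_dur
  data <- matrix(0, ns, n_rec * nspr[1L])
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = nspr[ch], size = 2L, endian = "little")
      if (length(dig) < nspr[ch]) stop("malformed EDF: truncated data record ", r)
      cols <- ((r - 1L) * nspr[ch] + 1L):(r * nspr[ch])
      data[ch, cols] <- pmin_[ch] + (dig - dmin[ch]) * gain[ch]
    }
  }
  rownames(data) <- labels
  list(data = data, fs = fs, channel_names = labels)
}
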