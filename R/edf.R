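# Minimal EDF (European Data Format) reader/writer for continuous
# multichannel recordings: 16-bit samples, identical sampling rate for
# all signals, no annotations.  Covers the interchange need of this
# package; it is not a general EDF+ implementation.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width)
}

#' Write / read an EEG signal in EDF
#'
#' @param x an `eeg_signal`.
#' @param path file path.
#' @param record_s data-record duration in seconds; the default writes
#'   the whole segment as a single record.
#' @return `write_edf` returns `path` invisibly; `read_edf` returns an
#'   `eeg_signal`.  Amplitudes are quantized to the 16-bit EDF grid.
#' @export
write_edf <- function(x, path, record_s = NULL) {
  stopifnot(inherits(x, "eeg_signal"))
  p <- nrow(x$data)
  T <- ncol(x$data)
  if (is.null(record_s)) record_s <- T / x$fs
  spr <- round(record_s * x$fs)
  if (spr < 1L || T %% spr != 0L)
    stop("record_s must divide the segment evenly")
  nrec <- T %/% spr
  pmin_ <- apply(x$data, 1L, min)
  pmax_ <- apply(x$data, 1L, max)
  flat <- pmax_ - pmin_ == 0
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768L
  dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  wrt <- function(s, w) writeChar(.edf_pad(s, w), con, nchars = w, eos = NULL)
  wrt("0", 8L)
  wrt("X X X X", 80L)
  wrt("Startdate X X X X", 80L)
  wrt("01.01.00", 8L); wrt("00.00.00", 8L)
  wrt(256L * (1L + p), 8L)
  wrt("", 44L)
  wrt(nrec, 8L)
  wrt(format(record_s, digits = 8), 8L)
  wrt(p, 4L)
  for (l in x$labels) wrt(l, 16L)
  for (i in seq_len(p)) wrt("", 80L)
  for (i in seq_len(p)) wrt("uV", 8L)
  for (v in pmin_) wrt(format(v, digits = 7), 8L)
  for (v in pmax_) wrt(format(v, digits = 7), 8L)
  for (i in seq_len(p)) wrt(dmin, 8L)
  for (i in seq_len(p)) wrt(dmax, 8L)
  for (i in seq_len(p)) wrt("", 80L)
  for (i in seq_len(p)) wrt(spr, 8L)
  for (i in seq_len(p)) wrt("", 32L)
  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(nrec)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    for (ch in seq_len(p)) {
      dig <- round((x$data[ch, cols] - pmin_[ch]) * scale[ch]) + dmin
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2L,
               endian = "little")
    }
  }
  invisible(path)
}

#' @rdname write_edf
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  ver <- rd(8L)
  if (ver != "0") stop("not an EDF file (version field '", ver, "')")
  rd(80L); rd(80L); rd(8L); rd(8L)
  rd(8L)                      # header bytes
  rd(44L)
  nrec <- as.integer(rd(8L))
  record_s <- as.numeric(rd(8L))
  p <- as.integer(rd(4L))
  labels <- vapply(seq_len(p), function(i) rd(16L), character(1L))
  for (i in seq_len(p)) rd(80L)
  for (i in seq_len(p)) rd(8L)
  pmin_ <- vapply(seq_len(p), function(i) as.numeric(rd(8L)), numeric(1L))
  pmax_ <- vapply(seq_len(p), function(i) as.numeric(rd(8L)), numeric(1L))
  dmin <- vapply(seq_len(p), function(i) as.numeric(rd(8L)), numeric(1L))
  dmax <- vapply(seq_len(p), function(i) as.numeric(rd(8L)), numeric(1L))
  for (i in seq_len(p)) rd(80L)
  spr <- vapply(seq_len(p), function(i) as.integer(rd(8L)), integer(1L))
  for (i in seq_len(p)) rd(32L)
  if (length(unique(spr)) != 1L)
    stop("mixed per-signal sampling rates are not supported")
  if (!is.finite(record_s) || record_s <= 0) stop("missing record duration")
  fs <- spr[1L] / record_s
  data <- matrix(0, p, nrec * spr[1L])
  for (r in seq_len(nrec)) {
    cols <- ((r - 1L) * spr[1L] + 1L):(r * spr[1L])
    for (ch in seq_len(p)) {
      dig <- readBin(con, integer(), n = spr[ch], size = 2L, signed = TRUE,
                     endian = "little")
      data[ch, cols] <- (dig - dmin[ch]) *
        (pmax_[ch] - pmin_[ch]) / (dmax[ch] - dmin[ch]) + pmin_[ch]
    }
  }
  eeg_signal(data, fs = fs, labels = labels)
}
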