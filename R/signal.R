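# Multichannel signal container and delimited-text I/O.

#' Multichannel EEG signal
#'
#' Container for a p-channel EEG segment sampled on a uniform grid.
#' The data matrix is stored channels-by-samples (p x T), the convention
#' used throughout this package for signals, lead fields and IMFs.
#'
#' @param data numeric matrix, p channels x T samples (microvolts), or a
#'   numeric vector for a single channel.
#' @param fs sampling rate in Hz (> 0).
#' @param t0 time of the first sample in seconds.
#' @param labels character vector of unique channel identifiers; defaults
#'   to `"ch1" ... "chp"`.
#' @return An object of class `eeg_signal`: a list with elements `data`,
#'   `fs`, `t0` and `labels`.
#' @examples
#' t <- seq(0, 1, by = 1 / 200)
#' y <- eeg_signal(rbind(sin(2 * pi * 10 * t), cos(2 * pi * 10 * t)), fs = 200)
#' y
#' @export
eeg_signal <- function(data, fs, t0 = 0, labels = NULL) {
  if (is.vector(data)) data <- matrix(data, nrow = 1L)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (ncol(data) < 4L) stop("need at least 4 samples")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive scalar")
  if (!all(is.finite(data))) stop("signal values must all be finite")
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  labels <- as.character(labels)
  if (length(labels) != nrow(data)) stop("one label per channel required")
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  rownames(data) <- labels
  structure(list(data = data, fs = fs, t0 = t0, labels = labels),
            class = "eeg_signal")
}

#' @export
print.eeg_signal <- function(x, ...) {
  cat(sprintf("<eeg_signal> %d channel(s) x %d samples @ %g Hz (%.3f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat(" channels:", paste(utils::head(x$labels, 8L), collapse = ", "),
      if (length(x$labels) > 8L) "..." else "", "\n")
  invisible(x)
}

#' Time axis of a signal
#'
#' @param x an `eeg_signal`.
#' @return numeric vector of sample times in seconds.
#' @export
signal_times <- function(x) {
  stopifnot(inherits(x, "eeg_signal"))
  x$t0 + (seq_len(ncol(x$data)) - 1L) / x$fs
}

#' Write / read a multichannel signal as delimited text
#'
#' The format is tab-separated: a comment line carrying the sampling
#' metadata (`# memdeeg-eeg fs=<Hz> t0=<s>`), then one row per channel
#' whose first field is the channel label followed by the T sample values.
#'
#' @param x an `eeg_signal`.
#' @param path file path.
#' @return `write_eeg` returns `path` invisibly; `read_eeg` returns an
#'   `eeg_signal`.
#' @export
write_eeg <- function(x, path) {
  stopifnot(inherits(x, "eeg_signal"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# memdeeg-eeg fs=%.17g t0=%.17g", x$fs, x$t0), con)
  utils::write.table(
    data.frame(label = x$labels, x$data, check.names = FALSE),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_eeg
#' @export
read_eeg <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!grepl("^# memdeeg-eeg ", hdr))
    stop("not a memdeeg delimited EEG file (missing metadata line): ", path)
  fs <- .meta_field(hdr, "fs")
  t0 <- .meta_field(hdr, "t0")
  if (!is.finite(fs)) stop("missing fs metadata in ", path)
  tab <- utils::read.table(path, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  labels <- as.character(tab[[1L]])
  data <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(data)) stop("non-numeric sample values in ", path)
  eeg_signal(data, fs = fs, t0 = if (is.finite(t0)) t0 else 0, labels = labels)
}

.meta_field <- function(line, key) {
  m <- regmatches(line, regexec(paste0(key, "=([-+0-9.eE]+)"), line))[[1L]]
  if (length(m) < 2L) return(NA_real_)
  as.numeric(m[2L])
}
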