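#' Construct an EEGRecording
#'
#' @param data numeric matrix, one row per channel, columns = time samples.
#' @param fs sampling rate in Hz.
#' @param channels character vector of channel names; defaults to rownames
#'   of \code{data} or, for 10-row matrices, the canonical montage.
#' @param subjectId subject identifier.
#' @param label class label: 0 (normal), 1 (PD) or NA (unknown).
#' @param canonical if TRUE, require the channel list to be exactly the
#'   canonical 10-channel montage in canonical order.
#' @return An \linkS4class{EEGRecording}.
#' @examples
#' rec <- eegRecording(matrix(rnorm(20), nrow = 2), fs = 250,
#'                     channels = c("C3", "C4"))
#' nSamples(rec)
#' @export
eegRecording <- function(data, fs, channels = NULL, subjectId = "s1",
                         label = NA, canonical = FALSE) {
  data <- as.matrix(data)
  if (is.null(channels)) {
    channels <- rownames(data)
    if (is.null(channels) && nrow(data) == length(CANONICAL_CHANNELS))
      channels <- CANONICAL_CHANNELS
  }
  if (is.null(channels))
    stop("channel names are required")
  if (canonical && !identical(as.character(channels), CANONICAL_CHANNELS))
    stop("canonical layout requires channels exactly ",
         paste(CANONICAL_CHANNELS, collapse = ", "), " in that order")
  if (length(channels) != nrow(data))
    stop("length(channels) must equal nrow(data)")
  rownames(data) <- channels
  new("EEGRecording", subjectId = as.character(subjectId),
      label = if (is.na(label)) NA_integer_ else as.integer(label),
      fs = as.numeric(fs), channels = as.character(channels), data = data)
}

#' @describeIn eegRecording TRUE if the recording uses the canonical
#'   10-channel montage in canonical order.
#' @param rec an EEGRecording.
#' @export
isCanonicalLayout <- function(rec) {
  identical(channelNames(rec), CANONICAL_CHANNELS)
}

#' Accessors for EEGRecording
#'
#' @param x an \linkS4class{EEGRecording}.
#' @return \code{channelNames}: character vector; \code{samplingRate}:
#'   numeric Hz; \code{nSamples}: integer; \code{signalMatrix}: the
#'   channels x samples matrix; \code{subjectLabel}: integer 0/1/NA.
#' @name EEGRecording-accessors
NULL

#' @rdname EEGRecording-accessors
#' @export
channelNames <- function(x) x@channels

#' @rdname EEGRecording-accessors
#' @export
samplingRate <- function(x) x@fs

#' @rdname EEGRecording-accessors
#' @export
nSamples <- function(x) ncol(x@data)

#' @rdname EEGRecording-accessors
#' @export
signalMatrix <- function(x) x@data

#' @rdname EEGRecording-accessors
#' @export
subjectLabel <- function(x) x@label

setMethod("show", "EEGRecording", function(object) {
  lab <- if (is.na(object@label)) "unknown"
         else if (object@label == 0L) "normal (0)" else "PD (1)"
  cat("EEGRecording", object@subjectId, "\n",
      sprintf("  %d channels x %d samples at %g Hz (%.1f s), label: %s\n",
              length(object@channels), ncol(object@data), object@fs,
              ncol(object@data) / object@fs, lab))
  cat("  channels:", paste(object@channels, collapse = " "), "\n")
})

.parseLabel <- function(tok) {
  tok <- tolower(trimws(tok))
  if (tok %in% c("0", "normal")) return(0L)
  if (tok %in% c("1", "pd"))     return(1L)
  if (tok %in% c("na", "unknown", "")) return(NA_integer_)
  stop("unknown label token: '", tok, "'")
}

#' Read an EEG recording from the package CSV dialect
#'
#' The dialect: '#'-prefixed \code{key=value} metadata lines (fs is
#' mandatory; subject_id and label optional), then a header row of channel
#' names, then one time sample per row, comma-separated, '.' decimal.
#'
#' @param path file to read.
#' @param canonical require the canonical 10-channel montage.
#' @return An \linkS4class{EEGRecording}.
#' @seealso [writeRecordingCSV()]
#' @export
readRecordingCSV <- function(path, canonical = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  metaIdx <- grep("^#", lines)
  meta <- list()
  for (ln in lines[metaIdx]) {
    kv <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0)
      meta[[trimws(substr(kv, 1, eq - 1))]] <- trimws(substr(kv, eq + 1, nchar(kv)))
  }
  if (is.null(meta$fs))
    stop("metadata line '# fs=<Hz>' is required in ", path)
  fs <- suppressWarnings(as.numeric(meta$fs))
  if (is.na(fs) || fs <= 0) stop("invalid fs metadata: '", meta$fs, "'")

  body <- lines[setdiff(seq_along(lines), metaIdx)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L) stop("file has no data rows: ", path)
  channels <- trimws(strsplit(body[1], ",", fixed = TRUE)[[1]])
  nch <- length(channels)
  rows <- strsplit(body[-1], ",", fixed = TRUE)
  nfield <- lengths(rows)
  if (any(nfield != nch)) {
    bad <- which(nfield != nch)[1]
    stop(sprintf("ragged row %d: %d fields, expected %d", bad + 1L,
                 nfield[bad], nch))
  }
  vals <- suppressWarnings(as.numeric(unlist(rows, use.names = FALSE)))
  if (anyNA(vals)) {
    flat <- which(is.na(vals))[1] - 1L
    stop(sprintf("malformed numeric cell at data row %d, column %d (%s)",
                 flat %/% nch + 1L, flat %% nch + 1L,
                 channels[flat %% nch + 1L]))
  }
  # file stores samples as rows; filling column-major puts channels in rows
  data <- matrix(vals, nrow = nch)
  eegRecording(data, fs = fs, channels = channels,
               subjectId = if (is.null(meta$subject_id)) "s1" else meta$subject_id,
               label = if (is.null(meta$label)) NA else .parseLabel(meta$label),
               canonical = canonical)
}

#' Write an EEG recording in the package CSV dialect
#'
#' Values are written with 15 significant digits so a read/write round
#' trip is lossless to within double round-off.
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @seealso [readRecordingCSV()]
#' @export
writeRecordingCSV <- function(rec, path) {
  stopifnot(is(rec, "EEGRecording"))
  validObject(rec)
  if (length(rec@channels) == 0L) stop("recording has no channels")
  lab <- if (is.na(rec@label)) "unknown" else as.character(rec@label)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# fs=", format(rec@fs, digits = 15)),
               paste0("# subject_id=", rec@subjectId),
               paste0("# label=", lab),
               paste(rec@channels, collapse = ",")), con)
  m <- t(rec@data)  # samples as rows
  txt <- apply(format(m, digits = 15, scientific = TRUE, trim = TRUE), 1,
               paste, collapse = ",")
  writeLines(txt, con)
  invisible(path)
}

#' Plain FFT periodogram
#'
#' One-sided periodogram normalized so that \code{sum(power)} equals the
#' mean square of the signal (a discrete Parseval identity): the DC bin
#' carries the squared mean, and the remaining bins carry the variance.
#' No windowing or segment averaging is applied.
#'
#' @param x numeric vector, length >= 2, all finite.
#' @param fs sampling rate in Hz.
#' @return A data.frame with columns \code{freq} (Hz, from 0 up to the
#'   Nyquist frequency fs/2) and \code{power} (nonnegative).
#' @examples
#' ps <- periodogram(sin(2 * pi * 10 * seq(0, 1, by = 1/250)), fs = 250)
#' ps$freq[which.max(ps$power)]  # 10 Hz
#' @export
periodogram <- function(x, fs) {
  if (length(x) < 2L) stop("need at least 2 samples")
  if (!all(is.finite(x))) stop("non-finite samples in input")
  n <- length(x)
  X <- fft(x)
  p2 <- Mod(X)^2 / n^2           # two-sided, sums to mean(x^2)
  half <- floor(n / 2)
  idx <- seq_len(half + 1L)      # bins 0..half
  power <- p2[idx]
  # fold the negative-frequency half onto positive bins
  dup <- 2:(if (n %% 2 == 0) half else half + 1L)
  power[dup] <- 2 * power[dup]
  data.frame(freq = (idx - 1L) * fs / n, power = power)
}
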