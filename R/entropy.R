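#' Entropy estimator parameters
#'
#' Bundle of the two tuning parameters shared by [sampEn()] and [apEn()]:
#' the embedding (template) dimension m and the match tolerance expressed
#' as a fraction of the analyzed series' standard deviation.  Defaults
#' m = 2, rFrac = 0.20 — the standard choice for EEG-length biomedical
#' series.
#'
#' @param m embedding dimension (positive integer).
#' @param rFrac tolerance as a fraction of the series SD (positive).
#' @return A validated list with class "EntropyParams".
#' @export
entropyParams <- function(m = 2L, rFrac = 0.20) {
  m <- as.integer(m)
  if (m < 1L) stop("m must be >= 1")
  if (!is.numeric(rFrac) || rFrac <= 0) stop("rFrac must be > 0")
  structure(list(m = m, rFrac = rFrac), class = "EntropyParams")
}

# population standard deviation: the scale of the analyzed series itself
.popSD <- function(x) sqrt(mean((x - mean(x))^2))

.resolveR <- function(x, p, r) {
  if (!is.null(r)) {
    if (r <= 0) stop("explicit tolerance r must be > 0")
    return(r)
  }
  s <- .popSD(x)
  if (s == 0)
    stop("degenerate tolerance: series is constant, so r = rFrac * SD = 0; ",
         "supply an explicit r > 0")
  p$rFrac * s
}

#' Chebyshev distance between template vectors
#'
#' The maximum absolute componentwise difference — the metric under which
#' two length-m templates "match" within tolerance r.
#'
#' @param u,v numeric vectors of equal length.
#' @return nonnegative scalar.
#' @examples
#' chebDist(c(1, 5), c(2, 3))  # 2
#' @export
chebDist <- function(u, v) {
  if (length(u) != length(v)) stop("length mismatch")
  max(abs(u - v))
}

#' Approximate entropy
#'
#' ApEn(m, r, N) = Phi^m(r) - Phi^(m+1)(r), where Phi^d(r) is the average
#' over templates u(i) = (x(i), ..., x(i+d-1)) of the log fraction of
#' templates (self-matches included) within Chebyshev distance r.  Lower
#' values indicate a more regular (self-similar) series.
#'
#' @param x numeric series, length >= m + 2.
#' @param p an [entropyParams()] bundle.
#' @param r explicit tolerance; overrides \code{p$rFrac * SD(x)}.
#' @return scalar; near 0 for regular series, larger for irregular ones.
#' @seealso [sampEn()]
#' @export
apEn <- function(x, p = entropyParams(), r = NULL) {
  x <- as.numeric(x)
  if (length(x) < p$m + 2L) stop("series too short: need length >= m + 2")
  if (!all(is.finite(x))) stop("non-finite values in series")
  r <- .resolveR(x, p, r)
  .apenPhi(x, p$m, r) - .apenPhi(x, p$m + 1L, r)
}

#' Sample entropy
#'
#' SampEn(m, r, N) = -ln(A/B), where B counts unordered template pairs
#' (i < j, both drawn from the first N-m positions) whose length-m
#' templates match within Chebyshev tolerance r, and A counts the same
#' pairs still matching when the templates are extended to length m+1.
#' Self-matches are excluded.  SampEn is 0 for a perfectly regular series
#' and grows with irregularity; it is undefined (error) when no template
#' pair matches at either length.
#'
#' @inheritParams apEn
#' @return nonnegative scalar (A <= B always, so -ln(A/B) >= 0).
#' @examples
#' sampEn(rep(c(1, -1), 25), r = 0.1)  # perfectly regular: 0
#' @export
sampEn <- function(x, p = entropyParams(), r = NULL) {
  x <- as.numeric(x)
  if (length(x) < p$m + 2L) stop("series too short: need length >= m + 2")
  if (!all(is.finite(x))) stop("non-finite values in series")
  r <- .resolveR(x, p, r)
  ab <- .sampenCounts(x, p$m, r)
  if (ab[2] == 0)
    stop("undefined sample entropy: no length-", p$m,
         " template pair matches within r")
  if (ab[1] == 0)
    stop("undefined sample entropy: no length-", p$m + 1L,
         " template pair matches within r")
  -log(ab[1] / ab[2])
}

#' Per-channel sample-entropy feature vector
#'
#' The feature-extraction stage of the pipeline: for each channel of a
#' canonical 10-channel recording, optionally decompose with the wavelet
#' pyramid and keep the level-\code{approxLevel} approximation series
#' (the low-frequency band where the discriminative EEG rhythms live),
#' then compute sample entropy with tolerance rFrac times the SD of the
#' analyzed series.
#'
#' @param rec an \linkS4class{EEGRecording} with the canonical layout.
#' @param useDwt if TRUE (default) analyze the approximation
#'   coefficients; if FALSE analyze the raw channel.
#' @param fb filter bank from [waveletFilter()].
#' @param p an [entropyParams()] bundle.
#' @param levels pyramid depth when \code{useDwt}.
#' @param approxLevel which approximation series to analyze (<= levels).
#' @return A one-row data.frame: subject_id, one SampEn column per
#'   channel (canonical order), label.
#' @export
extractFeatures <- function(rec, useDwt = TRUE, fb = waveletFilter("db4"),
                            p = entropyParams(), levels = 3L,
                            approxLevel = 3L) {
  stopifnot(is(rec, "EEGRecording"))
  if (!isCanonicalLayout(rec))
    stop("recording must use the canonical 10-channel layout")
  if (approxLevel > levels) stop("approxLevel must be <= levels")
  vals <- vapply(rec@channels, function(ch) {
    series <- rec@data[ch, ]
    if (useDwt) {
      wd <- dwtDecompose(series, fb, levels = levels, fs = rec@fs)
      series <- approxCoef(wd, approxLevel)
    }
    val <- tryCatch(sampEn(series, p),
                    error = function(e)
                      stop("channel ", ch, ": ", conditionMessage(e),
                           call. = FALSE))
    val
  }, numeric(1))
  out <- data.frame(subject_id = rec@subjectId, t(vals),
                    label = rec@label, check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Feature tables for a whole cohort
#'
#' Applies [extractFeatures()] to each recording and binds the rows.
#'
#' @param recordings list of \linkS4class{EEGRecording}.
#' @param ... passed to [extractFeatures()].
#' @return data.frame: subject_id, F3..O2, label.
#' @export
extractFeatureTable <- function(recordings, ...) {
  do.call(rbind, lapply(recordings, extractFeatures, ...))
}

#' Read/write feature tables
#'
#' CSV with columns subject_id, the 10 canonical channel names, label.
#'
#' @param features data.frame as produced by [extractFeatureTable()].
#' @param path file path.
#' @return \code{readFeatureCSV}: the data.frame; \code{writeFeatureCSV}:
#'   invisibly, \code{path}.
#' @export
writeFeatureCSV <- function(features, path) {
  write.table(format(features, digits = 15, trim = TRUE), path, sep = ",",
              quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname writeFeatureCSV
#' @export
readFeatureCSV <- function(path) {
  df <- read.table(path, sep = ",", header = TRUE, check.names = FALSE,
                   colClasses = "character")
  num <- setdiff(names(df), "subject_id")
  df[num] <- lapply(df[num], as.numeric)
  df$label <- as.integer(df$label)
  df
}
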