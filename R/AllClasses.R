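#' @useDynLib eegThreeWay, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats fft rnorm runif sd var predict
#' @importFrom utils read.table write.table head
NULL

#' Canonical 10-channel EEG montage
#'
#' Channel order used throughout the package: frontal (F3, F4), central
#' (C3, C4), temporal (T3, T4), parietal (P3, P4) and occipital (O1, O2).
#'
#' @format Character vector of length 10.
#' @export
CANONICAL_CHANNELS <- c("F3", "F4", "C3", "C4", "T3", "T4",
                        "P3", "P4", "O1", "O2")

#' EEGRecording: one subject's multichannel EEG
#'
#' Container for a single subject's recording: a channels x samples matrix
#' of potentials, the sampling rate, an ordered channel list and a binary
#' class label (0 = normal, 1 = PD, NA = unknown).
#'
#' @slot subjectId character scalar identifier.
#' @slot label integer scalar: 0 (normal), 1 (PD) or NA (unknown).
#' @slot fs numeric scalar, sampling rate in Hz (> 0).
#' @slot channels character vector of channel names, one per data row.
#' @slot data numeric matrix, rows = channels, columns = time samples.
#'
#' @export
setClass("EEGRecording",
  slots = c(
    subjectId = "character",
    label     = "integer",
    fs        = "numeric",
    channels  = "character",
    data      = "matrix"
  )
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (length(object@subjectId) != 1L)
    msg <- c(msg, "subjectId must be a single string")
  if (length(object@label) != 1L ||
      (!is.na(object@label) && !object@label %in% c(0L, 1L)))
    msg <- c(msg, "label must be 0, 1 or NA")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (nrow(object@data) != length(object@channels))
    msg <- c(msg, "nrow(data) must equal length(channels)")
  if (ncol(object@data) < 1L)
    msg <- c(msg, "data must have at least one sample")
  if (!is.numeric(object@data))
    msg <- c(msg, "data must be numeric")
  if (anyDuplicated(object@channels))
    msg <- c(msg, "channel names must be unique")
  if (length(msg)) msg else TRUE
})

#' WaveletDecomposition: multilevel Mallat pyramid coefficients
#'
#' Result of a multilevel discrete wavelet decomposition of a single
#' channel: approximation (A_j) and detail (D_j) coefficient series for
#' each level j, together with the bookkeeping needed to reconstruct the
#' signal and to map levels to frequency bands.
#'
#' @slot levels integer, number of decomposition levels.
#' @slot coeffs named list of numeric vectors, names A1, D1, ..., A<levels>,
#'   D<levels>.
#' @slot fs numeric, sampling rate of the decomposed signal in Hz.
#' @slot origLen integer, length of the original signal.
#' @slot wavelet character, filter-bank name (e.g. "db4").
#' @slot pad character, boundary mode: "symmetric" or "periodic".
#'
#' @export
setClass("WaveletDecomposition",
  slots = c(
    levels  = "integer",
    coeffs  = "list",
    fs      = "numeric",
    origLen = "integer",
    wavelet = "character",
    pad     = "character"
  )
)

setValidity("WaveletDecomposition", function(object) {
  msg <- character()
  lv <- object@levels
  if (length(lv) != 1L || lv < 1L)
    msg <- c(msg, "levels must be a positive integer")
  expected <- as.vector(rbind(paste0("A", seq_len(lv)),
                              paste0("D", seq_len(lv))))
  if (!all(expected %in% names(object@coeffs)))
    msg <- c(msg, sprintf("coeffs must contain %s",
                          paste(expected, collapse = ", ")))
  for (j in seq_len(lv)) {
    a <- object@coeffs[[paste0("A", j)]]
    d <- object@coeffs[[paste0("D", j)]]
    if (length(a) != length(d))
      msg <- c(msg, sprintf("length(A%d) must equal length(D%d)", j, j))
  }
  if (length(msg)) msg else TRUE
})

#' CoverModel: trained three-way covering classifier
#'
#' A fitted optimal-center constructive covering model: per-class covers
#' (center on the lifted sphere, Euclidean radius, class label and member
#' count), the min-max normalization parameters learned on the training
#' data, and the sphere-lifting radius R.
#'
#' @slot covers list; each element a list with fields \code{center}
#'   (numeric (n+1)-vector on the sphere), \code{radius}, \code{label}
#'   (0 or 1) and \code{memberCount}.
#' @slot featureMins numeric, per-dimension training minima.
#' @slot featureRanges numeric, per-dimension training ranges (zero-range
#'   dimensions stored as 1).
#' @slot R numeric, lifting radius (max norm of normalized training rows).
#' @slot radiusMode character, "midpoint" or "tight".
#' @slot featureNames character, names of the feature dimensions.
#'
#' @export
setClass("CoverModel",
  slots = c(
    covers        = "list",
    featureMins   = "numeric",
    featureRanges = "numeric",
    R             = "numeric",
    radiusMode    = "character",
    featureNames  = "character"
  )
)

setValidity("CoverModel", function(object) {
  msg <- character()
  n <- length(object@featureMins)
  if (length(object@featureRanges) != n)
    msg <- c(msg, "featureMins and featureRanges must have equal length")
  if (any(object@featureRanges <= 0))
    msg <- c(msg, "featureRanges must be positive (degenerate dims map to 1)")
  if (length(object@R) != 1L || object@R < 0)
    msg <- c(msg, "R must be a single nonnegative number")
  for (cv in object@covers) {
    if (!all(c("center", "radius", "label", "memberCount") %in% names(cv)))
      msg <- c(msg, "each cover needs center, radius, label, memberCount")
    else {
      if (length(cv$center) != n + 1L)
        msg <- c(msg, "cover centers must live in (n+1)-dimensional space")
      if (cv$radius < 0) msg <- c(msg, "cover radius must be >= 0")
      if (!cv$label %in% c(0L, 1L)) msg <- c(msg, "cover label must be 0 or 1")
      if (cv$memberCount < 1L) msg <- c(msg, "cover memberCount must be >= 1")
    }
  }
  if (length(msg)) msg else TRUE
})

#' EvalReport: cross-validated three-way classification metrics
#'
#' Confusion counts over all evaluated instances — correctly classified
#' (CCI), erroneously classified (ECI), boundary/abstained (BI), total
#' (SI) — and the derived ratios Acc = CCI/SI, Err = ECI/SI, Bnd = BI/SI.
#'
#' @slot SI integer, total instances.
#' @slot CCI integer, correctly classified instances.
#' @slot ECI integer, erroneously classified instances.
#' @slot BI integer, boundary (abstained) instances.
#' @slot acc,err,bnd numeric ratios in [0, 1].
#' @slot meta list, free-form provenance (classifier, k, seed, config).
#'
#' @export
setClass("EvalReport",
  slots = c(
    SI  = "integer", CCI = "integer", ECI = "integer", BI = "integer",
    acc = "numeric", err = "numeric", bnd = "numeric",
    meta = "list"
  )
)

setValidity("EvalReport", function(object) {
  msg <- character()
  if (object@SI < 1L) msg <- c(msg, "SI must be positive")
  if (any(c(object@CCI, object@ECI, object@BI) < 0L))
    msg <- c(msg, "counts must be nonnegative")
  if (object@CCI + object@ECI + object@BI != object@SI)
    msg <- c(msg, "CCI + ECI + BI must equal SI")
  if (abs(object@acc + object@err + object@bnd - 1) > 1e-12)
    msg <- c(msg, "acc + err + bnd must equal 1")
  if (abs(object@acc - object@CCI / object@SI) > 1e-12 ||
      abs(object@err - object@ECI / object@SI) > 1e-12 ||
      abs(object@bnd - object@BI  / object@SI) > 1e-12)
    msg <- c(msg, "ratios must equal counts / SI")
  if (length(msg)) msg else TRUE
})
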