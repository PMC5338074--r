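#' Synthetic cohort specification
#'
#' Parameters of the two-class synthetic EEG cohort.  Defaults mirror the
#' clinical cohort layout the pipeline targets: 25 normal and 17 PD-like
#' subjects, 10 canonical channels, 250 Hz, 40 s (10000 samples per
#' channel).  The classes differ only in the oscillatory-power fraction
#' w of each channel — w0 for the normal class, w0 + regularityGap for
#' the PD-like class — so the PD-like class is more rhythmic (lower
#' sample entropy) while per-channel standardization removes any
#' amplitude cue.
#'
#' @param nNormal,nPd class sizes.
#' @param fs sampling rate in Hz.
#' @param durationS recording length in seconds; fs * durationS must be
#'   an integer sample count.
#' @param regularityGap increment of the oscillatory fraction for the
#'   PD-like class, in (0, 1] (0 allowed: a null cohort with identical
#'   class distributions).
#' @param noiseExponent spectral slope of the pink-noise background
#'   (power ~ 1/f^noiseExponent).
#' @param w0 baseline oscillatory fraction of the normal class.
#' @param seed cohort seed; subject seeds are derived from it.
#' @return validated list of class "CohortSpec".
#' @export
cohortSpec <- function(nNormal = 25L, nPd = 17L, fs = 250, durationS = 40,
                       regularityGap = 0.4, noiseExponent = 1, w0 = 0.2,
                       seed = 1L) {
  n <- fs * durationS
  if (abs(n - round(n)) > 1e-9)
    stop("fs * durationS must be an integer sample count")
  if (nNormal < 0L || nPd < 0L) stop("class sizes must be >= 0")
  if (regularityGap < 0 || regularityGap > 1)
    stop("regularityGap must be in [0, 1]")
  if (w0 < 0 || w0 + regularityGap > 1)
    stop("w0 and w0 + regularityGap must stay in [0, 1]")
  structure(list(nNormal = as.integer(nNormal), nPd = as.integer(nPd),
                 fs = fs, durationS = durationS, n = as.integer(round(n)),
                 regularityGap = regularityGap,
                 noiseExponent = noiseExponent, w0 = w0,
                 seed = as.integer(seed)),
            class = "CohortSpec")
}

#' 1/f^a (pink) noise by frequency-domain shaping
#'
#' Draws random phases on the positive-frequency bins and scales bin
#' amplitudes by f^(-exponent/2), so the power spectrum falls off as
#' 1/f^exponent; the DC bin is zero.  Uses the caller's RNG stream.
#'
#' @param n number of samples.
#' @param exponent spectral slope (1 = pink, 0 = white, 2 = brown).
#' @return numeric vector of length n (unit variance not guaranteed;
#'   standardize if needed).
#' @export
pinkNoise <- function(n, exponent = 1) {
  nf <- n %/% 2L
  f <- seq_len(nf)
  amp <- f^(-exponent / 2)
  ph <- runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = ph)
  full <- complex(real = numeric(n))
  full[1 + f] <- spec
  if (n %% 2L == 0L) full[1 + nf] <- complex(real = amp[nf])  # real Nyquist
  mirror <- seq(n, by = -1, length.out = nf - (n %% 2L == 0L))
  full[mirror] <- Conj(full[1 + seq_len(nf - (n %% 2L == 0L))])
  Re(fft(full, inverse = TRUE)) / n
}

.standardize <- function(x) (x - mean(x)) / .popSD(x)

#' Generate one synthetic EEG recording
#'
#' Each of the 10 canonical channels is an independent mixture
#' (1 - w) * pink-noise + w * (10 Hz sine + 20 Hz sine) with random
#' phases, standardized to zero mean and unit variance.  The oscillatory
#' fraction w is \code{w0} for class "normal" and
#' \code{w0 + regularityGap} for class "pd", so PD-like channels are more
#' rhythmic and carry lower sample entropy.  Deterministic given
#' \code{subjectSeed}.
#'
#' @param cls "normal" or "pd".
#' @param spec a [cohortSpec()].
#' @param subjectSeed per-subject RNG seed.
#' @param subjectId identifier stored in the recording.
#' @return An \linkS4class{EEGRecording} with the canonical layout.
#' @export
synthRecording <- function(cls = c("normal", "pd"), spec = cohortSpec(),
                           subjectSeed = 1L, subjectId = NULL) {
  cls <- match.arg(cls)
  w <- spec$w0 + if (cls == "pd") spec$regularityGap else 0
  n <- spec$n
  tt <- (seq_len(n) - 1) / spec$fs
  if (is.null(subjectId)) subjectId <- paste0(cls, "-", subjectSeed)
  data <- .withSeed(subjectSeed, {
    t(vapply(CANONICAL_CHANNELS, function(ch) {
      noise <- .standardize(pinkNoise(n, spec$noiseExponent))
      ph <- runif(2, 0, 2 * pi)
      osc <- sin(2 * pi * 10 * tt + ph[1]) + sin(2 * pi * 20 * tt + ph[2])
      .standardize((1 - w) * noise + w * .standardize(osc))
    }, numeric(n)))
  })
  eegRecording(data, fs = spec$fs, channels = CANONICAL_CHANNELS,
               subjectId = subjectId,
               label = if (cls == "pd") 1L else 0L, canonical = TRUE)
}

#' Generate a reproducible two-class cohort
#'
#' Draws one distinct subject seed per recording from the cohort seed and
#' generates \code{nNormal} normal and \code{nPd} PD-like recordings.
#'
#' @param spec a [cohortSpec()].
#' @return list with \code{recordings} (list of
#'   \linkS4class{EEGRecording}) and \code{labels} (integer 0/1 vector).
#' @export
synthCohort <- function(spec = cohortSpec()) {
  ntot <- spec$nNormal + spec$nPd
  seeds <- .withSeed(spec$seed, sample.int(2147483646L, ntot))
  cls <- rep(c("normal", "pd"), c(spec$nNormal, spec$nPd))
  ids <- sprintf("%s-%02d", cls, seq_len(ntot))
  recordings <- lapply(seq_len(ntot), function(i)
    synthRecording(cls[i], spec, subjectSeed = seeds[i], subjectId = ids[i]))
  list(recordings = recordings,
       labels = rep(c(0L, 1L), c(spec$nNormal, spec$nPd)))
}

#' Gaussian-cluster feature table fixture
#'
#' Two spherical Gaussian clusters in \code{dim} dimensions with unit
#' within-class standard deviation and centers a Euclidean distance
#' \code{separation} apart — a direct fixture for the covering
#' classifier, bypassing signal generation.
#'
#' @param nPerClass samples per class.
#' @param dim feature dimensionality.
#' @param separation center distance in within-class SD units.
#' @param seed RNG seed.
#' @return labelled data.frame: subject_id, f1..f<dim>, label.
#' @export
synthFeatureTable <- function(nPerClass = 25L, dim = 10L, separation = 4,
                              seed = 1L) {
  if (dim < 1L) stop("dim must be >= 1")
  shift <- separation / sqrt(dim)
  .withSeed(seed, {
    x0 <- matrix(rnorm(nPerClass * dim), nPerClass)
    x1 <- matrix(rnorm(nPerClass * dim), nPerClass) + shift
    x <- rbind(x0, x1)
    colnames(x) <- paste0("f", seq_len(dim))
    df <- data.frame(subject_id = sprintf("s%03d", seq_len(2L * nPerClass)),
                     x, label = rep(c(0L, 1L), each = nPerClass))
    df
  })
}

#' Write / read a cohort directory
#'
#' One CSV per recording (package dialect, see [writeRecordingCSV()])
#' plus a \code{manifest.csv} with columns subject_id, label, file.
#'
#' @param cohort list as returned by [synthCohort()].
#' @param dir directory (created if missing).
#' @return \code{writeCohort}: invisibly, \code{dir}; \code{readCohort}:
#'   a cohort list.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- vapply(cohort$recordings, function(rec) {
    fn <- paste0(rec@subjectId, ".csv")
    writeRecordingCSV(rec, file.path(dir, fn))
    fn
  }, character(1))
  manifest <- data.frame(
    subject_id = vapply(cohort$recordings, function(r) r@subjectId, ""),
    label = cohort$labels, file = files)
  write.table(manifest, file.path(dir, "manifest.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest.csv in ", dir)
  manifest <- read.table(mf, sep = ",", header = TRUE,
                         colClasses = c("character", "integer", "character"))
  recordings <- lapply(seq_len(nrow(manifest)), function(i) {
    f <- file.path(dir, manifest$file[i])
    if (!file.exists(f))
      stop("manifest names missing recording file: ", manifest$file[i])
    rec <- readRecordingCSV(f, canonical = TRUE)
    if (!identical(rec@subjectId, manifest$subject_id[i]) ||
        !identical(rec@label, manifest$label[i]))
      stop("manifest/recording mismatch for ", manifest$file[i])
    rec
  })
  list(recordings = recordings, labels = manifest$label)
}
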