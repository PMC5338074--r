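# Daubechies scaling (low-pass analysis) filters, lowest-order moment
# first.  The high-pass analysis filter is the quadrature mirror
# hi[k] = (-1)^k lo[taps-1-k]; synthesis filters are the time reversals,
# so only the scaling filter needs to be stored.
WAVELET_SCALING <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(-0.12940952255126037, 0.2241438680420134, 0.8365163037378079,
          0.48296291314453416),
  db3 = c(0.03522629188570953, -0.08544127388202666, -0.13501102001025458,
          0.45987750211849154, 0.8068915093110925, 0.33267055295008263),
  db4 = c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
          -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
          0.7148465705529157, 0.2303778133088965),
  db5 = c(0.0033357252854737712, -0.012580751999081999, -0.006241490212798274,
          0.07757149384004572, -0.032244869584638375, -0.24229488706638203,
          0.13842814590132074, 0.7243085284377729, 0.6038292697971896,
          0.16010239797419293),
  db6 = c(-0.0010773010853084796, 0.004777257510945511, 0.0005538422011614961,
          -0.03158203931748603, 0.027522865530305727, 0.09750160558732304,
          -0.12976686756726194, -0.22626469396543983, 0.31525035170919763,
          0.7511339080210954, 0.49462389039845306, 0.11154074335010947),
  db7 = c(0.00035371379997452024, -0.0018016407040474908, 0.0004295779729213665,
          0.01255099855609984, -0.01657454163066688, -0.03802993693501441,
          0.08061260915108308, 0.07130921926683026, -0.22403618499387498,
          -0.14390600392856498, 0.4697822874051931, 0.7291320908462351,
          0.3965393194819173, 0.07785205408500918),
  db8 = c(-0.00011747678412476953, 0.0006754494064505693,
          -0.00039174037337694705, -0.004870352993451574, 0.008746094047405777,
          0.013981027917398282, -0.044088253930794755, -0.017369301001807547,
          0.12874742662047847, 0.0004724845739132828, -0.2840155429615469,
          -0.015829105256349306, 0.5853546836542067, 0.6756307362972898,
          0.31287159091429995, 0.05441584224310401),
  db9 = c(3.93473203162716e-05, -0.0002519631889427101, 0.00023038576352319597,
          0.0018476468830562265, -0.00428150368246343, -0.004723204757751397,
          0.022361662123679096, 0.00025094711483145197, -0.06763282906132997,
          0.03072568147933338, 0.14854074933810638, -0.09684078322297646,
          -0.2932737832791749, 0.13319738582500756, 0.6572880780513005,
          0.6048231236901112, 0.24383467461259034, 0.038077947363878345),
  db10 = c(-1.3264202894521244e-05, 9.358867032006959e-05,
           -0.00011646685512928545, -0.0006858566949597116,
           0.001992405295185056, 0.001395351747052901, -0.010733175483330575,
           0.0036065535669561697, 0.033212674059341, -0.029457536821875813,
           -0.07139414716639708, 0.09305736460357235, 0.12736934033579325,
           -0.19594627437737705, -0.24984642432731538, 0.2811723436605775,
           0.6884590394536035, 0.5272011889317256, 0.1881768000776915,
           0.026670057900555554)
)

#' Quadrature mirror filter bank
#'
#' Builds the four-tap-set filter bank (analysis low/high pass, synthesis
#' low/high pass) for an orthogonal wavelet selected by name.  Analysis
#' and synthesis banks satisfy perfect reconstruction:
#' \code{idwtLevel(dwtLevel(x))} recovers \code{x} to ~1e-10.
#'
#' @param name one of "haar", "db2" ... "db10".
#' @return A list with fields \code{name}, \code{taps}, \code{loA},
#'   \code{hiA} (analysis) and \code{loS}, \code{hiS} (synthesis), all of
#'   equal even length.
#' @examples
#' fb <- waveletFilter("db4")
#' fb$taps  # 8
#' @export
waveletFilter <- function(name = "db4") {
  lo <- WAVELET_SCALING[[name]]
  if (is.null(lo))
    stop("unknown wavelet '", name, "'; available: ",
         paste(names(WAVELET_SCALING), collapse = ", "))
  t <- length(lo)
  hi <- (-1)^seq_len(t) * rev(lo)
  list(name = name, taps = t,
       loA = lo, hiA = hi,        # analysis (decomposition)
       loS = rev(lo), hiS = rev(hi))  # synthesis (reconstruction)
}

# symmetric (half-point) padding: [x_p .. x_1 | x_1 .. x_N | x_N .. x_{N-p+1}]
.padSymmetric <- function(x, p) {
  n <- length(x)  # callers guarantee p < n
  c(x[p:1], x, x[n:(n - p + 1L)])
}

#' Single-level discrete wavelet transform
#'
#' One analysis step of the Mallat pyramid: the signal is filtered by the
#' low- and high-pass analysis filters and downsampled by two, producing
#' equal-length approximation and detail coefficient series.
#'
#' Boundary handling: \code{pad = "symmetric"} (default) uses half-point
#' symmetric extension and yields \code{floor((N + taps - 1)/2)}
#' coefficients per branch; \code{pad = "periodic"} uses circular
#' convolution on an even-length signal and yields \code{N/2}
#' coefficients per branch, conserving energy exactly for orthogonal
#' banks.
#'
#' @param x numeric signal, length >= taps.
#' @param fb filter bank from [waveletFilter()].
#' @param pad "symmetric" or "periodic".
#' @return list with numeric vectors \code{approx} and \code{detail}.
#' @seealso [idwtLevel()], [dwtDecompose()]
#' @export
dwtLevel <- function(x, fb = waveletFilter("db4"),
                     pad = c("symmetric", "periodic")) {
  pad <- match.arg(pad)
  n <- length(x)
  t <- fb$taps
  if (n < t)
    stop("signal length ", n, " is shorter than the ", t,
         "-tap filter; use fewer levels or a shorter wavelet")
  if (pad == "symmetric") {
    xp <- .padSymmetric(x, t - 1L)
    # full convolution, then keep every second sample starting at index
    # taps+1 (1-based); length floor((n + taps - 1)/2)
    la <- floor((n + t - 1) / 2)
    keep <- t + 1L + 2L * (seq_len(la) - 1L)
    ca <- convolve(xp, rev(fb$loA), type = "open")[keep]
    cd <- convolve(xp, rev(fb$hiA), type = "open")[keep]
  } else {
    if (n %% 2 != 0) stop("periodic padding requires even signal length")
    half <- n / 2L
    # a[k] = sum_j lo[j] x[(2k + t/2 - j) mod n]  (0-based), circular
    ca <- cd <- numeric(half)
    for (k in seq_len(half)) {
      idx <- ((2L * (k - 1L) + 1L + (t %/% 2L - 1L) - (seq_len(t) - 1L)) %% n) + 1L
      ca[k] <- sum(fb$loA * x[idx])
      cd[k] <- sum(fb$hiA * x[idx])
    }
  }
  list(approx = ca, detail = cd)
}

#' Single-level inverse discrete wavelet transform
#'
#' One synthesis step: upsample the approximation and detail series by
#' two, filter with the synthesis bank and sum.  Composed with
#' [dwtLevel()] under the same padding mode it reproduces the original
#' signal (perfect reconstruction).
#'
#' @param approx,detail equal-length coefficient vectors.
#' @param fb filter bank from [waveletFilter()].
#' @param outLen length of the reconstructed signal.
#' @param pad padding mode used at analysis.
#' @return numeric vector of length \code{outLen}.
#' @export
idwtLevel <- function(approx, detail, fb = waveletFilter("db4"), outLen,
                      pad = c("symmetric", "periodic")) {
  pad <- match.arg(pad)
  if (length(approx) != length(detail))
    stop("approx and detail must have equal length")
  t <- fb$taps
  la <- length(approx)
  if (pad == "symmetric") {
    up <- function(c) { u <- numeric(2L * la); u[seq(1L, 2L * la, 2L)] <- c; u }
    r <- convolve(up(approx), rev(fb$loS), type = "open") +
         convolve(up(detail), rev(fb$hiS), type = "open")
    start <- t - 1L  # 0-based t-2
    if (outLen > length(r) - start + 1L)
      stop("outLen ", outLen, " exceeds reconstructable length")
    r[start:(start + outLen - 1L)]
  } else {
    n <- 2L * la
    if (outLen != n) stop("periodic mode reconstructs exactly 2*length(approx)")
    x <- numeric(n)
    for (k in seq_len(la)) {
      idx <- ((2L * (k - 1L) + 1L + (t %/% 2L - 1L) - (seq_len(t) - 1L)) %% n) + 1L
      x[idx] <- x[idx] + fb$loA * approx[k] + fb$hiA * detail[k]
    }
    x
  }
}

#' Multilevel wavelet decomposition
#'
#' Cascades [dwtLevel()] on successive approximations: level j+1 is the
#' decomposition of approximation A_j.  Three levels (the default) split
#' an fs-sampled signal into detail bands D1 (fN/2, fN), D2 (fN/4, fN/2),
#' D3 (fN/8, fN/4) and the terminal approximation A3 (0, fN/8), with
#' fN = fs/2 the Nyquist frequency.
#'
#' @param x numeric signal.
#' @param fb filter bank from [waveletFilter()].
#' @param levels number of pyramid levels (default 3).
#' @param fs sampling rate in Hz (bookkeeping only).
#' @param pad padding mode, see [dwtLevel()].
#' @return A \linkS4class{WaveletDecomposition}.
#' @examples
#' wd <- dwtDecompose(rnorm(1000), waveletFilter("db4"), levels = 3, fs = 250)
#' lengths(approxCoef(wd, 3))
#' @export
dwtDecompose <- function(x, fb = waveletFilter("db4"), levels = 3L, fs = 1,
                         pad = c("symmetric", "periodic")) {
  pad <- match.arg(pad)
  levels <- as.integer(levels)
  if (levels < 1L) stop("levels must be >= 1")
  coeffs <- list()
  cur <- x
  for (j in seq_len(levels)) {
    if (length(cur) < fb$taps)
      stop("signal too short for ", levels, " levels with a ", fb$taps,
           "-tap filter (level ", j, " input has ", length(cur),
           " samples); reduce levels")
    lvl <- dwtLevel(cur, fb, pad)
    coeffs[[paste0("A", j)]] <- lvl$approx
    coeffs[[paste0("D", j)]] <- lvl$detail
    cur <- lvl$approx
  }
  new("WaveletDecomposition", levels = levels, coeffs = coeffs,
      fs = as.numeric(fs), origLen = length(x), wavelet = fb$name, pad = pad)
}

#' @describeIn dwtDecompose extract an approximation (A_j) coefficient
#'   series from a decomposition.
#' @param wd a WaveletDecomposition.
#' @param level pyramid level j.
#' @export
approxCoef <- function(wd, level = wd@levels) {
  stopifnot(is(wd, "WaveletDecomposition"))
  if (level < 1L || level > wd@levels) stop("level out of range")
  wd@coeffs[[paste0("A", level)]]
}

#' @describeIn dwtDecompose extract a detail (D_j) coefficient series.
#' @export
detailCoef <- function(wd, level) {
  stopifnot(is(wd, "WaveletDecomposition"))
  if (level < 1L || level > wd@levels) stop("level out of range")
  wd@coeffs[[paste0("D", level)]]
}

#' Reconstruct the signal from a wavelet decomposition
#'
#' Inverts the pyramid from \{A_L, D_L, ..., D_1\} by cascading
#' [idwtLevel()], recovering the original signal to round-off.
#'
#' @param wd a \linkS4class{WaveletDecomposition}.
#' @return numeric vector of length \code{wd@origLen}.
#' @export
waveletReconstruct <- function(wd) {
  stopifnot(is(wd, "WaveletDecomposition"))
  fb <- waveletFilter(wd@wavelet)
  # synthesis at level j must restore the length of A_{j-1} (A_0 = original)
  lens <- c(wd@origLen,
            vapply(seq_len(wd@levels - 1L),
                   function(j) length(wd@coeffs[[paste0("A", j)]]), 1L))
  cur <- wd@coeffs[[paste0("A", wd@levels)]]
  for (j in rev(seq_len(wd@levels))) {
    cur <- idwtLevel(cur, wd@coeffs[[paste0("D", j)]], fb,
                     outLen = lens[j], pad = wd@pad)
  }
  cur
}

setMethod("show", "WaveletDecomposition", function(object) {
  cat(sprintf("WaveletDecomposition: %d levels, %s, %s padding\n",
              object@levels, object@wavelet, object@pad))
  cat(sprintf("  original length %d at %g Hz\n", object@origLen, object@fs))
  for (j in seq_len(object@levels)) {
    be <- bandEdges(j, "detail", object@fs)
    cat(sprintf("  D%d: %5d coeffs  (%g, %g) Hz\n", j,
                length(object@coeffs[[paste0("D", j)]]), be[1], be[2]))
  }
  be <- bandEdges(object@levels, "approx", object@fs)
  cat(sprintf("  A%d: %5d coeffs  (%g, %g) Hz\n", object@levels,
              length(object@coeffs[[paste0("A", object@levels)]]),
              be[1], be[2]))
})

#' Frequency band of a pyramid subband
#'
#' With Nyquist frequency fN = fs/2, the approximation at level j spans
#' (0, fN/2^j) and the detail at level j spans (fN/2^j, fN/2^(j-1)).  The
#' detail bands of levels 1..L plus the level-L approximation tile
#' (0, fN) without overlap.
#'
#' @param level pyramid level (>= 1).
#' @param kind "approx" or "detail".
#' @param fs sampling rate in Hz.
#' @return numeric c(lo, hi) in Hz.
#' @examples
#' bandEdges(3, "approx", 250)  # 0 .. 15.625 Hz
#' @export
bandEdges <- function(level, kind = c("approx", "detail"), fs) {
  kind <- match.arg(kind)
  if (level < 1L) stop("level must be >= 1")
  fN <- fs / 2
  if (kind == "approx") c(0, fN / 2^level)
  else c(fN / 2^level, fN / 2^(level - 1L))
}
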