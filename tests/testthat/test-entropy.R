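test_that("Chebyshev distance over template components", {
  expect_equal(chebDist(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(chebDist(c(1, 5), c(2, 3)), 2)
  set.seed(1)
  for (i in 1:25) {
    u <- rnorm(5); v <- rnorm(5)
    expect_identical(chebDist(u, v), chebDist(v, u))
    expect_gte(chebDist(u, v), 0)
  }
  expect_error(chebDist(1:3, 1:4), "length mismatch")
})

test_that("constant series have zero entropy when r is supplied", {
  x <- rep(3.2, 60)
  expect_equal(apEn(x, r = 0.5), 0)
  expect_equal(sampEn(x, r = 0.5), 0)
  # r derived from SD of a constant series is degenerate
  expect_error(sampEn(x), "degenerate")
  expect_error(apEn(x), "degenerate")
})

test_that("period-2 alternating series is perfectly regular", {
  x <- rep(c(1, -1), 25)
  expect_equal(sampEn(x, entropyParams(m = 2), r = 0.1), 0)
})

test_that("apEn matches a literal transcription of its definition", {
  x <- as.numeric(1:10)
  expect_equal(apEn(x, entropyParams(m = 2), r = 0.5),
               oracleApEn(x, 2, 0.5), tolerance = 1e-14)
  set.seed(2)
  for (i in 1:50) {
    y <- rnorm(100)
    r <- 0.2 * sd(y)
    expect_equal(apEn(y, entropyParams(m = 2), r = r),
                 oracleApEn(y, 2, r), tolerance = 1e-12)
  }
})

test_that("sampEn agrees with both independent oracles", {
  set.seed(3)
  for (i in 1:50) {
    y <- rnorm(200)
    r <- 0.2 * sqrt(mean((y - mean(y))^2))
    ours <- sampEn(y, entropyParams(m = 2), r = r)
    expect_equal(ours, oracleSampEn(y, 2, r), tolerance = 1e-10)
    expect_equal(ours, pracma::sample_entropy(y, edim = 2, r = r),
                 tolerance = 1e-10)
  }
})

test_that("entropies are invariant under affine maps when r tracks the SD", {
  set.seed(4)
  for (i in 1:10) {
    x <- rnorm(150)
    a <- runif(1, 0.1, 10) * sample(c(-1, 1), 1)
    b <- runif(1, -5, 5)
    expect_equal(sampEn(a * x + b), sampEn(x), tolerance = 1e-10)
    expect_equal(apEn(a * x + b), apEn(x), tolerance = 1e-10)
  }
})

test_that("sampEn is nonnegative and errors rather than returning Inf", {
  set.seed(5)
  for (i in 1:20) expect_gte(sampEn(rnorm(120)), 0)
  # geometric growth: no two templates ever match at tiny tolerance
  expect_error(sampEn(2^(1:12), r = 0.01), "undefined")
  expect_error(sampEn(rnorm(3)), "too short")
})

test_that("regularity ordering: white noise > noisy sine > pure sine", {
  set.seed(6)
  n <- 500
  tt <- (0:(n - 1)) / 100
  pure <- sampEn(sin(2 * pi * 5 * tt))
  white <- noisy <- numeric(20)
  for (s in 1:20) {
    white[s] <- sampEn(rnorm(n))
    noisy[s] <- sampEn(sin(2 * pi * 5 * tt) + 0.3 * rnorm(n))
  }
  expect_gt(mean(white), mean(noisy))
  expect_gt(mean(noisy), pure)
})

test_that("feature extraction composes sampEn over canonical channels", {
  spec <- cohortSpec(durationS = 2)
  rec <- synthRecording("normal", spec, subjectSeed = 9)
  feats <- extractFeatures(rec, useDwt = FALSE)
  expect_identical(names(feats), c("subject_id", CANONICAL_CHANNELS, "label"))
  for (ch in c("F3", "O2"))
    expect_equal(feats[[ch]], sampEn(signalMatrix(rec)[ch, ]))
  expect_identical(feats$label, 0L)
  expect_true(all(is.finite(as.numeric(feats[CANONICAL_CHANNELS]))))
})

test_that("wavelet-band features rank noise channels above sine channels", {
  spec <- cohortSpec(durationS = 8)
  wins <- 0L
  for (s in 1:20) {
    set.seed(100 + s)
    n <- spec$n
    tt <- (0:(n - 1)) / spec$fs
    sine <- t(vapply(1:10, function(i)
      sin(2 * pi * 10 * tt + runif(1, 0, 2 * pi)) +
        0.02 * rnorm(n), numeric(n)))
    noise <- t(vapply(1:10, function(i) rnorm(n), numeric(n)))
    fSine <- extractFeatures(eegRecording(sine, fs = spec$fs,
                                          channels = CANONICAL_CHANNELS,
                                          label = 1), useDwt = TRUE)
    fNoise <- extractFeatures(eegRecording(noise, fs = spec$fs,
                                           channels = CANONICAL_CHANNELS,
                                           label = 0), useDwt = TRUE)
    wins <- wins + all(as.numeric(fNoise[CANONICAL_CHANNELS]) >
                         as.numeric(fSine[CANONICAL_CHANNELS]))
  }
  expect_identical(wins, 20L)
})

test_that("a constant channel aborts extraction naming the channel", {
  rec <- synthRecording("normal", cohortSpec(durationS = 2), 3)
  m <- signalMatrix(rec)
  m["T4", ] <- 1.5
  broken <- eegRecording(m, fs = 250, channels = CANONICAL_CHANNELS)
  expect_error(extractFeatures(broken, useDwt = FALSE), "T4")
})

test_that("feature tables round-trip through CSV", {
  ft <- synthFeatureTable(5, 3, separation = 2, seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  writeFeatureCSV(ft, path)
  back <- readFeatureCSV(path)
  expect_equal(featureMatrix(back), featureMatrix(ft), tolerance = 1e-12)
  expect_identical(featureLabels(back), featureLabels(ft))
})
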