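test_that("analysis matches the independent pyramid reference", {
  for (case in DWT_REFERENCE) {
    x <- sin(seq_len(case$n)) + 0.05 * seq_len(case$n)
    ad <- dwtLevel(x, waveletFilter(case$wavelet))
    expect_equal(ad$approx, case$approx, tolerance = 1e-12,
                 info = paste(case$wavelet, case$n))
    expect_equal(ad$detail, case$detail, tolerance = 1e-12,
                 info = paste(case$wavelet, case$n))
  }
})

test_that("constant signals have vanishing detail and sqrt(2)-scaled approx", {
  fb <- waveletFilter("db4")
  ad <- dwtLevel(rep(3, 200), fb)
  expect_lt(max(abs(ad$detail)), 1e-10)
  interior <- ad$approx[fb$taps:(length(ad$approx) - fb$taps)]
  expect_equal(interior, rep(3 * sqrt(2), length(interior)),
               tolerance = 1e-10)
})

test_that("coefficient lengths follow floor((N + taps - 1)/2)", {
  fb <- waveletFilter("db4")
  ad <- dwtLevel(rnorm(10000), fb)
  expect_length(ad$approx, 5003)
  expect_length(ad$detail, 5003)
  for (n in c(17, 64, 333)) {
    ad <- dwtLevel(rnorm(n), fb)
    expect_length(ad$approx, floor((n + fb$taps - 1) / 2))
  }
})

test_that("single-level round trip is a perfect reconstruction", {
  set.seed(1)
  for (wavelet in c("haar", "db2", "db4", "db10")) {
    fb <- waveletFilter(wavelet)
    for (n in c(64, 1000, 10000)) {
      x <- rnorm(n)
      ad <- dwtLevel(x, fb)
      expect_lt(max(abs(idwtLevel(ad$approx, ad$detail, fb, n) - x)), 1e-8)
    }
  }
})

test_that("synthesis is linear and maps zero to zero", {
  set.seed(2)
  fb <- waveletFilter("db4")
  a <- rnorm(30); d <- rnorm(30); a2 <- rnorm(30); d2 <- rnorm(30)
  expect_equal(idwtLevel(a + a2, d + d2, fb, 52),
               idwtLevel(a, d, fb, 52) + idwtLevel(a2, d2, fb, 52),
               tolerance = 1e-10)
  expect_equal(idwtLevel(numeric(30), numeric(30), fb, 52), numeric(52))
  expect_error(idwtLevel(rnorm(5), rnorm(6), fb, 10), "equal length")
})

test_that("orthogonal banks conserve energy under periodic padding", {
  set.seed(3)
  for (wavelet in c("haar", "db4", "db8")) {
    fb <- waveletFilter(wavelet)
    x <- rnorm(256)
    ad <- dwtLevel(x, fb, pad = "periodic")
    expect_lt(abs(sum(x^2) - sum(ad$approx^2) - sum(ad$detail^2)) / sum(x^2),
              1e-6)
    expect_lt(max(abs(idwtLevel(ad$approx, ad$detail, fb, 256,
                                pad = "periodic") - x)), 1e-8)
  }
})

test_that("three-level cascade has the reference lengths and reconstructs", {
  fb <- waveletFilter("db4")
  set.seed(4)
  x <- rnorm(10000)
  wd <- dwtDecompose(x, fb, levels = 3, fs = 250)
  # cascade of the floor((n + taps - 1)/2) rule: 10000 -> 5003 -> 2505 -> 1256
  expect_length(approxCoef(wd, 1), 5003)
  expect_length(approxCoef(wd, 2), 2505)
  expect_length(approxCoef(wd, 3), 1256)
  expect_length(detailCoef(wd, 3), 1256)
  expect_lt(max(abs(waveletReconstruct(wd) - x)), 1e-8)
  for (n in c(64, 1000)) {
    y <- rnorm(n)
    expect_lt(max(abs(waveletReconstruct(
      dwtDecompose(y, fb, levels = 3, fs = 250)) - y)), 1e-8)
  }
})

test_that("one-level decomposition reduces to dwtLevel", {
  fb <- waveletFilter("db2")
  set.seed(5)
  x <- rnorm(100)
  wd <- dwtDecompose(x, fb, levels = 1, fs = 100)
  ad <- dwtLevel(x, fb)
  expect_equal(approxCoef(wd, 1), ad$approx)
  expect_equal(detailCoef(wd, 1), ad$detail)
})

test_that("too-short signals raise an instructive error", {
  fb <- waveletFilter("db10")
  expect_error(dwtLevel(rnorm(10), fb), "reduce levels|shorter")
  # 22 -> 20 -> 19 coefficients: level 3 input is shorter than the filter
  expect_error(dwtDecompose(rnorm(22), fb, levels = 3, fs = 1),
               "reduce levels")
  expect_error(waveletFilter("sym5"), "unknown wavelet")
})

test_that("band edges halve from Nyquist and tile (0, fs/2)", {
  expect_equal(bandEdges(3, "approx", 250), c(0, 15.625))
  expect_equal(bandEdges(1, "detail", 250), c(62.5, 125))
  expect_equal(bandEdges(2, "detail", 250), c(31.25, 62.5))
  expect_error(bandEdges(0, "approx", 250), "level")
  # D1, D2, D3, A3 partition (0, 125) exactly, no overlap
  bands <- rbind(bandEdges(3, "approx", 250),
                 bandEdges(3, "detail", 250),
                 bandEdges(2, "detail", 250),
                 bandEdges(1, "detail", 250))
  expect_equal(bands[1, 1], 0)
  expect_equal(bands[nrow(bands), 2], 125)
  expect_equal(bands[-1, 1], bands[-nrow(bands), 2])  # contiguous, disjoint
  # the partition property holds for any level count
  for (L in 1:5) {
    edges <- c(bandEdges(L, "approx", 250)[2],
               vapply(rev(seq_len(L)), function(j)
                 bandEdges(j, "detail", 250)[2], 1))
    expect_equal(edges[length(edges)], 125)
    expect_true(all(diff(edges) > 0))
  }
})
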