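test_that("min-max normalization handles ordinary and degenerate columns", {
  norm <- normalizeFit(cbind(c(0, 5, 10)))
  expect_equal(unname(norm$mins), 0)
  expect_equal(unname(norm$ranges), 10)
  # constant column: range substituted with 1, values map to 0
  m <- cbind(a = c(1, 2, 3), b = c(4, 4, 4))
  norm <- normalizeFit(m)
  expect_equal(unname(norm$ranges["b"]), 1)
  z <- normalizeApply(m, norm)
  expect_equal(unname(z[, "b"]), c(0, 0, 0))
  expect_error(normalizeFit(matrix(0, 0, 3)), "empty")
  set.seed(1)
  x <- matrix(rnorm(200) * 40, 20)
  z <- normalizeApply(x, normalizeFit(x))
  expect_true(all(z >= 0 & z <= 1))
})

test_that("sphere lifting places all points exactly on the radius-R sphere", {
  expect_equal(sphereProject(c(0, 0), 1), c(0, 0, 1))
  x <- c(0.6, 0.8)  # |x| = 1 = R: last coordinate collapses to 0
  expect_equal(sphereProject(x, 1), c(0.6, 0.8, 0))
  expect_error(sphereProject(c(2, 0), 1), "exceeds")
  set.seed(2)
  pts <- matrix(runif(300), 100)
  R <- max(sqrt(rowSums(pts^2)))
  lifted <- sphereProject(pts, R)
  expect_equal(sqrt(rowSums(lifted^2)), rep(R, 100), tolerance = 1e-9)
})

test_that("cover radius splits the margin and never reaches an enemy", {
  center <- c(0, 0, 1)
  onSphere <- function(theta) c(sin(theta), 0, cos(theta))
  same <- rbind(center, onSphere(0.4))
  # no enemies: radius is the farthest friend
  d2 <- sqrt(sum((onSphere(0.4) - center)^2))
  expect_equal(coverRadius(center, same, NULL), d2)
  # midpoint between last friend and nearest enemy
  expect_equal(coverRadius(c(0, 0), rbind(c(0.6, 0)), rbind(c(1, 0))), 0.8)
  expect_equal(coverRadius(c(0, 0), rbind(c(0.6, 0)), rbind(c(1, 0)),
                           mode = "tight"), 0.6)
  expect_error(coverRadius(center, matrix(0, 0, 3), same), "same-class")
  set.seed(3)
  for (i in 1:50) {
    same <- matrix(rnorm(30), 10)
    enemy <- matrix(rnorm(15, mean = 3), 5)
    ctr <- same[1, ]
    r <- coverRadius(ctr, same, enemy)
    d1 <- min(sqrt(rowSums(sweep(enemy, 2, ctr)^2)))
    ds <- sqrt(rowSums(sweep(same, 2, ctr)^2))
    d2 <- max(ds[ds < d1])
    expect_lt(r, d1)
    expect_gte(r, d2)
  }
})

test_that("well-separated clusters train to one cover per class", {
  ft <- synthFeatureTable(10, 4, separation = 30, seed = 4)
  model <- occaTrain(ft)
  expect_length(model@covers, 2L)
  labs <- vapply(model@covers, `[[`, 0L, "label")
  expect_setequal(labs, c(0L, 1L))
  expect_equal(vapply(model@covers, `[[`, 0L, "memberCount"), c(10L, 10L))
})

test_that("the smallest instance yields two half-distance covers", {
  df <- data.frame(subject_id = c("a", "b"), f1 = c(0, 1), f2 = c(0, 1),
                   label = 0:1)
  model <- occaTrain(df)
  expect_length(model@covers, 2L)
  z <- normalizeApply(featureMatrix(df),
                      list(mins = model@featureMins,
                           ranges = model@featureRanges))
  lifted <- sphereProject(z, model@R)
  d1 <- sqrt(sum((lifted[1, ] - lifted[2, ])^2))
  for (cv in model@covers) expect_equal(cv$radius, d1 / 2)
})

test_that("training points are memorized; their labels are reproduced", {
  ft <- synthFeatureTable(15, 6, separation = 3, seed = 5)
  model <- occaTrain(ft)
  dec <- occaDecide(model, ft)
  expect_identical(dec$label, as.character(featureLabels(ft)))
  expect_true(all(dec$region %in% c("POS", "NEG")))
  # region <-> label correspondence (regions w.r.t. class 0)
  expect_identical(dec$region == "POS", dec$label == "0")
})

test_that("points claimed by neither or both classes defer to the boundary", {
  # clusters tucked into opposite corners: the far corner is uncovered
  set.seed(6)
  x0 <- matrix(runif(40, 0, 0.05), 20)
  x1 <- matrix(runif(40, 0.95, 1), 20)
  df <- data.frame(subject_id = sprintf("s%d", 1:40), rbind(x0, x1),
                   label = rep(0:1, each = 20))
  model <- occaTrain(df)
  far <- occaDecide(model, c(0.02, 0.98))
  expect_identical(far$label, "boundary")
  expect_identical(far$region, "BND")
  # contrived overlapping model: both classes own the same center
  overlap <- new("CoverModel",
    covers = list(list(center = c(0.5, 0.5, 0.7071), radius = 0.5,
                       label = 0L, memberCount = 1L),
                  list(center = c(0.5, 0.5, 0.7071), radius = 0.5,
                       label = 1L, memberCount = 1L)),
    featureMins = c(0, 0), featureRanges = c(1, 1), R = 1,
    radiusMode = "midpoint", featureNames = c("f1", "f2"))
  both <- occaDecide(overlap, c(0.5, 0.5))
  expect_identical(both$label, "boundary")
  expect_error(occaDecide(model, c(1, 2, 3)), "feature columns")
})

test_that("structural invariants hold across random separable datasets", {
  set.seed(7)
  for (i in 1:30) {
    ft <- synthFeatureTable(nPerClass = sample(4:12, 1),
                            dim = sample(2:6, 1),
                            separation = runif(1, 6, 20), seed = 1000 + i)
    model <- occaTrain(ft)
    labels <- featureLabels(ft)
    z <- normalizeApply(featureMatrix(ft),
                        list(mins = model@featureMins,
                             ranges = model@featureRanges))
    lifted <- sphereProject(z, model@R)
    labs <- vapply(model@covers, `[[`, 0L, "label")
    for (row in seq_len(nrow(lifted))) {
      d <- vapply(model@covers, function(cv)
        sqrt(sum((cv$center - lifted[row, ])^2)), 0)
      radii <- vapply(model@covers, `[[`, 0, "radius")
      expect_true(any(d <= radii & labs == labels[row]))      # own cover
      expect_false(any(d < radii & labs != labels[row]))      # no enemy inside
    }
    expect_lte(length(model@covers), nrow(ft))
    expect_identical(occaDecide(model, ft)$label, as.character(labels))
  }
})

test_that("training is deterministic and scale-invariant", {
  ft <- synthFeatureTable(8, 4, separation = 2, seed = 8)
  m1 <- occaTrain(ft); m2 <- occaTrain(ft)
  expect_equal(m1@covers, m2@covers)
  # per-column affine scaling is absorbed by min-max normalization
  scaled <- ft
  scaled$f1 <- scaled$f1 * 1000 + 5
  scaled$f3 <- scaled$f3 / 250
  probe <- synthFeatureTable(5, 4, separation = 2, seed = 9)
  probeScaled <- probe
  probeScaled$f1 <- probeScaled$f1 * 1000 + 5
  probeScaled$f3 <- probeScaled$f3 / 250
  d1 <- occaDecide(occaTrain(ft), probe)
  d2 <- occaDecide(occaTrain(scaled), probeScaled)
  expect_identical(d1$label, d2$label)
})

test_that("degenerate training inputs are rejected or flagged", {
  one <- data.frame(subject_id = c("a", "b"), f1 = c(1, 2), label = c(0L, 0L))
  expect_error(occaTrain(one), "each class")
  dup <- data.frame(subject_id = c("a", "b", "c", "d"),
                    f1 = c(0, 0, 1, 2), f2 = c(0, 0, 1, 2),
                    label = c(0L, 1L, 0L, 1L))
  expect_warning(occaTrain(dup), "conflicting labels")
})

test_that("cover models survive a JSON round trip", {
  ft <- synthFeatureTable(6, 3, separation = 5, seed = 10)
  model <- occaTrain(ft)
  path <- withr::local_tempfile(fileext = ".json")
  writeCoverModel(model, path)
  back <- readCoverModel(path)
  expect_equal(back@covers, model@covers, tolerance = 1e-12)
  expect_equal(back@R, model@R)
  probe <- synthFeatureTable(4, 3, separation = 5, seed = 11)
  expect_identical(occaDecide(back, probe)$label,
                   occaDecide(model, probe)$label)
})

test_that("negated-feature scale invariance holds for flipped label too", {
  # flipping a feature's sign flips its min-max orientation; decisions on
  # training points must still reproduce the labels
  ft <- synthFeatureTable(6, 2, separation = 8, seed = 12)
  ft$f2 <- -ft$f2
  model <- occaTrain(ft)
  expect_identical(occaDecide(model, ft)$label,
                   as.character(featureLabels(ft)))
})
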