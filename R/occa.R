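# ---- helpers on feature tables -------------------------------------------

.featureColumns <- function(df) {
  setdiff(names(df), c("subject_id", "label"))
}

#' @describeIn occaTrain extract the numeric feature matrix from a
#'   labelled table (all columns except subject_id and label).
#' @export
featureMatrix <- function(df) {
  as.matrix(df[.featureColumns(df)])
}

#' @describeIn occaTrain extract the 0/1 label vector.
#' @export
featureLabels <- function(df) as.integer(df$label)

# ---- normalization and sphere lifting ------------------------------------

#' Min-max normalization parameters
#'
#' Fits per-dimension min and range on training rows.  A zero-range
#' (constant) dimension gets range 1 so it maps to the constant 0 instead
#' of dividing by zero.
#'
#' @param x numeric matrix of training feature rows.
#' @return list with numeric vectors \code{mins} and \code{ranges}.
#' @export
normalizeFit <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 1L) stop("empty feature table")
  mins <- apply(x, 2, min)
  ranges <- apply(x, 2, max) - mins
  ranges[ranges == 0] <- 1
  list(mins = mins, ranges = ranges)
}

#' @rdname normalizeFit
#' @param norm parameters from \code{normalizeFit}.
#' @param clip clamp the result into [0, 1] (used for unseen test rows).
#' @export
normalizeApply <- function(x, norm, clip = FALSE) {
  x <- as.matrix(x)
  out <- sweep(sweep(x, 2, norm$mins), 2, norm$ranges, "/")
  if (clip) out <- pmin(pmax(out, 0), 1)
  out
}

#' Lift a normalized feature vector onto the (n+1)-sphere
#'
#' T(x) = (x, sqrt(R^2 - |x|^2)): appends the coordinate that places the
#' point on the radius-R sphere, so all lifted samples have equal norm
#' and Euclidean distances on the sphere respect the original geometry.
#'
#' @param x numeric n-vector (or matrix of rows) with |x| <= R.
#' @param R lifting radius, at least the largest row norm.
#' @return numeric (n+1)-vector, or matrix of lifted rows.
#' @examples
#' sphereProject(c(0, 0), R = 1)  # (0, 0, 1)
#' @export
sphereProject <- function(x, R) {
  if (is.matrix(x)) return(t(apply(x, 1, sphereProject, R = R)))
  nrm2 <- sum(x^2)
  if (nrm2 > R^2 * (1 + 1e-12))
    stop("|x| = ", sqrt(nrm2), " exceeds lifting radius R = ", R)
  c(x, sqrt(max(R^2 - nrm2, 0)))
}

# lift with radial clipping for unseen points whose norm exceeds R
.liftClip <- function(x, R) {
  nrm <- sqrt(sum(x^2))
  if (nrm > R) x <- x * (R / nrm)
  sphereProject(x, R)
}

.rowDist <- function(m, v) sqrt(colSums((t(m) - v)^2))

# ---- cover construction ---------------------------------------------------

#' Cover radius against friendly and enemy points
#'
#' Given a candidate center on the sphere, let d1 be the distance to the
#' nearest opposite-class point (Inf if there is none) and d2 the
#' distance to the farthest same-class point closer than d1.  The
#' "midpoint" rule returns (d1 + d2)/2 — splitting the margin between the
#' last friend and the first enemy — and the "tight" rule returns d2.
#' Either way no enemy point falls within the radius and the center
#' itself (distance 0) is always covered.
#'
#' @param center numeric lifted center.
#' @param same matrix of lifted same-class points (rows), non-empty.
#' @param enemy matrix of lifted opposite-class points (rows), possibly
#'   zero rows.
#' @param mode "midpoint" or "tight".
#' @return nonnegative scalar radius.
#' @export
coverRadius <- function(center, same, enemy,
                        mode = c("midpoint", "tight")) {
  mode <- match.arg(mode)
  same <- rbind(same)
  if (nrow(same) < 1L) stop("need at least one same-class point")
  d1 <- if (is.null(enemy) || nrow(rbind(enemy)) == 0L) Inf
        else min(.rowDist(rbind(enemy), center))
  ds <- .rowDist(same, center)
  eligible <- ds[ds < d1]
  d2 <- if (length(eligible)) max(eligible) else 0
  if (!is.finite(d1)) return(d2)
  if (mode == "tight") d2 else (d1 + d2) / 2
}

#' Train a three-way covering classifier (optimal-center CCA)
#'
#' Features are min-max normalized, lifted onto an (n+1)-sphere of radius
#' R = max lifted-input norm, and greedily covered: while any training
#' sample is uncovered, take the uncovered samples of one class (class 0
#' first, then alternating), choose as center the sample nearest the
#' uncovered-set mean (in lifted coordinates; ties to the lowest row
#' index), set its radius with [coverRadius()] against all
#' opposite-class samples, and mark the in-radius same-class samples as
#' covered.  Every sample ends up in a cover of its own class and no
#' sample lies strictly inside an opposite-class cover.
#'
#' @param features labelled data.frame (columns subject_id, features,
#'   label) or numeric matrix.
#' @param labels 0/1 vector, required when \code{features} is a matrix.
#' @param radiusMode "midpoint" (default) or "tight", see [coverRadius()].
#' @return A \linkS4class{CoverModel}.
#' @seealso [occaDecide()]
#' @export
occaTrain <- function(features, labels = NULL,
                      radiusMode = c("midpoint", "tight")) {
  radiusMode <- match.arg(radiusMode)
  if (is.data.frame(features)) {
    labels <- featureLabels(features)
    x <- featureMatrix(features)
  } else {
    x <- as.matrix(features)
  }
  labels <- as.integer(labels)
  if (length(labels) != nrow(x)) stop("labels must match feature rows")
  if (length(unique(labels)) < 2L)
    stop("need at least one sample of each class")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0 or 1")

  norm <- normalizeFit(x)
  z <- normalizeApply(x, norm)
  R <- max(sqrt(rowSums(z^2)))
  lifted <- sphereProject(z, R)

  dupConflict <- FALSE
  covered <- rep(FALSE, nrow(x))
  covers <- list()
  while (any(!covered)) {
    for (cls in c(0L, 1L)) {
      csetIdx <- which(!covered & labels == cls)
      if (!length(csetIdx)) next
      cset <- lifted[csetIdx, , drop = FALSE]
      mu <- colMeans(cset)
      dMu <- .rowDist(cset, mu)
      center <- cset[which.min(dMu), ]       # which.min: lowest index on ties
      enemy <- lifted[labels != cls, , drop = FALSE]
      theta <- coverRadius(center, cset, enemy, mode = radiusMode)
      if (theta == 0 && nrow(enemy) > 0 &&
          min(.rowDist(enemy, center)) == 0)
        dupConflict <- TRUE
      inCover <- .rowDist(cset, center) <= theta
      covered[csetIdx[inCover]] <- TRUE
      covers[[length(covers) + 1L]] <-
        list(center = unname(center), radius = theta, label = cls,
             memberCount = sum(inCover))
    }
  }
  if (dupConflict)
    warning("duplicate feature vectors with conflicting labels: ",
            "such points sit on zero-radius cover boundaries")
  new("CoverModel", covers = covers, featureMins = unname(norm$mins),
      featureRanges = unname(norm$ranges), R = R, radiusMode = radiusMode,
      featureNames = colnames(x) %||% paste0("f", seq_len(ncol(x))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Three-way decision for new feature vectors
#'
#' Each row is normalized with the training parameters, clipped into
#' [0, 1], lifted onto the training sphere (radially clipped to R if its
#' norm exceeds R) and tested against every cover.  A point inside at
#' least one class-0 cover and no class-1 cover is accepted as class 0
#' (POS region); the mirror case is class 1 (NEG region); a point claimed
#' by both classes or by neither is deferred to the boundary (BND).
#'
#' @param model a \linkS4class{CoverModel}.
#' @param x numeric vector, matrix of rows, or labelled data.frame.
#' @return data.frame with columns \code{region} ("POS", "NEG", "BND",
#'   regions taken with respect to class 0) and \code{label} ("0", "1" or
#'   "boundary").
#' @export
occaDecide <- function(model, x) {
  stopifnot(is(model, "CoverModel"))
  if (is.data.frame(x)) x <- featureMatrix(x)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  n <- length(model@featureMins)
  if (ncol(x) != n)
    stop("expected ", n, " feature columns, got ", ncol(x))
  z <- normalizeApply(x, list(mins = model@featureMins,
                              ranges = model@featureRanges), clip = TRUE)
  labs <- vapply(model@covers, function(cv) cv$label, 0L)
  centers <- do.call(rbind, lapply(model@covers, `[[`, "center"))
  radii <- vapply(model@covers, `[[`, 0, "radius")
  out <- data.frame(region = character(nrow(x)), label = character(nrow(x)),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(x))) {
    p <- .liftClip(z[i, ], model@R)
    d <- .rowDist(centers, p)
    inside <- d <= radii
    in0 <- any(inside & labs == 0L)
    in1 <- any(inside & labs == 1L)
    if (in0 && !in1)      { out$region[i] <- "POS"; out$label[i] <- "0" }
    else if (in1 && !in0) { out$region[i] <- "NEG"; out$label[i] <- "1" }
    else                  { out$region[i] <- "BND"; out$label[i] <- "boundary" }
  }
  out
}

#' @describeIn occaDecide \code{predict} method returning just the label
#'   tokens "0", "1" or "boundary".
#' @param object a CoverModel.
#' @param newdata features to classify.
#' @param ... ignored.
#' @export
setMethod("predict", "CoverModel", function(object, newdata, ...) {
  occaDecide(object, newdata)$label
})

setMethod("show", "CoverModel", function(object) {
  labs <- vapply(object@covers, function(cv) cv$label, 0L)
  cat(sprintf("CoverModel: %d covers (%d class-0, %d class-1), %s radius\n",
              length(object@covers), sum(labs == 0L), sum(labs == 1L),
              object@radiusMode))
  cat(sprintf("  %d features, lifting radius R = %.4g\n",
              length(object@featureMins), object@R))
})

#' Serialize / restore a CoverModel as versioned JSON
#'
#' @param model a \linkS4class{CoverModel}.
#' @param path JSON file path.
#' @return \code{readCoverModel}: the restored model; \code{writeCoverModel}:
#'   invisibly, \code{path}.
#' @export
writeCoverModel <- function(model, path) {
  stopifnot(is(model, "CoverModel"))
  doc <- list(
    format = "eegThreeWay-covermodel", version = 1L,
    radiusMode = model@radiusMode, R = model@R,
    featureNames = model@featureNames,
    featureMins = model@featureMins, featureRanges = model@featureRanges,
    covers = lapply(model@covers, function(cv)
      list(center = cv$center, radius = cv$radius, label = cv$label,
           memberCount = cv$memberCount))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCoverModel
#' @export
readCoverModel <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "eegThreeWay-covermodel"))
    stop("not a cover-model document: ", path)
  covers <- if (is.data.frame(doc$covers)) {
    lapply(seq_len(nrow(doc$covers)), function(i)
      list(center = unlist(doc$covers$center[i]),
           radius = doc$covers$radius[i],
           label = as.integer(doc$covers$label[i]),
           memberCount = as.integer(doc$covers$memberCount[i])))
  } else {
    lapply(doc$covers, function(cv)
      list(center = unlist(cv$center), radius = cv$radius,
           label = as.integer(cv$label),
           memberCount = as.integer(cv$memberCount)))
  }
  new("CoverModel", covers = covers,
      featureMins = as.numeric(doc$featureMins),
      featureRanges = as.numeric(doc$featureRanges),
      R = as.numeric(doc$R), radiusMode = doc$radiusMode,
      featureNames = as.character(doc$featureNames))
}
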