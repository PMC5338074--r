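#' Build an EvalReport from confusion counts
#'
#' Acc = CCI/SI, Err = ECI/SI, Bnd = BI/SI, where SI is the number of
#' evaluated instances, CCI those correctly classified (POS of their own
#' class), ECI those classified as the opposite class, and BI those
#' deferred to the boundary region.
#'
#' @param SI total instances (> 0).
#' @param CCI,ECI,BI correct / erroneous / boundary counts; must sum to
#'   SI.
#' @param meta optional provenance list.
#' @return An \linkS4class{EvalReport}.
#' @examples
#' metricsFromCounts(42, 39, 2, 1)  # Acc 92.86%, Err 4.76%, Bnd 2.38%
#' @export
metricsFromCounts <- function(SI, CCI, ECI, BI, meta = list()) {
  SI <- as.integer(SI); CCI <- as.integer(CCI)
  ECI <- as.integer(ECI); BI <- as.integer(BI)
  if (SI <= 0L) stop("SI must be positive")
  if (any(c(CCI, ECI, BI) < 0L)) stop("counts must be nonnegative")
  if (CCI + ECI + BI != SI)
    stop("inconsistent counts: CCI + ECI + BI = ", CCI + ECI + BI,
         " but SI = ", SI)
  new("EvalReport", SI = SI, CCI = CCI, ECI = ECI, BI = BI,
      acc = CCI / SI, err = ECI / SI, bnd = BI / SI, meta = meta)
}

#' @describeIn metricsFromCounts ratio rendered as a percentage rounded
#'   half-up to 2 decimals (the convention of the reported tables).
#' @param ratio value in [0, 1].
#' @export
percentValue <- function(ratio) floor(ratio * 10000 + 0.5) / 100

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: SI=%d  CCI=%d  ECI=%d  BI=%d\n",
              object@SI, object@CCI, object@ECI, object@BI))
  cat(sprintf("  Acc %.2f%%   Err %.2f%%   Bnd %.2f%%\n",
              percentValue(object@acc), percentValue(object@err),
              percentValue(object@bnd)))
  if (length(object@meta))
    cat("  meta:", paste(names(object@meta), unlist(lapply(
      object@meta, function(v) paste(format(v), collapse = "/"))),
      sep = "=", collapse = "  "), "\n")
})

#' @describeIn metricsFromCounts serialize a report (counts, ratios and
#'   meta) as JSON.
#' @param report an EvalReport.
#' @param path output file, or NULL to return the JSON string.
#' @export
writeEvalReport <- function(report, path = NULL) {
  doc <- list(SI = report@SI, CCI = report@CCI, ECI = report@ECI,
              BI = report@BI, acc = report@acc, err = report@err,
              bnd = report@bnd,
              acc_pct = percentValue(report@acc),
              err_pct = percentValue(report@err),
              bnd_pct = percentValue(report@bnd),
              meta = report@meta)
  if (is.null(path))
    return(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# run body with a private RNG stream, restoring the caller's stream
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Stratified k-fold split
#'
#' Partitions 1..n into k folds, stratified by label: within each class
#' the shuffled members are dealt round-robin, with a single dealing
#' pointer continuing across classes so fold sizes stay within one of
#' each other.  Deterministic given the seed.
#'
#' @param n number of samples.
#' @param k number of folds (2 <= k <= n).
#' @param labels class labels, length n.
#' @param seed RNG seed for the within-class shuffles.
#' @return list of k disjoint integer index vectors covering 1..n.
#' @export
kfoldSplit <- function(n, k, labels, seed = 1L) {
  if (k < 2L) stop("k must be >= 2")
  if (k > n) stop("k must be <= n")
  if (length(labels) != n) stop("labels must have length n")
  folds <- vector("list", k)
  .withSeed(seed, {
    ptr <- 0L
    for (cls in sort(unique(labels))) {
      members <- which(labels == cls)
      members <- members[sample.int(length(members))]
      for (m in members) {
        f <- (ptr %% k) + 1L
        folds[[f]] <- c(folds[[f]], m)
        ptr <- ptr + 1L
      }
    }
  })
  folds
}

# ---- classifier contract --------------------------------------------------

#' Classifier contracts for cross-validated evaluation
#'
#' A classifier is a list with fields \code{name}, \code{fit(features)}
#' returning a fitted object, and \code{predict(fit, features)} returning
#' one token per row from \{"0", "1", "boundary"\}.  Binary baselines
#' never emit "boundary"; only the three-way covering classifier
#' abstains.
#'
#' \code{occaClassifier} wraps [occaTrain()]/[occaDecide()].
#' \code{dummyClassifier} provides degenerate references: "abstain"
#' always defers, "flip" predicts the opposite of the training majority
#' label, "majority" predicts the training majority.
#' \code{baselineClassifier} adapts established binary implementations
#' (comparison only, internals not re-implemented): "svm" and "nb" from
#' e1071, "knn" from class, "rf" from randomForest.
#'
#' @param radiusMode passed to [occaTrain()].
#' @return a classifier contract list.
#' @export
occaClassifier <- function(radiusMode = "midpoint") {
  list(name = paste0("occa-", radiusMode),
       fit = function(features) occaTrain(features, radiusMode = radiusMode),
       predict = function(fit, features) occaDecide(fit, features)$label)
}

#' @rdname occaClassifier
#' @param type dummy behaviour: "abstain", "flip" or "majority".
#' @export
dummyClassifier <- function(type = c("abstain", "flip", "majority")) {
  type <- match.arg(type)
  list(name = paste0("dummy-", type),
       fit = function(features) {
         lab <- featureLabels(features)
         maj <- if (sum(lab == 1L) > sum(lab == 0L)) "1" else "0"
         list(majority = maj, flipped = if (maj == "0") "1" else "0")
       },
       predict = function(fit, features) {
         n <- nrow(features)
         switch(type,
                abstain = rep("boundary", n),
                flip = rep(fit$flipped, n),
                majority = rep(fit$majority, n))
       })
}

#' @rdname occaClassifier
#' @param method "svm", "knn", "nb" or "rf".
#' @param ... passed to the underlying implementation.
#' @export
baselineClassifier <- function(method = c("svm", "knn", "nb", "rf"), ...) {
  method <- match.arg(method)
  pkg <- switch(method, svm = "e1071", nb = "e1071", knn = "class",
                rf = "randomForest")
  if (!requireNamespace(pkg, quietly = TRUE))
    stop("baseline '", method, "' needs package ", pkg)
  fit <- switch(method,
    svm = function(features)
      e1071::svm(x = featureMatrix(features),
                 y = factor(featureLabels(features), c(0, 1)), ...),
    nb = function(features)
      e1071::naiveBayes(x = as.data.frame(featureMatrix(features)),
                        y = factor(featureLabels(features), c(0, 1)), ...),
    rf = function(features)
      randomForest::randomForest(
        x = featureMatrix(features),
        y = factor(featureLabels(features), c(0, 1)), ...),
    knn = function(features)
      list(train = featureMatrix(features),
           cl = factor(featureLabels(features), c(0, 1)))
  )
  pred <- switch(method,
    svm = function(f, features)
      as.character(predict(f, featureMatrix(features))),
    nb = function(f, features)
      as.character(predict(f, as.data.frame(featureMatrix(features)))),
    rf = function(f, features)
      as.character(predict(f, featureMatrix(features))),
    knn = function(f, features)
      as.character(class::knn(train = f$train, test = featureMatrix(features),
                              cl = f$cl, ...))
  )
  list(name = method, fit = fit, predict = pred)
}

#' Cross-validated three-way evaluation
#'
#' Stratified k-fold cross-validation: for each fold, the classifier is
#' fitted on the remaining folds and the held-out rows are decided;
#' predictions are pooled over folds into the confusion counts CCI
#' (prediction equals the true label), ECI (opposite label) and BI
#' (boundary), and summarized with [metricsFromCounts()].
#'
#' @param features labelled data.frame (subject_id, features, label).
#' @param classifier a contract from [occaClassifier()],
#'   [dummyClassifier()] or [baselineClassifier()].
#' @param k number of folds (default 10).
#' @param seed fold-assignment seed.
#' @return An \linkS4class{EvalReport} with provenance in \code{meta}.
#' @export
evaluateCV <- function(features, classifier, k = 10L, seed = 1L) {
  labels <- featureLabels(features)
  n <- nrow(features)
  folds <- kfoldSplit(n, k, labels, seed)
  CCI <- ECI <- BI <- 0L
  for (f in folds) {
    fit <- classifier$fit(features[-f, , drop = FALSE])
    pred <- classifier$predict(fit, features[f, , drop = FALSE])
    if (!all(pred %in% c("0", "1", "boundary")))
      stop("classifier '", classifier$name,
           "' emitted tokens outside {0, 1, boundary}: ",
           paste(unique(setdiff(pred, c("0", "1", "boundary"))),
                 collapse = ", "))
    truth <- as.character(labels[f])
    BI <- BI + sum(pred == "boundary")
    CCI <- CCI + sum(pred != "boundary" & pred == truth)
    ECI <- ECI + sum(pred != "boundary" & pred != truth)
  }
  metricsFromCounts(n, CCI, ECI, BI,
                    meta = list(classifier = classifier$name, k = k,
                                seed = seed, n = n))
}
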