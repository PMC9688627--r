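# Data-driven selection of time-window span, key electrode group and
# feature combination, all scored with a standardized logistic-regression
# baseline under stratified k-fold cross-validation and compared with
# paired fold-wise t-tests.

#' Cross-validation result container
#'
#' @param unit identifier of the evaluated unit (a span, region,
#'   combination or classifier name).
#' @param scores per-fold accuracies in [0, 1].
#' @return list of class `CVResult` with `unit`, `scores`, `mean`, `sd`.
#' @export
cvResult <- function(unit, scores) {
  structure(list(unit = unit, scores = as.numeric(scores),
                 mean = mean(scores), sd = sd(scores)),
            class = "CVResult")
}

#' @export
print.CVResult <- function(x, ...) {
  cat(sprintf("CVResult %s: %.3f (+/- %.4f) over %d folds\n",
              x$unit, x$mean, x$sd, length(x$scores)))
  invisible(x)
}

#' Tabulate a list of CVResults
#' @param results list of `CVResult`.
#' @return data.frame with `unit`, `mean`, `sd`, `k`.
#' @export
cvTable <- function(results) {
  data.frame(unit = vapply(results, function(r) as.character(r$unit),
                           character(1)),
             mean = vapply(results, `[[`, numeric(1), "mean"),
             sd = vapply(results, `[[`, numeric(1), "sd"),
             k = vapply(results, function(r) length(r$scores),
                        integer(1)),
             stringsAsFactors = FALSE)
}

#' Selection configuration
#'
#' @param spans candidate spans in seconds, strictly increasing
#'   (default 1, 3, ..., 17).
#' @param kFolds folds for every cross-validated baseline (default 10).
#' @param baselineFeatures the two exploratory features (default
#'   Higuchi + SampEnt).
#' @param alpha significance level for the paired t-tests.
#' @param seed fold seed.
#' @return list of class `SelectionConfig`.
#' @export
selectionConfig <- function(spans = seq(1, 17, by = 2), kFolds = 10,
                            baselineFeatures = c("Higuchi", "SampEnt"),
                            alpha = 0.05, seed = 1L) {
  stopifnot(length(spans) >= 1, all(diff(spans) > 0), kFolds >= 2,
            alpha > 0, alpha < 1)
  structure(list(spans = spans, kFolds = as.integer(kFolds),
                 baselineFeatures = baselineFeatures, alpha = alpha,
                 seed = as.integer(seed)),
            class = "SelectionConfig")
}

#' Stratified fold assignment
#'
#' Shuffles within each class (seeded) and deals fold labels
#' round-robin, so every fold contains every class.
#'
#' @param y class labels.
#' @param k number of folds.
#' @param seed seed.
#' @return integer vector of fold ids in 1..k.
#' @export
stratifiedFolds <- function(y, k, seed = 1L) {
  if (min(table(y)) < k)
    stop("stratification error: a class has fewer than k = ", k,
         " members, some fold would miss it")
  set.seed(seed)
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# paired fold-wise t-test p-value; identical scores give 1 (no
# evidence of a difference), a constant nonzero difference gives 0
.pairedP <- function(a, b) {
  d <- a - b
  if (isTRUE(all.equal(var(d), 0)) || var(d) == 0)
    return(if (mean(d) == 0) 1 else 0)
  t.test(a, b, paired = TRUE)$p.value
}

# standardized logistic-regression CV accuracies (scaler fit per
# training fold)
.cvAccuracyLR <- function(X, y, folds) {
  X <- as.matrix(X)
  vapply(sort(unique(folds)), function(fold) {
    te <- folds == fold
    sc <- .fitScaler(X[!te, , drop = FALSE])
    Xtr <- .applyScaler(X[!te, , drop = FALSE], sc)
    Xte <- .applyScaler(X[te, , drop = FALSE], sc)
    df <- data.frame(y = y[!te], Xtr)
    fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
    p <- suppressWarnings(
      predict(fit, newdata = as.data.frame(Xte), type = "response"))
    mean((p > 0.5) == y[te])
  }, numeric(1))
}

#' Sweep candidate time-window spans
#'
#' For each span, windows 1..span of every subject are scored with the
#' two baseline features averaged over all montage channels and a
#' standardized LR under stratified k-fold CV. Identical seed gives
#' identical folds.
#'
#' @param cohort list of [EEGRecording-class] objects, or NULL if
#'   `chanFeat` is given.
#' @param config a [selectionConfig()].
#' @param chanFeat optional precomputed [channelFeatures()] table at
#'   max(spans); windows are identical across spans (consecutive 1 s
#'   windows after the trigger), so the sweep only subsets it.
#' @param params [featureParams()] used if `chanFeat` is NULL.
#' @return list of `CVResult`, one per span (unit = the span).
#' @export
sweepSpans <- function(cohort, config = selectionConfig(),
                       chanFeat = NULL, params = featureParams()) {
  if (is.null(chanFeat))
    chanFeat <- channelFeatures(cohort, max(config$spans), params)
  fv <- featureVectors(chanFeat, features = config$baselineFeatures)
  lapply(config$spans, function(span) {
    sub <- fv[fv$window <= span, , drop = FALSE]
    folds <- stratifiedFolds(sub$y, config$kFolds, config$seed)
    cvResult(span, .cvAccuracyLR(sub[, config$baselineFeatures],
                                 sub$y, folds))
  })
}

#' Choose the span: smallest not significantly worse than any larger
#'
#' Returns the smallest span whose fold scores are not significantly
#' lower (paired t-test at `alpha`) than those of every larger span;
#' ties break toward the smaller span.
#'
#' @param results list of `CVResult` from [sweepSpans()].
#' @param alpha significance level.
#' @return the chosen span (seconds).
#' @export
chooseSpan <- function(results, alpha = 0.05) {
  spans <- vapply(results, `[[`, numeric(1), "unit")
  ord <- order(spans)
  results <- results[ord]
  spans <- spans[ord]
  for (i in seq_along(spans)) {
    worse <- FALSE
    for (j in seq_along(spans)) {
      if (spans[j] <= spans[i]) next
      p <- .pairedP(results[[i]]$scores, results[[j]]$scores)
      if (p < alpha && results[[i]]$mean < results[[j]]$mean) {
        worse <- TRUE
        break
      }
    }
    if (!worse) return(spans[i])
  }
  spans[length(spans)]
}

#' Sweep Desikan regions at a fixed span
#'
#' One cross-validated baseline per region whose electrodes are all
#' present in the montage, using the two baseline features averaged
#' over the region's electrodes. Folds are identical across regions.
#'
#' @param cohort cohort list, or NULL if `chanFeat` is given.
#' @param span the chosen span (seconds).
#' @param regionMap region -> electrodes map (default the shipped
#'   table).
#' @param config a [selectionConfig()].
#' @param chanFeat optional precomputed [channelFeatures()] table.
#' @param params [featureParams()] used if `chanFeat` is NULL.
#' @return list of `CVResult`, one per usable region (unit = region
#'   name).
#' @export
sweepRegions <- function(cohort, span, regionMap = desikanRegionMap(),
                         config = selectionConfig(), chanFeat = NULL,
                         params = featureParams()) {
  if (is.null(chanFeat))
    chanFeat <- channelFeatures(cohort, span, params)
  chanFeat <- chanFeat[chanFeat$window <= span, , drop = FALSE]
  have <- unique(toupper(chanFeat$channel))
  usable <- names(regionMap)[vapply(regionMap, function(el)
    all(toupper(canonicalizeLabels(el)) %in% have), logical(1))]
  if (length(usable) == 0)
    stop("no region of the map is fully covered by the montage")
  foldsRef <- NULL
  lapply(usable, function(rg) {
    fv <- featureVectors(chanFeat, electrodes = regionMap[[rg]],
                         features = config$baselineFeatures)
    if (is.null(foldsRef))
      foldsRef <<- stratifiedFolds(fv$y, config$kFolds, config$seed)
    cvResult(rg, .cvAccuracyLR(fv[, config$baselineFeatures], fv$y,
                               foldsRef))
  })
}

#' Choose the region: best mean, parsimony on ties
#'
#' The region with the highest mean accuracy wins; every region not
#' significantly different from it (paired t-test at `alpha`) is a
#' candidate, and among candidates the one with the fewest electrodes
#' (then lexicographically first) is returned.
#'
#' @param results list of `CVResult` from [sweepRegions()].
#' @param regionMap region -> electrodes map (for electrode counts).
#' @param alpha significance level.
#' @return the chosen region name.
#' @export
chooseRegion <- function(results, regionMap = desikanRegionMap(),
                         alpha = 0.05) {
  stopifnot(length(results) >= 1)
  means <- vapply(results, `[[`, numeric(1), "mean")
  best <- which.max(means)
  cand <- vapply(seq_along(results), function(i) {
    i == best ||
      .pairedP(results[[i]]$scores, results[[best]]$scores) >= alpha
  }, logical(1))
  units <- vapply(results, function(r) as.character(r$unit),
                  character(1))
  nel <- vapply(units, function(u) length(regionMap[[u]]), integer(1))
  pool <- which(cand)
  pool <- pool[order(nel[pool], units[pool])]
  units[pool[1]]
}

#' Rank features by mutual information with the class label
#'
#' A k-nearest-neighbour estimator for continuous features against a
#' discrete target (Kraskov-style, with the class-conditional neighbour
#' radius construction): for each sample, the distance to its k-th
#' neighbour within the same class defines a radius, and the number of
#' points of any class inside it enters the digamma estimator. A tiny
#' seeded jitter breaks ties, making the estimator deterministic given
#' the seed; constant features get MI 0 and rank last. MI is reported
#' in nats and clipped at 0.
#'
#' @param featVec data.frame with feature columns and `y`, or a
#'   numeric matrix plus `labels`.
#' @param labels binary labels (taken from `featVec$y` if missing).
#' @param k neighbour count (default 3).
#' @param seed jitter seed.
#' @param features feature columns to rank.
#' @return data.frame with `feature` and `mi`, sorted by decreasing MI
#'   (ties in canonical feature order).
#' @export
rankFeaturesMI <- function(featVec, labels = NULL, k = 3, seed = 1L,
                           features = NULL) {
  if (is.null(features))
    features <- intersect(featureNames(), colnames(featVec))
  if (length(features) == 0)
    features <- setdiff(colnames(featVec), c("subject", "window", "y"))
  if (is.null(labels)) labels <- featVec$y
  stopifnot(length(unique(labels)) >= 2)
  mi <- vapply(features, function(f)
    .miKnnCd(as.numeric(featVec[[f]]), labels, k = k, seed = seed),
    numeric(1))
  ord <- order(-mi, match(features, featureNames()), features)
  data.frame(feature = features[ord], mi = mi[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}

.miKnnCd <- function(x, y, k = 3, seed = 1L) {
  n <- length(x)
  if (var(x) == 0) return(0)
  set.seed(seed)
  x <- x + rnorm(n, sd = 1e-10 * max(sd(x), .Machine$double.eps))
  D <- abs(outer(x, x, "-"))
  diag(D) <- Inf
  radius <- numeric(n)
  kUse <- integer(n)
  for (i in seq_len(n)) {
    same <- which(y == y[i])
    same <- same[same != i]
    ki <- min(k, length(same))
    kUse[i] <- ki
    radius[i] <- sort(D[i, same], partial = ki)[ki]
  }
  # neighbour counts within the radius include the point itself
  m <- vapply(seq_len(n), function(i) 1 + sum(D[i, ] < radius[i]),
              numeric(1))
  ny <- as.numeric(table(y)[as.character(y)])
  mi <- digamma(n) + mean(digamma(kUse)) - mean(digamma(ny)) -
    mean(digamma(pmax(m, 1)))
  max(mi, 0)
}

#' Evaluate cumulative feature combinations COMB0..COMB5
#'
#' Prefixes of the mutual-information ranking are scored with the
#' standardized LR baseline under identical stratified folds. The
#' selected combination is the full set unless a shorter prefix is
#' significantly better (paired t-test at `alpha`), in which case the
#' shortest such prefix wins.
#'
#' @param ranked character vector of feature names in ranking order
#'   (or the data.frame from [rankFeaturesMI()]).
#' @param featVec feature table from [featureVectors()] restricted to
#'   the selected electrodes and span.
#' @param config a [selectionConfig()].
#' @return list with `results` (named list of `CVResult`, units
#'   COMB0..COMB5), `selected` (combination name) and `features`
#'   (character vector of the selected combination).
#' @export
greedyCombinations <- function(ranked, featVec,
                               config = selectionConfig()) {
  if (is.data.frame(ranked)) ranked <- ranked$feature
  folds <- stratifiedFolds(featVec$y, config$kFolds, config$seed)
  results <- lapply(seq_along(ranked), function(i) {
    feats <- ranked[seq_len(i)]
    cvResult(paste0("COMB", i - 1L),
             .cvAccuracyLR(featVec[, feats, drop = FALSE], featVec$y,
                           folds))
  })
  names(results) <- vapply(results, `[[`, character(1), "unit")
  full <- results[[length(results)]]
  sel <- length(results)
  for (i in seq_len(length(results) - 1L)) {
    p <- .pairedP(results[[i]]$scores, full$scores)
    if (p < config$alpha && results[[i]]$mean > full$mean) {
      sel <- i
      break
    }
  }
  list(results = results, selected = names(results)[sel],
       features = ranked[seq_len(sel)])
}

#' Run the full selection chain
#'
#' Span sweep -> span choice -> region sweep at the chosen span ->
#' region choice -> mutual-information ranking of the six features on
#' the chosen electrodes -> combination evaluation. Per-channel
#' features are computed once at the largest candidate span and reused
#' by every stage.
#'
#' @param cohort list of [EEGRecording-class] objects.
#' @param config a [selectionConfig()].
#' @param regionMap region -> electrode map.
#' @param params [featureParams()].
#' @param chanFeat optional precomputed [channelFeatures()] table at
#'   max(config$spans).
#' @return list of class `SelectionReport`: chosen `span`, `region`,
#'   `electrodes`, `combination`, `features`, `miRanking`, and the CV
#'   tables `spanResults`, `regionResults`, `combResults`.
#' @export
runSelection <- function(cohort, config = selectionConfig(),
                         regionMap = desikanRegionMap(),
                         params = featureParams(), chanFeat = NULL) {
  if (is.null(chanFeat))
    chanFeat <- channelFeatures(cohort, max(config$spans), params)
  spanRes <- sweepSpans(NULL, config, chanFeat = chanFeat)
  span <- chooseSpan(spanRes, config$alpha)
  regRes <- sweepRegions(NULL, span, regionMap, config,
                         chanFeat = chanFeat)
  region <- chooseRegion(regRes, regionMap, config$alpha)
  electrodes <- regionMap[[region]]
  fv <- featureVectors(chanFeat[chanFeat$window <= span, ,
                                drop = FALSE],
                       electrodes = electrodes)
  mi <- rankFeaturesMI(fv, seed = config$seed)
  comb <- greedyCombinations(mi, fv, config)
  structure(list(span = span, region = region, electrodes = electrodes,
                 combination = comb$selected, features = comb$features,
                 miRanking = mi, spanResults = spanRes,
                 regionResults = regRes, combResults = comb$results,
                 config = config),
            class = "SelectionReport")
}

#' @export
print.SelectionReport <- function(x, ...) {
  cat("Selection report\n")
  cat("  span:", x$span, "s\n")
  cat("  region:", x$region, "(",
      paste(x$electrodes, collapse = ", "), ")\n")
  cat("  combination:", x$combination, "=",
      paste(x$features, collapse = " + "), "\n")
  invisible(x)
}
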