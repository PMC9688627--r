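# Span / region / feature-combination selection: fold construction,
# decision rules on constructed scores, the MI estimator, and
# ground-truth recovery on synthetic cohorts.

test_that("stratified folds keep every class in every fold, deterministically", {
  y <- rep(c(0, 1), c(30, 24))
  f1 <- stratifiedFolds(y, 10, seed = 3)
  f2 <- stratifiedFolds(y, 10, seed = 3)
  expect_identical(f1, f2)
  expect_setequal(unique(f1), 1:10)
  for (k in 1:10) expect_setequal(unique(y[f1 == k]), c(0, 1))
  expect_false(identical(stratifiedFolds(y, 10, seed = 4), f1))
  expect_error(stratifiedFolds(rep(c(0, 1), c(3, 50)), 10),
               "stratification")
})

test_that("chooseSpan returns the smallest non-inferior span", {
  set.seed(5)
  mk <- function(span, m, s = 0.002) cvResult(span, rnorm(10, m, s))
  # plateau from 15 s: every shorter span significantly below 15/17
  plateau <- list(mk(9, 0.80), mk(11, 0.85), mk(13, 0.90),
                  mk(15, 0.95), mk(17, 0.95))
  expect_equal(chooseSpan(plateau), 15)
  # identical scores everywhere: smallest span wins
  flat <- lapply(c(1, 5, 9), function(s) cvResult(s, rep(0.9, 10)))
  expect_equal(chooseSpan(flat), 1)
  # strictly improving with significance at every step: largest wins
  rising <- list(mk(1, 0.6), mk(3, 0.7), mk(5, 0.8), mk(7, 0.9))
  expect_equal(chooseSpan(rising), 7)
})

test_that("chooseRegion prefers fewer electrodes among statistical ties", {
  set.seed(6)
  tied <- list(cvResult("Lateral orbitofrontal", rnorm(10, 0.987, 0.01)),
               cvResult("Caudal anterior-cingulate",
                        rnorm(10, 0.987, 0.01)))
  expect_identical(chooseRegion(tied), "Caudal anterior-cingulate")
  expect_identical(chooseRegion(tied[2]), "Caudal anterior-cingulate")
  # a clear winner wins regardless of electrode count
  clear <- list(cvResult("Caudal anterior-cingulate",
                         rnorm(10, 0.70, 0.005)),
                cvResult("Lateral orbitofrontal",
                         rnorm(10, 0.95, 0.005)))
  expect_identical(chooseRegion(clear), "Lateral orbitofrontal")
})

test_that("MI ranking: perfect dependence, independence, invariance", {
  set.seed(7)
  n <- 1000
  y <- rep(c(0, 1), each = n / 2)
  fv <- data.frame(PermEnt = as.numeric(y),       # feature == label
                   SampEnt = rnorm(n),            # independent noise
                   DFA = rep(1.3, n),             # constant
                   y = y)
  rk <- rankFeaturesMI(fv, features = c("PermEnt", "SampEnt", "DFA"))
  expect_identical(rk$feature[1], "PermEnt")
  expect_identical(rk$feature[3], "DFA")
  expect_equal(rk$mi[rk$feature == "PermEnt"], log(2), tolerance = 0.05)
  nullMI <- vapply(1:5, function(i) {
    fvN <- fv
    fvN$SampEnt <- rnorm(n)
    rankFeaturesMI(fvN, features = "SampEnt", seed = i)$mi
  }, numeric(1))
  expect_lte(mean(nullMI), 0.02)
  expect_identical(rk$mi[rk$feature == "DFA"], 0)

  # ranking is invariant to the order of the feature columns
  rk2 <- rankFeaturesMI(fv, features = c("DFA", "SampEnt", "PermEnt"))
  expect_equal(rk$mi[order(rk$feature)], rk2$mi[order(rk2$feature)])
  expect_identical(rk$feature, rk2$feature)
})

test_that("combination evaluation follows the cumulative COMB scheme", {
  set.seed(8)
  n <- 200
  y <- rep(c(0, 1), n / 2)
  fv <- data.frame(matrix(rnorm(n * 6), n, 6,
                          dimnames = list(NULL, featureNames())),
                   y = y)
  fv$PermEnt <- y + rnorm(n, sd = 0.1)          # one informative feature
  cfg <- selectionConfig(kFolds = 5)
  gc <- greedyCombinations(featureNames(), fv, cfg)
  expect_identical(names(gc$results), paste0("COMB", 0:5))
  expect_identical(gc$results$COMB5$unit, "COMB5")
  # COMB0 (the informative feature alone) is already within alpha of
  # the full set
  p <- t.test(gc$results$COMB0$scores, gc$results$COMB5$scores,
              paired = TRUE)$p.value
  expect_true(p >= cfg$alpha || gc$results$COMB0$mean >=
                gc$results$COMB5$mean)
  expect_gte(gc$results$COMB0$mean, 0.9)

  # all-noise features: every combination near chance
  fv$PermEnt <- rnorm(n)
  gcNull <- greedyCombinations(featureNames(), fv, cfg)
  for (r in gcNull$results)
    expect_true(r$mean >= 0.35 && r$mean <= 0.65)
})

test_that("span sweep returns one CVResult per span on a tiny cohort", {
  co <- effectCohort(nPerClass = 4, channels = c("FC2", "AFz", "F2"),
                     seed = 12)
  cfg <- selectionConfig(spans = c(1, 3, 5), kFolds = 3, seed = 12)
  res <- sweepSpans(co, cfg)
  expect_length(res, 3)
  expect_identical(vapply(res, `[[`, numeric(1), "unit"), c(1, 3, 5))
  expect_true(all(vapply(res, function(r) length(r$scores), integer(1))
                  == 3))
  # identical seed reproduces identical scores
  res2 <- sweepSpans(co, cfg)
  expect_identical(lapply(res, `[[`, "scores"),
                   lapply(res2, `[[`, "scores"))
})

test_that("region sweep covers usable regions and recovers the effect site", {
  co <- effectCohort(nPerClass = 6, seed = 13)
  cfg <- selectionConfig(kFolds = 5, seed = 13)
  cf <- channelFeatures(co, 9)
  res <- sweepRegions(NULL, 9, config = cfg, chanFeat = cf)
  units <- vapply(res, function(r) as.character(r$unit), character(1))
  expect_true("Caudal anterior-cingulate" %in% units)
  expect_lte(length(res), 26)
  tab <- cvTable(res)
  expect_identical(tab$unit[which.max(tab$mean)],
                   "Caudal anterior-cingulate")
  expect_error(sweepRegions(NULL, 9, config = cfg,
                            chanFeat = cf[cf$channel == "Pz", ]),
               "no region")
})

test_that("null cohort region scores are mutually close and near chance", {
  co <- nullCohort(nPerClass = 8, seed = 14)
  cfg <- selectionConfig(kFolds = 5, seed = 14)
  cf <- channelFeatures(co, 9)
  tab <- cvTable(sweepRegions(NULL, 9, config = cfg, chanFeat = cf))
  expect_lte(max(tab$mean) - min(tab$mean), 0.15)
  expect_true(all(tab$mean >= 0.35 & tab$mean <= 0.65))
})

test_that("the selection chain recovers the planted ground truth across seeds", {
  hits <- 0L
  for (seed in 1:10) {
    co <- effectCohort(nPerClass = 8, seed = 100 + seed)
    cfg <- selectionConfig(spans = c(1, 5, 9, 15), kFolds = 5,
                           seed = seed)
    sel <- runSelection(co, cfg)
    ok <- sel$region == "Caudal anterior-cingulate" &&
      sel$span <= 15 &&
      any(c("DFA", "SpectEnt") %in% sel$features)
    hits <- hits + ok
  }
  expect_gte(hits, 9L)
})

test_that("selection is deterministic under a fixed seed", {
  co <- effectCohort(nPerClass = 5, channels = c("FC2", "AFz", "F2",
                                                 "PO3", "Pz", "POz"),
                     seed = 15)
  cfg <- selectionConfig(spans = c(1, 5), kFolds = 4, seed = 15)
  s1 <- runSelection(co, cfg)
  s2 <- runSelection(co, cfg)
  expect_identical(s1$span, s2$span)
  expect_identical(s1$region, s2$region)
  expect_identical(s1$miRanking, s2$miRanking)
  expect_identical(lapply(s1$combResults, `[[`, "scores"),
                   lapply(s2$combResults, `[[`, "scores"))
})
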