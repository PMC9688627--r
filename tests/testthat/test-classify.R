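# Classifier suite: architecture contracts, exact gradients, training
# behaviour, checkpointing and fold-matched comparison.

test_that("built architectures follow the stated layer sequences", {
  lstm <- buildModel(modelSpec("LSTM"))
  expect_identical(modelSummary(lstm)$type,
                   c("lstm", "lstm", "lstm", "lstm", "batchnorm",
                     "dense"))
  expect_equal(vapply(lstm$layers[1:4], `[[`, numeric(1), "units"),
               c(64, 64, 32, 32))
  last <- lstm$layers[[6]]
  expect_identical(last$act, "sigmoid")
  expect_identical(ncol(last$params$W), 1L)
  expect_gt(last$l2, 0)

  gru <- buildModel(modelSpec("CNNGRU"))
  expect_identical(modelSummary(gru)$type,
                   c("conv1d", "maxpool", "gru", "flatten", "dense"))
  expect_identical(gru$layers[[5]]$act, "sigmoid")

  expect_identical(modelSummary(buildModel(modelSpec("MLP")))$type,
                   c("flatten", "dense", "dense", "dense"))
  expect_identical(modelSummary(buildModel(modelSpec("CNN")))$type,
                   c("conv1d", "conv1d", "flatten", "dense"))
  expect_true(is.null(buildModel(modelSpec("LR"))$layers))
})

test_that("backpropagated gradients match numerical differentiation", {
  set.seed(20)
  configs <- list(
    list(kind = "MLP", hyper = list(units = c(4, 3))),
    list(kind = "CNN", hyper = list(filters = 3, kernel = 3)),
    list(kind = "LSTM", hyper = list(units = c(3, 2), l2 = 1e-3)),
    list(kind = "CNNGRU", hyper = list(filters = 3, kernel = 3,
                                       pool = 2, gruUnits = 3)))
  X <- array(rnorm(5 * 6), c(5, 6, 1))
  y <- c(0, 1, 1, 0, 1)
  for (cfg in configs) {
    m <- buildModel(modelSpec(cfg$kind, inputShape = c(6, 1),
                              hyper = cfg$hyper, seed = 21))
    lg <- restingEEG:::.nnLossGrads(m$layers, X, y, training = TRUE)
    for (li in seq_along(m$layers)) {
      ps <- m$layers[[li]]$params
      if (is.null(ps)) next
      for (nm in names(ps)) {
        idx <- seq_len(min(4, length(ps[[nm]])))
        num <- vapply(idx, function(ii) {
          eps <- 1e-6
          L <- m$layers
          L[[li]]$params[[nm]][ii] <- L[[li]]$params[[nm]][ii] + eps
          up <- restingEEG:::.nnLossGrads(L, X, y, training = TRUE)$loss
          L[[li]]$params[[nm]][ii] <- L[[li]]$params[[nm]][ii] - 2 * eps
          dn <- restingEEG:::.nnLossGrads(L, X, y, training = TRUE)$loss
          (up - dn) / (2 * eps)
        }, numeric(1))
        expect_equal(unname(lg$grads[[li]][[nm]][idx]), num,
                     tolerance = 1e-4,
                     label = paste(cfg$kind, "layer", li, nm))
      }
    }
  }
})

test_that("training separates separable data and records its history", {
  fv <- separableFeatures(n = 60, seed = 22)
  X <- as.matrix(fv[, featureNames()])
  tm <- trainModel(buildModel(modelSpec("MLP", seed = 22)), X, fv$y,
                   trainConfig(epochs = 100, batchSize = 16, seed = 22))
  expect_identical(nrow(tm$history), 100L)
  expect_identical(tm$bestEpoch, which.min(tm$history$valLoss))
  expect_gte(mean((predictProb(tm, X) > 0.5) == fv$y), 0.99)
})

test_that("label-shuffled data stay at chance on validation", {
  fv <- separableFeatures(n = 80, seed = 23)
  set.seed(23)
  yShuf <- sample(fv$y)
  tm <- trainModel(buildModel(modelSpec("MLP", seed = 23)),
                   as.matrix(fv[, featureNames()]), yShuf,
                   trainConfig(epochs = 30, batchSize = 16, seed = 23))
  acc <- tail(tm$history$valAcc, 1)
  expect_gte(acc, 0.35)
  expect_lte(acc, 0.65)
})

test_that("every deep architecture can overfit 32 samples", {
  set.seed(24)
  X <- matrix(rnorm(32 * 6), 32, 6,
              dimnames = list(NULL, featureNames()))
  y <- rep(c(0, 1), 16)
  tr <- setdiff(seq_len(32), restingEEG:::.stratSplit(y, 0.2, 25))
  for (kd in c("MLP", "CNN", "LSTM", "CNNGRU")) {
    tm <- trainModel(buildModel(modelSpec(kd, seed = 24)), X, y,
                     trainConfig(epochs = 300, batchSize = 8, lr = 3e-3,
                                 restoreBest = FALSE, seed = 25))
    p <- pmin(pmax(predictProb(tm, X[tr, ]), 1e-7), 1 - 1e-7)
    loss <- -mean(y[tr] * log(p) + (1 - y[tr]) * log(1 - p))
    expect_lt(loss, 0.05, label = paste(kd, "training loss"))
  }
})

test_that("checkpoint round trip reproduces bit-identical predictions", {
  fv <- separableFeatures(n = 40, seed = 26)
  X <- as.matrix(fv[, featureNames()])
  tm <- trainModel(buildModel(modelSpec("CNNGRU", seed = 26)), X, fv$y,
                   trainConfig(epochs = 5, seed = 26))
  f <- tempfile(fileext = ".rds")
  saveCheckpoint(tm, f)
  tm2 <- loadCheckpoint(f)
  expect_identical(predictProb(tm2, X), predictProb(tm, X))
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_identical(side$kind, "CNNGRU")
  expect_identical(length(side$history), 5L)   # one record per epoch
})

test_that("single-class training data are rejected", {
  X <- matrix(rnorm(60), 10, 6, dimnames = list(NULL, featureNames()))
  expect_error(trainModel(buildModel(modelSpec("MLP")), X, rep(1, 10)),
               "single class")
})

test_that("classifier comparison is fold-matched with a paired t matrix", {
  fv <- separableFeatures(n = 100, seed = 27)
  specs <- list(modelSpec("LR"), modelSpec("SVM_RBF"),
                modelSpec("MLP", seed = 27))
  cmp <- compareClassifiers(fv, specs, k = 5, seed = 27,
                            config = trainConfig(epochs = 30,
                                                 seed = 27))
  expect_length(cmp$results, 3)
  expect_identical(dim(cmp$pvalues), c(3L, 3L))
  expect_true(all(is.na(diag(cmp$pvalues))))
  expect_equal(cmp$pvalues[1, 2], cmp$pvalues[2, 1])
  for (r in cmp$results) {
    expect_length(r$scores, 5)
    expect_gte(r$mean, 0.9)        # separable construction
  }
  # identical specs on identical folds agree (p ~ 1 or undefined)
  cmp2 <- compareClassifiers(fv, list(modelSpec("LR"), modelSpec("LR")),
                             k = 5, seed = 27)
  expect_identical(cmp2$results[[1]]$scores, cmp2$results[[2]]$scores)
  p <- cmp2$pvalues[1, 2]
  expect_true(is.na(p) || p >= 0.999)
})
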