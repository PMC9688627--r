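# The classifier suite: LR and SVM-RBF via established fitters, and the
# tuned deep architectures (MLP, CNN, LSTM, CNNGRU) on the in-package
# network engine. Sequence models consume each 6-feature vector as a
# (timesteps = 6, channels = 1) sequence in the canonical feature order
# -- an explicit convention of this package, configurable via
# `inputShape`.

.DL_KINDS <- c("MLP", "CNN", "LSTM", "CNNGRU")

#' Classifier specification
#'
#' @param kind one of "LR", "SVM_RBF", "MLP", "CNN", "LSTM", "CNNGRU".
#' @param inputShape `(timesteps, channels)` of one sample for sequence
#'   models; default c(6, 1).
#' @param hyper named list overriding the defaults (hidden sizes,
#'   `l2`, SVM `cost`, ...).
#' @param seed integer seed for weight initialization.
#' @return list of class `ModelSpec`.
#' @export
modelSpec <- function(kind = c("LR", "SVM_RBF", "MLP", "CNN", "LSTM",
                               "CNNGRU"),
                      inputShape = c(6, 1), hyper = list(), seed = 1L) {
  kind <- match.arg(kind)
  def <- switch(kind,
    LR = list(),
    SVM_RBF = list(cost = 1),
    MLP = list(units = c(64, 32)),
    CNN = list(filters = 32, kernel = 3),
    LSTM = list(units = c(64, 64, 32, 32), l2 = 1e-3),
    CNNGRU = list(filters = 32, kernel = 3, pool = 2, gruUnits = 32))
  def[names(hyper)] <- hyper
  structure(list(kind = kind, inputShape = as.integer(inputShape),
                 hyper = def, seed = as.integer(seed)),
            class = "ModelSpec")
}

#' Training configuration
#'
#' @param epochs training epochs (default 100).
#' @param batchSize minibatch size (default 32).
#' @param validationFraction fraction held out for validation
#'   (default 0.2; in (0, 1)).
#' @param lr,beta1,beta2 Adam hyperparameters.
#' @param restoreBest restore the weights of the epoch with the lowest
#'   validation loss (default TRUE); FALSE keeps the final weights.
#' @param seed seed for the split and the shuffles.
#' @return list of class `TrainConfig`.
#' @export
trainConfig <- function(epochs = 100, batchSize = 32,
                        validationFraction = 0.2, lr = 1e-3,
                        beta1 = 0.9, beta2 = 0.999,
                        restoreBest = TRUE, seed = 1L) {
  stopifnot(validationFraction > 0, validationFraction < 1, epochs >= 1)
  structure(list(epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize),
                 validationFraction = validationFraction,
                 lr = lr, beta1 = beta1, beta2 = beta2,
                 restoreBest = isTRUE(restoreBest),
                 seed = as.integer(seed)),
            class = "TrainConfig")
}

#' Build an untrained model from a specification
#'
#' Layer sequences of the deep models:
#' \itemize{
#'   \item LSTM: four stacked LSTM layers (64/64/32/32 units), batch
#'     normalization, dense(1, sigmoid) with an L2 kernel regularizer.
#'   \item CNNGRU: Conv1D (32 filters, kernel 3, ReLU), max-pooling
#'     (2), GRU (32, returning sequences), flatten, dense(1, sigmoid).
#'   \item MLP: dense 64 and 32 (ReLU), dense(1, sigmoid).
#'   \item CNN: two Conv1D(32, 3, ReLU) blocks, flatten,
#'     dense(1, sigmoid).
#' }
#' LR is a standardized logistic regression (glm) and SVM_RBF a
#' radial-kernel support vector machine (C = 1); both are fitted lazily
#' at [trainModel()] time.
#'
#' @param spec a [modelSpec()].
#' @return list of class `NNModel` with elements `spec` and (for deep
#'   kinds) `layers`.
#' @export
buildModel <- function(spec) {
  stopifnot(inherits(spec, "ModelSpec"))
  if (!spec$kind %in% .DL_KINDS)
    return(structure(list(spec = spec, layers = NULL),
                     class = "NNModel"))
  set.seed(spec$seed)
  Tn <- spec$inputShape[1]
  Cn <- spec$inputShape[2]
  h <- spec$hyper
  layers <- switch(spec$kind,
    MLP = c(list(.layerFlatten()),
            local({
              inF <- Tn * Cn
              ls <- list()
              for (u in h$units) {
                ls <- c(ls, list(.layerDense(inF, u, "relu")))
                inF <- u
              }
              c(ls, list(.layerDense(inF, 1, "sigmoid")))
            })),
    CNN = {
      t1 <- Tn - h$kernel + 1L
      t2 <- t1 - h$kernel + 1L
      list(.layerConv1d(Cn, h$filters, h$kernel),
           .layerConv1d(h$filters, h$filters, h$kernel),
           .layerFlatten(),
           .layerDense(t2 * h$filters, 1, "sigmoid"))
    },
    LSTM = {
      u <- h$units
      ls <- list()
      inC <- Cn
      for (i in seq_along(u)) {
        ls <- c(ls, list(.layerLSTM(inC, u[i],
                                    returnSeq = i < length(u))))
        inC <- u[i]
      }
      c(ls, list(.layerBatchNorm(u[length(u)]),
                 .layerDense(u[length(u)], 1, "sigmoid", l2 = h$l2)))
    },
    CNNGRU = {
      t1 <- Tn - h$kernel + 1L
      t2 <- t1 %/% h$pool
      list(.layerConv1d(Cn, h$filters, h$kernel),
           .layerMaxPool(h$pool),
           .layerGRU(h$filters, h$gruUnits, returnSeq = TRUE),
           .layerFlatten(),
           .layerDense(t2 * h$gruUnits, 1, "sigmoid"))
    })
  structure(list(spec = spec, layers = layers), class = "NNModel")
}

#' Layer-by-layer parameter counts
#' @param model an `NNModel` from [buildModel()].
#' @return data.frame with `layer`, `type` and `n_params`.
#' @export
modelSummary <- function(model) {
  if (is.null(model$layers))
    return(data.frame(layer = 1L, type = model$spec$kind,
                      n_params = NA_integer_))
  data.frame(
    layer = seq_along(model$layers),
    type = vapply(model$layers, `[[`, character(1), "type"),
    n_params = vapply(model$layers, function(l)
      sum(vapply(l$params, length, integer(1))), integer(1)))
}

.toSeqArray <- function(X, shape) {
  array(as.matrix(X), c(nrow(X), shape[1], shape[2]))
}

.fitScaler <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(mu = mu, sd = sdv)
}

.applyScaler <- function(X, sc) {
  sweep(sweep(as.matrix(X), 2, sc$mu), 2, sc$sd, "/")
}

.stratSplit <- function(y, fraction, seed) {
  set.seed(seed)
  val <- integer(0)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    nVal <- max(1L, round(fraction * length(idx)))
    val <- c(val, sample(idx, nVal))
  }
  sort(val)
}

#' Train a model
#'
#' Deep models train with binary cross-entropy and Adam on an 80/20
#' stratified train/validation split (per `config`), recording per-epoch
#' training and validation loss and restoring the weights of the epoch
#' with the lowest validation loss (checkpointing). LR and SVM_RBF are
#' fitted directly on the training split. Inputs are standardized with
#' training-split statistics.
#'
#' @param model an `NNModel` from [buildModel()].
#' @param X samples x features matrix (canonical feature order).
#' @param y 0/1 labels (1 = CTL is the positive class).
#' @param config a [trainConfig()].
#' @return list of class `TrainedModel`: `model`, `scaler`, `history`
#'   (epoch, trainLoss, valLoss, valAcc), `bestEpoch`, `config`.
#' @export
trainModel <- function(model, X, y, config = trainConfig()) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("training data contain a single class")
  val <- .stratSplit(y, config$validationFraction, config$seed)
  tr <- setdiff(seq_along(y), val)
  sc <- .fitScaler(X[tr, , drop = FALSE])
  Xs <- .applyScaler(X, sc)
  spec <- model$spec

  if (!spec$kind %in% .DL_KINDS) {
    fit <- if (spec$kind == "LR") {
      df <- data.frame(y = y[tr], Xs[tr, , drop = FALSE])
      suppressWarnings(glm(y ~ ., data = df, family = binomial()))
    } else {
      e1071::svm(x = Xs[tr, , drop = FALSE], y = factor(y[tr]),
                 kernel = "radial", cost = spec$hyper$cost,
                 probability = TRUE)
    }
    return(structure(list(model = model, fit = fit, scaler = sc,
                          history = NULL, bestEpoch = NA_integer_,
                          config = config),
                     class = "TrainedModel"))
  }

  toX <- function(M) .toSeqArray(M, spec$inputShape)
  layers <- model$layers
  state <- .adamInit(layers)
  set.seed(config$seed)
  bestLoss <- Inf
  bestLayers <- layers
  bestEpoch <- NA_integer_
  hist <- data.frame(epoch = seq_len(config$epochs), trainLoss = NA_real_,
                     valLoss = NA_real_, valAcc = NA_real_)
  step <- 0L
  for (ep in seq_len(config$epochs)) {
    ord <- sample(tr)
    batches <- split(ord, ceiling(seq_along(ord) / config$batchSize))
    bl <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      b <- batches[[bi]]
      lg <- .nnLossGrads(layers, toX(Xs[b, , drop = FALSE]), y[b],
                         training = TRUE)
      layers <- lg$layers
      step <- step + 1L
      upd <- .adamStep(layers, lg$grads, state, step, lr = config$lr,
                       beta1 = config$beta1, beta2 = config$beta2)
      layers <- upd$layers
      state <- upd$state
      bl[bi] <- lg$loss
    }
    fwVal <- .nnForward(layers, toX(Xs[val, , drop = FALSE]),
                        training = FALSE)
    lgVal <- .bceLossGrad(as.numeric(fwVal$out), y[val])
    hist$trainLoss[ep] <- mean(bl)
    hist$valLoss[ep] <- lgVal$loss
    hist$valAcc[ep] <- mean((as.numeric(fwVal$out) > 0.5) == y[val])
    if (lgVal$loss < bestLoss) {
      bestLoss <- lgVal$loss
      bestLayers <- layers
      bestEpoch <- ep
    }
  }
  trained <- model
  trained$layers <- if (config$restoreBest) bestLayers else layers
  structure(list(model = trained, fit = NULL, scaler = sc,
                 history = hist, bestEpoch = bestEpoch,
                 config = config),
            class = "TrainedModel")
}

#' Predict class-1 probabilities
#'
#' @param trained a `TrainedModel`.
#' @param X samples x features matrix.
#' @return numeric vector of probabilities of class 1 (CTL).
#' @export
predictProb <- function(trained, X) {
  X <- as.matrix(X)
  Xs <- .applyScaler(X, trained$scaler)
  spec <- trained$model$spec
  if (!spec$kind %in% .DL_KINDS) {
    if (spec$kind == "LR") {
      df <- as.data.frame(Xs)
      names(df) <- names(trained$fit$coefficients)[-1]
      return(as.numeric(suppressWarnings(
        predict(trained$fit, newdata = df, type = "response"))))
    }
    pr <- attr(predict(trained$fit, Xs, probability = TRUE),
               "probabilities")
    return(as.numeric(pr[, "1"]))
  }
  fw <- .nnForward(trained$model$layers,
                   .toSeqArray(Xs, spec$inputShape), training = FALSE)
  as.numeric(fw$out)
}

#' Save / load a trained-model checkpoint
#'
#' The weights go to `<path>` (RDS) and a JSON sidecar
#' `<path>.json` records the spec, seed, best epoch and history.
#' Reloading reproduces bit-identical predictions.
#'
#' @param trained a `TrainedModel`.
#' @param path checkpoint path.
#' @return `saveCheckpoint`: invisibly `path`; `loadCheckpoint`: the
#'   `TrainedModel`.
#' @export
saveCheckpoint <- function(trained, path) {
  saveRDS(trained, path)
  side <- list(kind = trained$model$spec$kind,
               inputShape = trained$model$spec$inputShape,
               seed = trained$model$spec$seed,
               bestEpoch = trained$bestEpoch,
               history = trained$history)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) readRDS(path)

#' Cross-validated classifier comparison
#'
#' Fold-matched stratified k-fold accuracies for every specification
#' (identical folds across specs) plus the matrix of pairwise paired
#' t-test p-values (NA on the diagonal and for zero-variance
#' differences of identical scores, where the test is undefined).
#'
#' @param featVec feature table from [featureVectors()], or any
#'   data.frame containing the feature columns and `y`.
#' @param specs list of [modelSpec()]s.
#' @param k folds (default 10).
#' @param seed fold seed.
#' @param config a [trainConfig()] used for the deep models.
#' @param features feature columns to use.
#' @return list with `results` (list of `CVResult`), `pvalues`
#'   (matrix) and `folds`.
#' @export
compareClassifiers <- function(featVec, specs, k = 10, seed = 1L,
                               config = trainConfig(),
                               features = featureNames()) {
  X <- as.matrix(featVec[, features, drop = FALSE])
  y <- featVec$y
  folds <- stratifiedFolds(y, k, seed)
  names(specs) <- vapply(specs, `[[`, character(1), "kind")
  results <- lapply(specs, function(spec) {
    spec$inputShape <- c(length(features), 1L)
    scores <- vapply(seq_len(k), function(fold) {
      te <- folds == fold
      tr <- buildModel(spec)
      fit <- trainModel(tr, X[!te, , drop = FALSE], y[!te], config)
      mean((predictProb(fit, X[te, , drop = FALSE]) > 0.5) == y[te])
    }, numeric(1))
    cvResult(spec$kind, scores)
  })
  n <- length(specs)
  pv <- matrix(NA_real_, n, n, dimnames = list(names(specs),
                                               names(specs)))
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    pv[i, j] <- .pairedP(results[[i]]$scores, results[[j]]$scores)
  list(results = results, pvalues = pv, folds = folds)
}
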