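#' Training configuration
#'
#' Defaults follow the published protocol: categorical cross-entropy loss,
#' Adam with its standard rate, at most 50 epochs of batches of 128, early
#' stopping on categorical accuracy with patience 4.
#'
#' @param maxEpochs,batchSize,patience integers.
#' @param lr,beta1,beta2,epsilon Adam hyperparameters.
#' @param monitor `"val_accuracy"` (uses the validation split when present,
#'   otherwise falls back to training accuracy) or `"accuracy"`.
#' @param seed integer seed for batch shuffling.
#' @return a list of class `"trainConfig"`.
#' @export
trainConfig <- function(maxEpochs = 50L, batchSize = 128L, patience = 4L,
                        lr = 0.001, beta1 = 0.9, beta2 = 0.999,
                        epsilon = 1e-7, monitor = c("val_accuracy", "accuracy"),
                        seed = 1L) {
  stopifnot(maxEpochs >= 1, patience >= 0, batchSize >= 1)
  structure(list(maxEpochs = as.integer(maxEpochs),
                 batchSize = as.integer(batchSize),
                 patience = as.integer(patience), lr = lr, beta1 = beta1,
                 beta2 = beta2, epsilon = epsilon,
                 monitor = match.arg(monitor), seed = as.integer(seed)),
            class = "trainConfig")
}

# One-hot encode labels against the model's class order.
.oneHot <- function(labels, classNames) {
  labels <- as.character(labels)
  idx <- match(labels, classNames)
  if (anyNA(idx))
    stop(sprintf("unknown label(s): %s",
                 paste(unique(labels[is.na(idx)]), collapse = ", ")))
  Y <- matrix(0, length(idx), length(classNames))
  Y[cbind(seq_along(idx), idx)] <- 1
  list(Y = Y, idx = idx)
}

.resolveXY <- function(x, labels = NULL) {
  if (is(x, "PanCancerExperiment")) {
    if (is.null(labels)) labels <- sampleLabels(x)
    x <- modelInput(x)
  }
  list(x = as.matrix(x), labels = labels)
}

#' Train a CNN model
#'
#' Minibatch Adam on categorical cross-entropy with early stopping: training
#' halts once the monitored categorical accuracy has failed to improve for
#' `patience` consecutive epochs, or at `maxEpochs`. The returned model keeps
#' the weights of the stopping epoch and a per-epoch history.
#'
#' @param model an untrained (or trained) [CNNModel-class].
#' @param x samples x genes matrix or a labelled [PanCancerExperiment-class].
#' @param labels class labels (taken from `x` when it carries them).
#' @param validation optional `list(x = , labels = )` monitored for early
#'   stopping and recorded in the history.
#' @param config a [trainConfig()].
#' @return the trained model; `model@history` holds epoch, loss, accuracy
#'   and (when validation is given) valLoss, valAccuracy.
#' @export
trainModel <- function(model, x, labels = NULL, validation = NULL,
                       config = trainConfig()) {
  xy <- .resolveXY(x, labels)
  X <- xy$x
  if (ncol(X) != modelInputLength(model))
    stop(sprintf("input has %d features but model expects %d", ncol(X),
                 modelInputLength(model)))
  if (is.null(xy$labels)) stop("labels are required")
  enc <- .oneHot(xy$labels, model@classNames)
  hasVal <- !is.null(validation)
  if (hasVal) {
    vxy <- .resolveXY(validation$x, validation$labels)
    vEnc <- .oneHot(vxy$labels, model@classNames)
  }

  w <- .getWeights(model)
  adam <- .adamInit(lapply(w, function(a) dim(a) %||% length(a)))
  step <- 0L
  set.seed(config$seed)
  n <- nrow(X)
  monitorBest <- -Inf
  badEpochs <- 0L
  hist <- list()

  for (epoch in seq_len(config$maxEpochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = config$batchSize)
    for (s in starts) {
      bIdx <- ord[s:min(s + config$batchSize - 1L, n)]
      Xb <- X[bIdx, , drop = FALSE]
      Yb <- enc$Y[bIdx, , drop = FALSE]
      fw <- .forward(model, Xb, keep = TRUE)
      dLogits <- (fw$probs - Yb) / nrow(Xb)
      grads <- .gradList(model, .backward(model, Xb, fw, dLogits))
      step <- step + 1L
      for (name in names(w)) {
        upd <- .adamStep(w[[name]], grads[[name]], adam[[name]], step,
                         config$lr, config$beta1, config$beta2,
                         config$epsilon)
        w[[name]] <- upd$value
        adam[[name]] <- upd$state
      }
      model <- .setWeights(model, w)
    }
    fwAll <- .forward(model, X)
    row <- data.frame(epoch = epoch,
                      loss = .crossEntropy(fwAll$probs, enc$Y),
                      accuracy = .accuracyFromProbs(fwAll$probs, enc$idx))
    if (hasVal) {
      fwVal <- .forward(model, vxy$x)
      row$valLoss <- .crossEntropy(fwVal$probs, vEnc$Y)
      row$valAccuracy <- .accuracyFromProbs(fwVal$probs, vEnc$idx)
    }
    hist[[epoch]] <- row
    metric <- if (config$monitor == "val_accuracy" && hasVal)
      row$valAccuracy else row$accuracy
    if (metric > monitorBest) {
      monitorBest <- metric
      badEpochs <- 0L
    } else {
      badEpochs <- badEpochs + 1L
      # patience p: halt after p consecutive non-improving epochs (p = 0
      # behaves like p = 1: halt on the first non-improvement)
      if (badEpochs >= max(config$patience, 1L)) break
    }
  }
  model@trained <- TRUE
  model@history <- do.call(rbind, hist)
  model
}

#' Predict classes or class probabilities
#'
#' @param object a trained [CNNModel-class].
#' @param newdata samples x genes matrix or [PanCancerExperiment-class].
#' @param type `"class"` (factor of predicted labels) or `"prob"`
#'   (samples x classes probability matrix; rows sum to 1).
#' @return factor or matrix, see `type`.
#' @export
setMethod("predict", "CNNModel",
  function(object, newdata, type = c("class", "prob")) {
    type <- match.arg(type)
    X <- .resolveXY(newdata)$x
    if (ncol(X) != modelInputLength(object))
      stop(sprintf("input has %d features but model expects %d", ncol(X),
                   modelInputLength(object)))
    probs <- .forward(object, X)$probs
    colnames(probs) <- object@classNames
    if (type == "prob") return(probs)
    factor(object@classNames[max.col(probs, ties.method = "first")],
           levels = object@classNames)
  })

#' Stratified holdout split
#'
#' @param labels per-sample class labels.
#' @param trainFraction fraction per class assigned to training (default 0.8).
#' @param seed integer RNG seed.
#' @return `list(train = , validation = )` of disjoint index vectors covering
#'   all samples, class proportions preserved within rounding.
#' @export
holdoutSplit <- function(labels, trainFraction = 0.8, seed = 1L) {
  stopifnot(trainFraction > 0, trainFraction < 1)
  labels <- as.character(labels)
  set.seed(as.integer(seed))
  train <- integer(0)
  for (cl in orderClasses(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < 2)
      stop(sprintf("class '%s' has %d sample(s); >= 2 required to stratify",
                   cl, length(idx)))
    nTr <- round(trainFraction * length(idx))
    nTr <- min(max(nTr, 1L), length(idx) - 1L)
    train <- c(train, sample(idx)[seq_len(nTr)])
  }
  train <- sort(train)
  list(train = train, validation = setdiff(seq_along(labels), train))
}

# Stratified fold assignment; errors naming any class smaller than nFolds.
.foldAssign <- function(labels, nFolds, seed) {
  labels <- as.character(labels)
  set.seed(as.integer(seed))
  folds <- integer(length(labels))
  for (cl in orderClasses(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < nFolds)
      stop(sprintf("class '%s' has %d samples, fewer than nFolds = %d",
                   cl, length(idx), nFolds))
    folds[sample(idx)] <- rep_len(seq_len(nFolds), length(idx))
  }
  folds
}

#' Repeated stratified k-fold cross-validation
#'
#' For each repeat and fold a fresh model is built and trained on the fold's
#' training portion; `innerValFraction` of that portion (stratified) is held
#' out as the early-stopping monitor so that fold-test data never influence
#' training. Test accuracies are aggregated over all repeat x fold pairs.
#'
#' @param arch a [CNNArchitecture-class] (built fresh per fold).
#' @param x samples x genes matrix or labelled [PanCancerExperiment-class].
#' @param labels class labels.
#' @param nFolds,nRepeats protocol size (defaults 5 and 6).
#' @param config a [trainConfig()]; its seed also drives fold assignment.
#' @param innerValFraction fraction of each fold-training portion held out
#'   for the early-stop monitor; 0 monitors training accuracy instead.
#' @return a [CVReport-class].
#' @export
crossValidate <- function(arch, x, labels = NULL, nFolds = 5L, nRepeats = 6L,
                          config = trainConfig(), innerValFraction = 0.1) {
  xy <- .resolveXY(x, labels)
  X <- xy$x
  labels <- as.character(xy$labels)
  classNames <- orderClasses(labels)
  if (arch@nClasses != length(classNames))
    stop(sprintf("architecture has %d classes but labels contain %d",
                 arch@nClasses, length(classNames)))
  confusion <- matrix(0L, length(classNames), length(classNames),
                      dimnames = list(truth = classNames,
                                      predicted = classNames))
  rows <- list()
  for (r in seq_len(nRepeats)) {
    folds <- .foldAssign(labels, nFolds, config$seed + 1009L * r)
    for (f in seq_len(nFolds)) {
      testIdx <- which(folds == f)
      trainIdx <- which(folds != f)
      model <- buildModel(arch, classNames = classNames,
                          seed = config$seed + 101L * r + f)
      foldCfg <- config
      foldCfg$seed <- config$seed + 211L * r + 17L * f
      if (innerValFraction > 0) {
        sp <- holdoutSplit(labels[trainIdx], 1 - innerValFraction,
                           seed = foldCfg$seed)
        model <- trainModel(model,
                            X[trainIdx[sp$train], , drop = FALSE],
                            labels[trainIdx[sp$train]],
                            validation = list(
                              x = X[trainIdx[sp$validation], , drop = FALSE],
                              labels = labels[trainIdx[sp$validation]]),
                            config = foldCfg)
      } else {
        model <- trainModel(model, X[trainIdx, , drop = FALSE],
                            labels[trainIdx], config = foldCfg)
      }
      pred <- as.character(predict(model, X[testIdx, , drop = FALSE]))
      acc <- mean(pred == labels[testIdx])
      confusion <- confusion + unclass(table(
        factor(labels[testIdx], levels = classNames),
        factor(pred, levels = classNames)))
      rows[[length(rows) + 1L]] <- data.frame(repeat_ = r, fold = f,
                                              accuracy = acc)
    }
  }
  accs <- do.call(rbind, rows)
  new("CVReport", accuracies = accs, mean = mean(accs$accuracy),
      sd = sd(accs$accuracy), confusion = confusion,
      nFolds = as.integer(nFolds), nRepeats = as.integer(nRepeats))
}

#' @export
setMethod("show", "CVReport", function(object) {
  cat(sprintf("CVReport: %d-fold x %d repeats, accuracy %.4f +/- %.4f\n",
              object@nFolds, object@nRepeats, object@mean, object@sd))
})

#' Exhaustive grid search over architecture hyperparameters
#'
#' Evaluates every Cartesian grid point by stratified cross-validation and
#' reports mean/sd of the categorical cross-entropy on the training and test
#' portions, shaped like the published hyperparameter tables. Grid names must
#' be slots of the template architecture. Points whose architecture fails
#' validity are recorded as failed rows rather than aborting the search.
#'
#' @param arch template [CNNArchitecture-class].
#' @param grid named list of hyperparameter values to cross.
#' @param x,labels data (as in [crossValidate()]).
#' @param config a [trainConfig()].
#' @param nFolds folds of the inner evaluation (default 5).
#' @return data.frame with one row per grid point: the hyperparameters,
#'   meanTrainLoss, sdTrainLoss, meanTestLoss, sdTestLoss, failed, and best
#'   (flagging the lowest mean test loss).
#' @export
gridSearch <- function(arch, grid, x, labels = NULL,
                       config = trainConfig(), nFolds = 5L) {
  stopifnot(length(grid) > 0, !is.null(names(grid)))
  xy <- .resolveXY(x, labels)
  X <- xy$x
  labels <- as.character(xy$labels)
  classNames <- orderClasses(labels)
  points <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  out <- points
  out$meanTrainLoss <- out$sdTrainLoss <- NA_real_
  out$meanTestLoss <- out$sdTestLoss <- NA_real_
  out$failed <- FALSE
  for (i in seq_len(nrow(points))) {
    slots <- lapply(points[i, , drop = FALSE], function(v)
      if (is.numeric(v)) as.integer(v) else v)
    cand <- try({
      a <- do.call(initialize, c(list(arch), slots))
      validObject(a)
      a
    }, silent = TRUE)
    if (inherits(cand, "try-error")) {
      out$failed[i] <- TRUE
      next
    }
    folds <- .foldAssign(labels, nFolds, config$seed)
    trLoss <- teLoss <- numeric(nFolds)
    for (f in seq_len(nFolds)) {
      testIdx <- which(folds == f)
      trainIdx <- which(folds != f)
      model <- buildModel(cand, classNames = classNames,
                          seed = config$seed + f)
      foldCfg <- config
      foldCfg$seed <- config$seed + 31L * f
      model <- trainModel(model, X[trainIdx, , drop = FALSE],
                          labels[trainIdx], config = foldCfg)
      encTr <- .oneHot(labels[trainIdx], classNames)
      encTe <- .oneHot(labels[testIdx], classNames)
      trLoss[f] <- .crossEntropy(
        .forward(model, X[trainIdx, , drop = FALSE])$probs, encTr$Y)
      teLoss[f] <- .crossEntropy(
        .forward(model, X[testIdx, , drop = FALSE])$probs, encTe$Y)
    }
    out$meanTrainLoss[i] <- mean(trLoss)
    out$sdTrainLoss[i] <- sd(trLoss)
    out$meanTestLoss[i] <- mean(teLoss)
    out$sdTestLoss[i] <- sd(teLoss)
  }
  out$best <- FALSE
  ok <- which(!out$failed)
  if (length(ok))
    out$best[ok[which.min(out$meanTestLoss[ok])]] <- TRUE
  attr(out, "nFolds") <- nFolds
  out
}

#' Accuracy of a trained model under increasing test-set noise
#'
#' Corrupts the (clean) test set with [addGaussianNoise()] at each noise
#' ratio `k` and records micro-averaged accuracy; `k = 0` uses the untouched
#' data, so its accuracy equals the clean test accuracy exactly.
#'
#' @param model trained [CNNModel-class].
#' @param x,labels clean test data.
#' @param ks numeric noise ratios (0 to 5 = 0-500% of each gene's mean).
#' @param nSeeds noise replicates averaged per k (k = 0 is deterministic).
#' @param seed base RNG seed.
#' @return data.frame with k, accuracy (mean over replicates) and sd.
#' @export
noiseRobustnessCurve <- function(model, x, labels = NULL,
                                 ks = c(0, 0.25, 0.5, 0.75, 1, 2, 5),
                                 nSeeds = 1L, seed = 1L) {
  if (any(ks < 0)) stop("noise ratios must be >= 0")
  xy <- .resolveXY(x, labels)
  X <- xy$x
  truth <- as.character(xy$labels)
  rows <- lapply(ks, function(k) {
    if (k == 0) {
      acc <- mean(as.character(predict(model, X)) == truth)
      return(data.frame(k = k, accuracy = acc, sd = 0))
    }
    accs <- vapply(seq_len(nSeeds), function(s) {
      Xn <- addGaussianNoise(X, k, seed = seed + 7919L * s)
      mean(as.character(predict(model, Xn)) == truth)
    }, numeric(1))
    data.frame(k = k, accuracy = mean(accs),
               sd = if (nSeeds > 1) sd(accs) else 0)
  })
  do.call(rbind, rows)
}
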