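test_that("stratified holdout splits preserve proportions and determinism", {
  lab <- rep(c("A", "B", "C", "D", "E"), each = 20)
  sp <- holdoutSplit(lab, 0.8, seed = 1L)
  expect_length(sp$train, 80)
  expect_length(sp$validation, 20)
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_setequal(c(sp$train, sp$validation), seq_along(lab))
  expect_equal(as.integer(table(lab[sp$train])), rep(16L, 5))  # stratified
  sp2 <- holdoutSplit(lab, 0.8, seed = 1L)
  expect_identical(sp, sp2)
  expect_false(identical(sp, holdoutSplit(lab, 0.8, seed = 2L)))
  expect_error(holdoutSplit(c("A", "A", "B"), 0.5), "class 'B'")
})

test_that("label/width mismatch fails before any optimization", {
  m <- buildModel(tinyArch1D(3L), classNames = c("a", "b", "c"), seed = 1L)
  X <- matrix(runif(10 * 280), 10, 280)
  expect_error(trainModel(m, X, rep(c("a", "zzz"), 5)), "unknown label")
  expect_error(trainModel(m, X[, 1:100], rep("a", 10)), "expects 280")
})

test_that("early stopping halts within patience and never past maxEpochs", {
  x <- tinySimulated(seed = 31L, samplesPerClass = 20L)
  lab <- sampleLabels(x)
  X <- modelInput(x)
  m <- buildModel(tinyArch1D(nlevels(lab)), classNames = levels(lab), seed = 1L)
  # training-accuracy monitor saturates at 1 and then stops after `patience`
  # consecutive non-improving epochs
  tm <- trainModel(m, X, lab, config = trainConfig(maxEpochs = 40L,
                                                   patience = 3L,
                                                   monitor = "accuracy",
                                                   seed = 2L))
  h <- tm@history
  expect_lte(nrow(h), 40L)
  best <- cummax(h$accuracy)
  tail3 <- nrow(h) - (0:2)
  if (nrow(h) < 40L)  # stopped early: the last 3 epochs did not improve
    expect_true(all(h$accuracy[tail3] <= best[nrow(h) - 3]))
  # with patience >= maxEpochs the full schedule runs
  tf <- trainModel(m, X, lab, config = trainConfig(maxEpochs = 5L,
                                                   patience = 50L,
                                                   monitor = "accuracy",
                                                   seed = 2L))
  expect_equal(nrow(tf@history), 5L)
})

test_that("training is deterministic given fixed seeds", {
  x <- tinySimulated(seed = 8L, samplesPerClass = 15L)
  lab <- sampleLabels(x)
  X <- modelInput(x)
  run <- function() {
    m <- buildModel(tinyArch1D(nlevels(lab)), classNames = levels(lab),
                    seed = 5L)
    trainModel(m, X, lab, config = trainConfig(maxEpochs = 4L, seed = 6L,
                                               monitor = "accuracy"))@history
  }
  expect_identical(run(), run())
})

test_that("separable data trains to high accuracy; zero-signal stays at chance", {
  # dense planted signal (40 of 280 genes per class at 3 log2 units): the
  # regime the shared-filter convolution is designed for
  x <- simulatePanCancer(syntheticDesign(
    nTissues = 2L, cancersPerTissue = 2L, nGenes = 280L,
    markersPerClass = 40L, tissueGenesPerTissue = 20L, cancerEffect = 3,
    tissueEffect = 1.5, baseSd = 1, samplesPerClass = 80L,
    normalsPerTissue = 8L, seed = 41L))
  lab <- sampleLabels(x)
  X <- modelInput(x)
  sp <- holdoutSplit(lab, 0.8, seed = 3L)
  m <- buildModel(tinyArch1D(nlevels(lab)), classNames = levels(lab), seed = 4L)
  m <- trainModel(m, X[sp$train, ], lab[sp$train],
                  validation = list(x = X[sp$validation, ],
                                    labels = lab[sp$validation]),
                  config = trainConfig(seed = 5L))
  acc <- mean(predict(m, X[sp$validation, ]) == lab[sp$validation])
  expect_gt(acc, 0.85)
  # shuffled labels: accuracy collapses to ~1/nClasses
  set.seed(6)
  shuf <- sample(as.character(lab[sp$train]))
  m0 <- buildModel(tinyArch1D(nlevels(lab)), classNames = levels(lab), seed = 7L)
  m0 <- trainModel(m0, X[sp$train, ], shuf,
                   config = trainConfig(maxEpochs = 10L, seed = 8L,
                                        monitor = "accuracy"))
  acc0 <- mean(predict(m0, X[sp$validation, ]) == lab[sp$validation])
  expect_lt(acc0, 2.5 / nlevels(lab))
})

test_that("cross-validation is leak-free with the right bookkeeping", {
  x <- tinySimulated(seed = 51L, samplesPerClass = 15L)
  lab <- sampleLabels(x)
  folds <- cancerCNN:::.foldAssign(as.character(lab), 3L, seed = 9L)
  expect_equal(sort(unique(folds)), 1:3)
  for (cl in levels(lab))      # stratification: every class in every fold
    expect_equal(sort(unique(folds[lab == cl])), 1:3)
  expect_error(cancerCNN:::.foldAssign(c("A", "A", "B", "B"), 3L, 1L),
               "class 'A'")
  cv <- crossValidate(tinyArch1D(nlevels(lab)), x, nFolds = 2L, nRepeats = 2L,
                      config = trainConfig(maxEpochs = 2L, seed = 10L),
                      innerValFraction = 0)
  expect_equal(nrow(cv@accuracies), 4L)      # nFolds x nRepeats entries
  expect_true(cv@mean >= 0 && cv@mean <= 1)
  # confusion totals: every sample predicted once per repeat
  expect_equal(rowSums(cv@confusion),
               2L * unname(table(lab)[rownames(cv@confusion)]),
               ignore_attr = TRUE)
})

test_that("a toy whose labels are recoverable from one gene cross-validates perfectly", {
  set.seed(12)
  n <- 40L
  X <- matrix(runif(n * 56, 0, 1), n, 56)
  lab <- rep(c("lo", "hi"), each = n / 2)
  X[lab == "hi", 1] <- X[lab == "hi", 1] + 10   # one decisive gene
  arch <- arch1DCNN(inputLen = 56L, kernelLen = 14L, nFilters = 4L,
                    denseUnits = 0L, nClasses = 2L)
  cv <- crossValidate(arch, X, lab, nFolds = 2L, nRepeats = 1L,
                      config = trainConfig(maxEpochs = 50L, batchSize = 8L,
                                           seed = 13L, monitor = "accuracy"),
                      innerValFraction = 0)
  expect_equal(cv@mean, 1)
  expect_equal(cv@sd, 0)
})

test_that("grid search covers the Cartesian grid and records failures", {
  set.seed(14)
  n <- 30L
  X <- matrix(runif(n * 56, 0, 1), n, 56)
  lab <- rep(c("lo", "hi"), each = n / 2)
  X[lab == "hi", 1] <- X[lab == "hi", 1] + 8
  arch <- arch1DCNN(inputLen = 56L, kernelLen = 14L, nFilters = 4L,
                    denseUnits = 0L, nClasses = 2L)
  g1 <- gridSearch(arch, list(nFilters = 2L), X, lab,
                   config = trainConfig(maxEpochs = 2L, seed = 15L,
                                        monitor = "accuracy"), nFolds = 2L)
  expect_equal(nrow(g1), 1L)
  g4 <- gridSearch(arch, list(nFilters = c(2L, 4L), denseUnits = c(0L, 4L)),
                   X, lab, config = trainConfig(maxEpochs = 2L, seed = 15L,
                                                monitor = "accuracy"),
                   nFolds = 2L)
  expect_equal(nrow(g4), 4L)
  expect_equal(sum(g4$best), 1L)
  expect_true(all(g4$meanTrainLoss[!g4$failed] >= 0))
  # an unbuildable point (kernel not dividing the input) is a failed row
  gf <- gridSearch(arch, list(kernelLen = c(14L, 15L)), X, lab,
                   config = trainConfig(maxEpochs = 2L, seed = 15L,
                                        monitor = "accuracy"), nFolds = 2L)
  expect_equal(gf$failed, c(FALSE, TRUE))
})

test_that("noise curve starts at the clean accuracy and rejects negative k", {
  x <- tinySimulated(seed = 61L, samplesPerClass = 20L)
  lab <- sampleLabels(x)
  X <- modelInput(x)
  m <- buildModel(tinyArch1D(nlevels(lab)), classNames = levels(lab), seed = 16L)
  m <- trainModel(m, X, lab, config = trainConfig(maxEpochs = 5L, seed = 17L,
                                                  monitor = "accuracy"))
  clean <- mean(predict(m, X) == lab)
  nc <- noiseRobustnessCurve(m, X, lab, ks = c(0, 1), nSeeds = 2L, seed = 18L)
  expect_equal(nc$accuracy[nc$k == 0], clean)
  expect_error(noiseRobustnessCurve(m, X, lab, ks = c(-1, 0)), ">= 0")
})
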