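test_that("guided saliency on a linear softmax model matches the closed-form gradient", {
  set.seed(20)
  W <- matrix(rnorm(12 * 4), 12, 4)
  b <- rnorm(4)
  m <- cancerCNN:::.denseSoftmaxModel(W, b)
  x <- runif(12)
  # logit variant: gradient of logit c is the weight column; positive part
  sLogit <- guidedSaliency(m, x, 2, wrt = "logit")
  expect_equal(as.numeric(sLogit), pmax(W[, 2], 0), tolerance = 1e-12)
  # softmax variant: d p_c / d x = p_c (W[,c] - W %*% p); positive part
  p <- as.numeric(predict(m, matrix(x, 1), type = "prob"))
  g <- p[2] * (W[, 2] - as.numeric(W %*% p))
  sSoft <- guidedSaliency(m, x, 2, wrt = "softmax")
  expect_equal(as.numeric(sSoft), pmax(g, 0), tolerance = 1e-10)
  expect_error(guidedSaliency(m, x, 9), "out of range")
})

test_that("gene-effect matrix on a linear model equals the scaled analytic gradient", {
  set.seed(21)
  W <- matrix(rnorm(10 * 3), 10, 3)
  m <- cancerCNN:::.denseSoftmaxModel(W, classNames = c("a", "b", "Normal"))
  X <- matrix(runif(9 * 10), 9, 10)
  lab <- rep(c("a", "b", "Normal"), each = 3)
  gem <- geneEffectMatrix(m, X, lab, wrt = "logit")
  s <- effectScores(gem)
  expected <- sapply(1:3, function(c) {
    col <- pmax(W[, c], 0)
    col / max(col)
  })
  expect_equal(unname(s), unname(expected), tolerance = 1e-5)
  expect_true(all(apply(s, 2, max) == 1))
  expect_true(all(s >= 0 & s <= 1))
})

test_that("saliency excludes padding pseudo-genes and matches the real gene count", {
  x <- tinySimulated(seed = 22L, samplesPerClass = 10L)
  xp <- padAndOrder(x, 300L)     # 20 padding columns
  lab <- sampleLabels(xp)
  arch <- arch1DCNN(inputLen = 300L, nFilters = 4L, kernelLen = 30L,
                    denseUnits = 8L, nClasses = nlevels(lab))
  m <- buildModel(arch, classNames = levels(lab), seed = 23L)
  m <- trainModel(m, xp, config = trainConfig(maxEpochs = 2L, seed = 24L,
                                              monitor = "accuracy"))
  s <- guidedSaliency(m, xp, 1)
  expect_equal(ncol(s), 280L)                 # real genes only
  gem <- geneEffectMatrix(m, xp)
  expect_equal(nrow(effectScores(gem)), 280L)
  expect_false(any(grepl("^_PAD", rownames(effectScores(gem)))))
})

test_that("planted markers score above unplanted genes in their class column", {
  x <- tinySimulated(seed = 25L, samplesPerClass = 60L, cancerEffect = 3)
  lab <- sampleLabels(x)
  m <- buildModel(tinyArch1D(nlevels(lab)), classNames = levels(lab), seed = 26L)
  sp <- holdoutSplit(lab, 0.8, seed = 27L)
  X <- modelInput(x)
  m <- trainModel(m, X[sp$train, ], lab[sp$train],
                  validation = list(x = X[sp$validation, ],
                                    labels = lab[sp$validation]),
                  config = trainConfig(seed = 28L))
  gem <- geneEffectMatrix(m, x)
  s <- effectScores(gem)
  md <- S4Vectors::metadata(x)
  planted <- unlist(md$truthMarkers)
  for (cl in names(md$truthMarkers)) {
    own <- s[md$truthMarkers[[cl]], cl]
    unplanted <- s[setdiff(rownames(s), c(planted,
                                          unlist(md$truthTissueGenes))), cl]
    expect_gt(mean(own), mean(unplanted))
  }
})

test_that("marker selection applies the strict threshold with nesting and unique counts", {
  s <- matrix(c(1.0, 0.6, 0.4, 0.1,
                0.55, 1.0, 0.2, 0.0), 4, 2,
              dimnames = list(c("g1", "g2", "g3", "g4"), c("A", "B")))
  gem <- new("GeneEffectMatrix", scores = s, scaling = "perClass")
  mk5 <- selectMarkers(gem, 0.5)
  expect_equal(markerList(mk5)$A$gene, c("g1", "g2"))
  expect_equal(markerList(mk5)$B$gene, c("g2", "g1"))   # sorted by score
  expect_equal(markerCount(mk5), 4L)                    # with multiplicity
  expect_setequal(uniqueGenes(mk5), c("g1", "g2"))      # union of symbols
  mk9 <- selectMarkers(gem, 0.9)
  for (cl in c("A", "B"))                               # threshold nesting
    expect_true(all(markerList(mk9)[[cl]]$gene %in% markerList(mk5)[[cl]]$gene))
  # threshold above every score yields an empty set (strict >)
  empty <- selectMarkers(gem, 0.999999)
  expect_equal(markerCount(empty), 2L)  # the two exact-1 column maxima remain
  expect_equal(nrow(markerList(empty)$A), 1L)
})

test_that("marker concordance recovers the planted effect and is shift-invariant", {
  x <- tinySimulated(seed = 29L, samplesPerClass = 80L)
  md <- S4Vectors::metadata(x)
  cl <- names(md$truthMarkers)[1]
  res <- markerConcordance(md$truthMarkers[[cl]], x, className = cl)
  expect_lt(res$p.value, 0.01)
  expect_equal(res$markerMean, 2.0, tolerance = 0.15)
  expect_true(all(res$differences >= 0))
  # shift invariance: adding a constant to every value changes nothing
  X <- modelInput(x)
  lab <- sampleLabels(x)
  r1 <- markerConcordance(md$truthMarkers[[cl]], X, lab, className = cl)
  r2 <- markerConcordance(md$truthMarkers[[cl]], X + 5, lab, className = cl)
  expect_equal(r1$differences, r2$differences, tolerance = 1e-9)
  expect_equal(r1$p.value, r2$p.value, tolerance = 1e-9)
  expect_error(markerConcordance(md$truthMarkers[[cl]], x, className = "nope"),
               "absent")
})

test_that("degenerate concordance (no expression differences) is non-significant", {
  X <- matrix(2, 20, 10, dimnames = list(NULL, paste0("g", 1:10)))
  lab <- rep(c("A", "B"), each = 10)
  res <- markerConcordance(c("g1", "g2"), X, lab, className = "A")
  expect_true(res$degenerate)
  expect_equal(res$p.value, 1)
  expect_true(all(res$differences == 0))
})

test_that("Fisher enrichment matches brute-force enumeration and tail properties", {
  universe <- paste0("g", 1:20)
  sets <- list(hit = paste0("g", 1:5), none = paste0("x", 1:3))
  markers <- c("g1", "g2", "g3", "g4", "g18")   # overlap 4 with 'hit'
  expect_warning(
    res <- geneSetEnrichment(markers, sets, universe, alpha = 0.001),
    "no overlap")
  expect_equal(res$overlap[res$set == "hit"], 4L)
  # worked example: P(X >= 4) with universe 20, set 5, markers 5
  expect_equal(res$p[res$set == "hit"],
               bruteForceFisherTail(4, 5, 5, 20), tolerance = 1e-12)
  # p monotone non-increasing in overlap at fixed margins
  ps <- vapply(0:5, function(a) {
    mk <- c(head(paste0("g", 1:5), a), head(paste0("g", 16:20), 5 - a))
    geneSetEnrichment(mk, sets["hit"], universe)$p
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
  # zero overlap is the whole tail: p = 1 exactly
  expect_equal(ps[1], 1)
  expect_error(geneSetEnrichment(c("zz"), sets, universe), "subset")
  expect_error(geneSetEnrichment("g1", sets, character(0)), "empty universe")
})

test_that("GMT collections round-trip through the reader", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tG1\tG2\tG3", "setB\tdesc\tG2\tG9"), f)
  gs <- readGmt(f)
  expect_named(gs, c("setA", "setB"))
  expect_equal(gs$setA, c("G1", "G2", "G3"))
})

test_that("gene-effect matrices and marker sets write tidy TSVs", {
  s <- matrix(c(1, 0.2, 0.7, 1), 2, 2,
              dimnames = list(c("g1", "g2"), c("A", "B")))
  gem <- new("GeneEffectMatrix", scores = s, scaling = "perClass")
  dir <- withr::local_tempdir()
  writeGeneEffectMatrix(gem, file.path(dir, "gem.tsv"))
  back <- data.table::fread(file.path(dir, "gem.tsv"))
  expect_equal(back$A, c(1, 0.2))
  writeMarkerSet(selectMarkers(gem, 0.5), file.path(dir, "mk.tsv"))
  mk <- data.table::fread(file.path(dir, "mk.tsv"))
  expect_equal(nrow(mk), 3L)
})
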