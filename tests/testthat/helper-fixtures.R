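# Small fixtures shared across test files; everything is generated in code.

# A tiny raw-FPKM experiment with known values.
tinyRawExperiment <- function() {
  values <- matrix(c(0, 1, 7, 3,
                     1, 0, 7, 15,
                     3, 1, 0, 31), nrow = 3, byrow = TRUE)
  panCancerExperiment(values, geneSymbols = c("B", "A", "D", "C"),
                      sampleIds = c("s1", "s2", "s3"))
}

# A small, quickly separable simulated dataset (4 cancers over 2 tissues +
# Normal), already on the log2 scale.
tinySimulated <- function(seed = 5L, samplesPerClass = 40L,
                          cancerEffect = 2, tissueEffect = 1.5) {
  simulatePanCancer(syntheticDesign(
    nTissues = 2L, cancersPerTissue = 2L, nGenes = 280L,
    markersPerClass = 10L, tissueGenesPerTissue = 20L,
    cancerEffect = cancerEffect, tissueEffect = tissueEffect, baseSd = 1,
    samplesPerClass = samplesPerClass, normalsPerTissue = 8L, seed = seed))
}

# A small 1D architecture matching tinySimulated's 280-gene input.
tinyArch1D <- function(nClasses, denseUnits = 16L) {
  arch1DCNN(inputLen = 280L, nFilters = 8L, kernelLen = 28L,
            denseUnits = denseUnits, nClasses = as.integer(nClasses))
}

# Random small-but-valid architecture specs for oracle sweeps.
randomArch <- function(kind) {
  if (kind == "1d") {
    K <- sample(2:12, 1)
    P <- sample(2:12, 1)
    arch1DCNN(inputLen = K * P, nFilters = sample(1:8, 1), kernelLen = K,
              poolSize = sample(1:min(2L, P), 1),
              denseUnits = sample(c(0L, 4L, 9L), 1),
              nClasses = sample(2:6, 1))
  } else if (kind == "2d_vanilla") {
    R <- sample(6:16, 1); Cc <- sample(6:16, 1)
    kr <- sample(2:4, 1); kc <- sample(2:4, 1)
    arch2DVanillaCNN(inputRows = R, inputCols = Cc, nFilters = sample(1:6, 1),
                     kernelRows = kr, kernelCols = kc,
                     strideRows = sample(1:2, 1), strideCols = sample(1:2, 1),
                     poolRows = 2L, poolCols = 2L,
                     denseUnits = sample(c(0L, 5L), 1),
                     nClasses = sample(2:5, 1))
  } else {
    arch2DHybridCNN(inputRows = sample(3:15, 1), inputCols = sample(3:15, 1),
                    nFilters = sample(1:6, 1), poolSize = 2L,
                    denseUnits = sample(c(0L, 6L), 1),
                    nClasses = sample(2:5, 1))
  }
}

# Brute-force hypergeometric upper tail P(X >= a) via choose(), independent
# of stats::fisher.test / stats::phyper.
bruteForceFisherTail <- function(a, setSize, nMarkers, nUniverse) {
  ks <- max(a, 0):min(setSize, nMarkers)
  sum(choose(setSize, ks) * choose(nUniverse - setSize, nMarkers - ks)) /
    choose(nUniverse, nMarkers)
}
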