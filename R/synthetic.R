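#' Construct a synthetic pan-cancer design
#'
#' Defaults define the package's canonical study conditions, mirroring the
#' pan-cancer setting: 11 tissues x 3 cancer classes (33 cancers) plus
#' matched normals, 60 tumor samples per class and 6 normals per tissue,
#' 7091 genes (the post-filter pan-cancer gene count, padded to 7100
#' downstream), 108 planted markers per cancer class (the average marker
#' count observed per class) shifted by `cancerEffect` = 2.0 on the log2
#' scale, 200 tissue-signature genes per tissue shifted by
#' `tissueEffect` = 1.5 in tumors and normals alike, and unit per-gene
#' Gaussian noise.
#'
#' @param nTissues,cancersPerTissue class structure.
#' @param nGenes total genes simulated.
#' @param markersPerClass planted cancer-specific markers per cancer class.
#' @param tissueGenesPerTissue planted tissue-signature genes per tissue.
#' @param cancerEffect,tissueEffect mean log2 shifts of planted genes.
#' @param baseSd per-gene Gaussian noise sd.
#' @param samplesPerClass tumor samples per cancer class.
#' @param normalsPerTissue "Normal"-labelled samples per tissue.
#' @param seed integer RNG seed.
#' @return a [SyntheticDesign-class].
#' @export
syntheticDesign <- function(nTissues = 11L, cancersPerTissue = 3L,
                            nGenes = 7091L, markersPerClass = 108L,
                            tissueGenesPerTissue = 200L, cancerEffect = 2.0,
                            tissueEffect = 1.5, baseSd = 1.0,
                            samplesPerClass = 60L, normalsPerTissue = 6L,
                            seed = 1L) {
  new("SyntheticDesign", nTissues = as.integer(nTissues),
      cancersPerTissue = as.integer(cancersPerTissue),
      nGenes = as.integer(nGenes),
      markersPerClass = as.integer(markersPerClass),
      tissueGenesPerTissue = as.integer(tissueGenesPerTissue),
      cancerEffect = cancerEffect, tissueEffect = tissueEffect,
      baseSd = baseSd, samplesPerClass = as.integer(samplesPerClass),
      normalsPerTissue = as.integer(normalsPerTissue),
      seed = as.integer(seed))
}

#' @export
setMethod("show", "SyntheticDesign", function(object) {
  cat(sprintf(paste0(
    "SyntheticDesign: %d tissues x %d cancers (+Normal), %d genes\n",
    "  %d markers/class (effect %.2f), %d tissue genes/tissue (effect %.2f)\n",
    "  %d samples/class, %d normals/tissue, baseSd %.2f, seed %d\n"),
    object@nTissues, object@cancersPerTissue, object@nGenes,
    object@markersPerClass, object@cancerEffect, object@tissueGenesPerTissue,
    object@tissueEffect, object@samplesPerClass, object@normalsPerTissue,
    object@baseSd, object@seed))
})

#' Generate a labelled pan-cancer expression dataset with planted signal
#'
#' Expression of a sample from cancer class c of tissue t is
#' `baseline + tissueEffect * 1[tissue genes of t] +
#' cancerEffect * 1[markers of c] + N(0, baseSd^2)`, truncated at 0, emitted
#' directly on the log2(FPKM+1) scale. Normals carry only their tissue's
#' signature, all pooled under a single "Normal" label — the tissue-of-origin
#' confound. Baseline gene means are drawn from U(1.5, 3.5) so that, with the
#' default noise level, every gene passes the low-information filter by
#' construction.
#'
#' @param design a [SyntheticDesign-class].
#' @param includeNormals logical; `FALSE` yields the tumor-only dataset used
#'   for confound experiments.
#' @return a [PanCancerExperiment-class] with labels in
#'   `colData(x)$label` and truth in `metadata(x)$truthMarkers`,
#'   `$truthTissueGenes`, `$tissueOfClass` and `$design`.
#' @export
simulatePanCancer <- function(design = syntheticDesign(),
                              includeNormals = TRUE) {
  validObject(design)
  set.seed(design@seed)
  nT <- design@nTissues; nC <- design@cancersPerTissue
  nClasses <- nT * nC
  tissues <- sprintf("T%02d", seq_len(nT))
  classes <- as.vector(t(outer(tissues, seq_len(nC),
                               function(t, j) sprintf("%sC%d", t, j))))
  tissueOfClass <- setNames(rep(tissues, each = nC), classes)
  genes <- sprintf("G%04d", seq_len(design@nGenes))

  # deterministic role assignment: disjoint marker and tissue-gene sets
  roles <- sample(design@nGenes)
  nm <- design@markersPerClass * nClasses
  nt <- design@tissueGenesPerTissue * nT
  markerIdx <- if (nm > 0)
    split(roles[seq_len(nm)], rep(seq_len(nClasses),
                                  each = design@markersPerClass))
  else rep(list(integer(0)), nClasses)
  tissueIdx <- if (nt > 0)
    split(roles[nm + seq_len(nt)], rep(seq_len(nT),
                                       each = design@tissueGenesPerTissue))
  else rep(list(integer(0)), nT)
  names(markerIdx) <- classes
  names(tissueIdx) <- tissues

  baseline <- runif(design@nGenes, 1.5, 3.5)

  labels <- c(rep(classes, each = design@samplesPerClass),
              if (includeNormals)
                rep("Normal", nT * design@normalsPerTissue))
  sampleTissue <- c(rep(tissueOfClass[classes], each = design@samplesPerClass),
                    if (includeNormals)
                      rep(tissues, each = design@normalsPerTissue))
  n <- length(labels)
  vals <- matrix(rnorm(n * design@nGenes, sd = design@baseSd),
                 nrow = design@nGenes, ncol = n)
  vals <- vals + baseline
  for (i in seq_len(n)) {
    ti <- sampleTissue[i]
    vals[tissueIdx[[ti]], i] <- vals[tissueIdx[[ti]], i] + design@tissueEffect
    if (labels[i] != "Normal")
      vals[markerIdx[[labels[i]]], i] <-
        vals[markerIdx[[labels[i]]], i] + design@cancerEffect
  }
  vals <- pmax(vals, 0)
  rownames(vals) <- genes
  ids <- sprintf("S%05d", seq_len(n))
  colnames(vals) <- ids

  x <- panCancerExperiment(vals, geneSymbols = genes, sampleIds = ids,
                           labels = labels, logTransformed = TRUE,
                           genesInRows = TRUE)
  S4Vectors::metadata(x) <- list(
    nPadding = 0L,
    truthMarkers = lapply(markerIdx, function(i) genes[sort(i)]),
    truthTissueGenes = lapply(tissueIdx, function(i) genes[sort(i)]),
    tissueOfClass = tissueOfClass,
    sampleTissue = setNames(sampleTissue, ids),
    design = design)
  x
}

#' Generate a breast-cancer-subtype-like dataset (one tissue, 5 classes)
#'
#' A single-tissue variant whose default class sizes mirror the PAM50 subtype
#' imbalance (Basal 147, Her2 68, Luminal A 437, Luminal B 186, Normal 26).
#' All non-"Normal" classes receive planted markers; the default breadth of
#' 100 markers per subtype reflects that intrinsic-subtype expression
#' differences span hundreds of genes (PAM50 is a minimal reporting panel,
#' not the breadth of the underlying differences).
#'
#' @param classNames character class names; a class named "Normal" carries no
#'   subtype markers.
#' @param classSizes integer sample count per class.
#' @param nGenes,markersPerClass,cancerEffect,baseSd as in
#'   [syntheticDesign()].
#' @param seed integer RNG seed.
#' @return a labelled [PanCancerExperiment-class] with truth metadata.
#' @export
simulateBrcaSubtypes <- function(classNames = c("Basal", "Her2", "LuminalA",
                                                "LuminalB", "Normal"),
                                 classSizes = c(147L, 68L, 437L, 186L, 26L),
                                 nGenes = 7091L, markersPerClass = 100L,
                                 cancerEffect = 2.0, baseSd = 1.0,
                                 seed = 1L) {
  stopifnot(length(classNames) == length(classSizes),
            !anyDuplicated(classNames), all(classSizes >= 1))
  set.seed(as.integer(seed))
  genes <- sprintf("G%04d", seq_len(nGenes))
  marked <- setdiff(classNames, "Normal")
  stopifnot(markersPerClass * length(marked) <= nGenes)
  roles <- sample(nGenes)
  markerIdx <- split(roles[seq_len(markersPerClass * length(marked))],
                     rep(seq_along(marked), each = markersPerClass))
  names(markerIdx) <- marked
  baseline <- runif(nGenes, 1.5, 3.5)
  labels <- rep(classNames, times = classSizes)
  n <- length(labels)
  vals <- matrix(rnorm(n * nGenes, sd = baseSd), nrow = nGenes, ncol = n)
  vals <- vals + baseline
  for (i in seq_len(n)) {
    if (labels[i] %in% marked)
      vals[markerIdx[[labels[i]]], i] <-
        vals[markerIdx[[labels[i]]], i] + cancerEffect
  }
  vals <- pmax(vals, 0)
  rownames(vals) <- genes
  ids <- sprintf("S%05d", seq_len(n))
  colnames(vals) <- ids
  x <- panCancerExperiment(vals, geneSymbols = genes, sampleIds = ids,
                           labels = labels, logTransformed = TRUE,
                           genesInRows = TRUE)
  S4Vectors::metadata(x) <- list(
    nPadding = 0L,
    truthMarkers = lapply(markerIdx, function(i) genes[sort(i)]))
  x
}

#' Write a synthetic dataset as delimited text plus a truth sidecar
#'
#' @param x a simulated [PanCancerExperiment-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly; writes `expression.tsv`, `labels.tsv`
#'   and `truth_markers.tsv` (class, gene).
#' @export
writeSyntheticDataset <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeExpressionTable(x, file.path(dir, "expression.tsv"),
                       labelFile = file.path(dir, "labels.tsv"))
  tm <- S4Vectors::metadata(x)$truthMarkers
  if (!is.null(tm)) {
    dt <- data.table::data.table(
      class = rep(names(tm), lengths(tm)),
      gene = unlist(tm, use.names = FALSE))
    data.table::fwrite(dt, file.path(dir, "truth_markers.tsv"), sep = "\t")
  }
  invisible(dir)
}

#' @rdname addGaussianNoise
#' @export
setMethod("addGaussianNoise", "matrix", function(x, k, seed = 1L) {
  if (k < 0) stop("noise ratio k must be >= 0")
  if (k == 0) return(x)
  set.seed(as.integer(seed))
  mu <- colMeans(x)                       # genes are columns (model input)
  noise <- matrix(rnorm(length(x)), nrow(x), ncol(x))
  noise <- sweep(noise, 2, k * mu, "*")
  pmax(x + noise, 0)
})

#' @rdname addGaussianNoise
#' @export
setMethod("addGaussianNoise", "PanCancerExperiment", function(x, k, seed = 1L) {
  v <- SummarizedExperiment::assay(x, "expr")
  SummarizedExperiment::assay(x, "expr") <-
    t(addGaussianNoise(t(v), k, seed = seed))
  x
})
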