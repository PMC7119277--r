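#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom stats rnorm runif sd predict fisher.test t.test setNames
#' @importFrom utils head modifyList
NULL

#' PanCancerExperiment: expression container for the CNN pipeline
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with genes in rows and
#' samples in columns. The single assay `"expr"` holds expression values,
#' either raw FPKM (`logTransformed = FALSE`) or log2(FPKM+1). Zero-filled
#' padding pseudo-genes appended by [padAndOrder()] are tracked in
#' `rowData(x)$isPadding` and excluded from all marker reporting.
#'
#' @slot logTransformed logical; `TRUE` once values are on the log2(FPKM+1)
#'   scale.
#'
#' @seealso [panCancerExperiment()], [logTransform()], [filterLowInformation()],
#'   [padAndOrder()]
#' @export
setClass("PanCancerExperiment",
  contains = "SummarizedExperiment",
  slots = c(logTransformed = "logical"),
  prototype = prototype(logTransformed = FALSE)
)

setValidity("PanCancerExperiment", function(object) {
  msg <- character()
  if (!"expr" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'expr' is required")
  else {
    v <- SummarizedExperiment::assay(object, "expr")
    if (anyNA(v)) msg <- c(msg, "expression values must not contain NA")
    else if (any(v < 0)) msg <- c(msg, "expression values must be non-negative")
  }
  rn <- rownames(object)
  if (is.null(rn) || anyDuplicated(rn))
    msg <- c(msg, "gene symbols (rownames) must be present and unique")
  if (!"isPadding" %in% colnames(SummarizedExperiment::rowData(object)))
    msg <- c(msg, "rowData must contain an 'isPadding' column")
  if (length(msg)) msg else TRUE
})

#' Virtual parent of the three CNN architecture specifications
#'
#' @export
setClass("CNNArchitecture", representation("VIRTUAL",
  nFilters = "integer", denseUnits = "integer", nClasses = "integer"))

#' 1D-CNN architecture: non-overlapping one-dimensional kernels
#'
#' The stride equals the kernel length, so each kernel summarises a disjoint
#' window of the gene vector. `denseUnits = 0` drops the fully connected layer
#' (the breast-cancer subtype variant).
#'
#' @slot inputLen integer, length of the (padded) gene vector.
#' @slot kernelLen integer, kernel length = stride.
#' @slot poolSize integer, max-pooling window along the convolution output.
#' @export
setClass("Conv1DArchitecture", contains = "CNNArchitecture",
  slots = c(inputLen = "integer", kernelLen = "integer", poolSize = "integer"))

setValidity("Conv1DArchitecture", function(object) {
  msg <- character()
  if (object@inputLen %% object@kernelLen != 0) {
    need <- object@kernelLen * ceiling(object@inputLen / object@kernelLen) -
      object@inputLen
    msg <- c(msg, sprintf(
      "inputLen %d is not divisible by kernelLen %d; pad input with %d more zeros",
      object@inputLen, object@kernelLen, need))
  } else if (object@inputLen %/% object@kernelLen < object@poolSize) {
    msg <- c(msg, "conv output shorter than the pooling window")
  }
  if (object@nClasses < 2) msg <- c(msg, "nClasses must be >= 2")
  if (object@nFilters < 1 || object@poolSize < 1 || object@denseUnits < 0)
    msg <- c(msg, "nFilters, poolSize must be >= 1 and denseUnits >= 0")
  if (length(msg)) msg else TRUE
})

#' 2D-Vanilla-CNN architecture: one strided 2D convolution on the gene grid
#'
#' @slot inputRows,inputCols integer grid shape (row-major reshape of the
#'   padded gene vector).
#' @slot kernelRows,kernelCols integer 2D kernel shape.
#' @slot strideRows,strideCols integer strides.
#' @slot poolRows,poolCols integer max-pooling window (floor semantics).
#' @export
setClass("Conv2DVanillaArchitecture", contains = "CNNArchitecture",
  slots = c(inputRows = "integer", inputCols = "integer",
            kernelRows = "integer", kernelCols = "integer",
            strideRows = "integer", strideCols = "integer",
            poolRows = "integer", poolCols = "integer"))

setValidity("Conv2DVanillaArchitecture", function(object) {
  msg <- character()
  if (object@kernelRows > object@inputRows || object@kernelCols > object@inputCols)
    msg <- c(msg, "kernel does not fit inside the input grid")
  if (object@strideRows < 1 || object@strideCols < 1)
    msg <- c(msg, "strides must be >= 1")
  if (object@nClasses < 2) msg <- c(msg, "nClasses must be >= 2")
  if (length(msg) == 0) {
    or <- (object@inputRows - object@kernelRows) %/% object@strideRows + 1L
    oc <- (object@inputCols - object@kernelCols) %/% object@strideCols + 1L
    if (or %/% object@poolRows < 1 || oc %/% object@poolCols < 1)
      msg <- c(msg, "pooled feature map would be empty")
  }
  if (length(msg)) msg else TRUE
})

#' 2D-Hybrid-CNN architecture: orthogonal row- and column-spanning 1D kernels
#'
#' One kernel the size of a grid row slides vertically (one position per row);
#' the other, the size of a column, slides horizontally (one per column). Each
#' branch is max-pooled with window 2 using ceiling semantics on odd lengths
#' before concatenation.
#'
#' @slot inputRows,inputCols integer grid shape.
#' @slot poolSize integer pooling window per branch.
#' @export
setClass("Conv2DHybridArchitecture", contains = "CNNArchitecture",
  slots = c(inputRows = "integer", inputCols = "integer", poolSize = "integer"))

setValidity("Conv2DHybridArchitecture", function(object) {
  msg <- character()
  if (object@inputRows < 1 || object@inputCols < 1)
    msg <- c(msg, "input grid must be non-empty")
  if (object@nClasses < 2) msg <- c(msg, "nClasses must be >= 2")
  if (object@poolSize < 1) msg <- c(msg, "poolSize must be >= 1")
  if (length(msg)) msg else TRUE
})

#' A built (and possibly trained) CNN model
#'
#' Weights are plain numeric matrices/vectors; `branches` holds per-branch
#' gather indices, kernels and pooling maps used by the internal engine.
#'
#' @slot architecture the [CNNArchitecture-class] the model was built from.
#' @slot branches list of convolution branches (empty for a dense-only model).
#' @slot denseW,denseB fully connected layer (zero-size when absent).
#' @slot outW,outB softmax prediction layer.
#' @slot classNames character, output class order ("Normal" sorts last).
#' @slot trained logical.
#' @slot history data.frame of per-epoch losses/metrics (empty until trained).
#' @export
setClass("CNNModel",
  slots = c(architecture = "ANY", branches = "list",
            denseW = "matrix", denseB = "numeric",
            outW = "matrix", outB = "numeric",
            classNames = "character", trained = "logical",
            history = "data.frame"))

#' Gene-effect matrix: class-wise saliency scores per gene
#'
#' Genes × classes scores in the unit interval; within each class column the top gene
#' scores exactly 1 (per-class scaling) unless the column is identically zero.
#' Padding pseudo-genes are excluded before scaling.
#'
#' @slot scores numeric matrix, genes × classes.
#' @slot scaling character, `"perClass"` or `"global"`.
#' @export
setClass("GeneEffectMatrix",
  slots = c(scores = "matrix", scaling = "character"))

setValidity("GeneEffectMatrix", function(object) {
  s <- object@scores
  msg <- character()
  if (anyNA(s) || any(s < 0) || any(s > 1))
    msg <- c(msg, "scores must lie in [0, 1]")
  if (is.null(rownames(s)) || is.null(colnames(s)))
    msg <- c(msg, "scores must carry gene symbols and class names as dimnames")
  if (length(msg)) msg else TRUE
})

#' Marker genes selected from a gene-effect matrix
#'
#' @slot markers named list, one data.frame(gene, score) per class, sorted by
#'   decreasing score; only scores strictly above `threshold` are kept.
#' @slot threshold numeric score cutoff.
#' @export
setClass("MarkerSet", slots = c(markers = "list", threshold = "numeric"))

#' Design of a synthetic pan-cancer expression dataset
#'
#' Each tissue contributes `cancersPerTissue` cancer classes plus
#' `normalsPerTissue` matched normal samples. Every cancer class receives
#' `markersPerClass` planted marker genes shifted by `cancerEffect`; every
#' tissue has `tissueGenesPerTissue` genes shifted by `tissueEffect` in all of
#' its samples, tumor and normal alike — the tissue-of-origin confound.
#' Values are generated directly on the log2(FPKM+1) scale.
#'
#' @export
setClass("SyntheticDesign",
  slots = c(nTissues = "integer", cancersPerTissue = "integer",
            nGenes = "integer", markersPerClass = "integer",
            tissueGenesPerTissue = "integer",
            cancerEffect = "numeric", tissueEffect = "numeric",
            baseSd = "numeric", samplesPerClass = "integer",
            normalsPerTissue = "integer", seed = "integer"))

setValidity("SyntheticDesign", function(object) {
  msg <- character()
  nClasses <- object@nTissues * object@cancersPerTissue
  budget <- object@markersPerClass * nClasses +
    object@tissueGenesPerTissue * object@nTissues
  if (budget > object@nGenes)
    msg <- c(msg, sprintf(
      "gene budget infeasible: %d marker + tissue genes needed but nGenes = %d",
      budget, object@nGenes))
  if (object@cancerEffect < 0 || object@tissueEffect < 0 || object@baseSd < 0)
    msg <- c(msg, "effects and baseSd must be >= 0")
  if (object@samplesPerClass < 1 || object@normalsPerTissue < 0)
    msg <- c(msg, "samplesPerClass must be >= 1, normalsPerTissue >= 0")
  if (length(msg)) msg else TRUE
})

#' Cross-validation report
#'
#' @slot accuracies data.frame with columns repeat_, fold, accuracy.
#' @slot mean,sd numeric summary over all repeat × fold test accuracies.
#' @slot confusion integer matrix summed over every repeat × fold prediction
#'   (row sums equal nRepeats × class counts).
#' @slot nFolds,nRepeats integer.
#' @export
setClass("CVReport",
  slots = c(accuracies = "data.frame", mean = "numeric", sd = "numeric",
            confusion = "matrix", nFolds = "integer", nRepeats = "integer"))

#' Classification metrics report
#'
#' @slot accuracy micro-averaged accuracy (= micro precision = micro recall).
#' @slot perClass data.frame with class, precision, recall, f1, support.
#' @slot confusion integer matrix, rows = truth, columns = prediction.
#' @slot undefinedPrecision classes never predicted (precision reported as 0).
#' @export
setClass("MetricsReport",
  slots = c(accuracy = "numeric", perClass = "data.frame",
            confusion = "matrix", undefinedPrecision = "character"))
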