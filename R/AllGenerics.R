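#' Analytic trainable-parameter count of an architecture
#'
#' Computes the closed-form number of trainable parameters (weights + biases
#' per layer) from the architecture alone, without constructing a network.
#' Serves as an independent oracle for [countParameters()] on built models.
#'
#' @param object a [CNNArchitecture-class] specification.
#' @return integer parameter count.
#' @examples
#' parameterCount(arch1DCNN(nClasses = 33L)) # 211489
#' @export
setGeneric("parameterCount", function(object) standardGeneric("parameterCount"))

#' Build a CNN model from an architecture specification
#'
#' @param object a [CNNArchitecture-class].
#' @param classNames character vector of output classes (length must equal
#'   `nClasses`); defaults to `Class01`, ...
#' @param seed integer seed for Glorot-uniform weight initialization.
#' @return a [CNNModel-class].
#' @export
setGeneric("buildModel", function(object, classNames = NULL, seed = 1L)
  standardGeneric("buildModel"))

#' Trainable parameters of a built model, counted from its weight arrays
#' @param object a [CNNModel-class].
#' @return integer count (sum of lengths of all weight/bias arrays).
#' @export
setGeneric("countParameters", function(object) standardGeneric("countParameters"))

#' log2(FPKM + 1) transform
#' @param x a [PanCancerExperiment-class] holding raw FPKM values.
#' @return the object with transformed values and `logTransformed = TRUE`.
#' @export
setGeneric("logTransform", function(x) standardGeneric("logTransform"))

#' Remove low-information genes
#'
#' Retains genes whose per-gene mean and standard deviation across all samples
#' (regardless of class) meet both thresholds; genes with mean below
#' `meanThreshold` or sd below `sdThreshold` are removed.
#'
#' @param x a [PanCancerExperiment-class] on the log2(FPKM+1) scale.
#' @param meanThreshold,sdThreshold numeric cutoffs (defaults 0.5 and 0.8).
#' @return the filtered object, gene order preserved.
#' @export
setGeneric("filterLowInformation",
  function(x, meanThreshold = 0.5, sdThreshold = 0.8)
    standardGeneric("filterLowInformation"))

#' Alphabetize genes and zero-pad to a target length
#'
#' Sorts genes by symbol, then appends all-zero pseudo-genes with reserved
#' `_PAD` symbols until the gene count reaches `targetLen`.
#'
#' @param x a [PanCancerExperiment-class].
#' @param targetLen integer, final gene count (>= current count).
#' @return the padded object; `nPadding(x)` records the appended count.
#' @export
setGeneric("padAndOrder", function(x, targetLen) standardGeneric("padAndOrder"))

#' Additive per-gene Gaussian noise with clipping at zero
#'
#' Adds independent noise N(0, (k * mu_i)^2) to every entry, where mu_i is the
#' mean expression of gene i in the matrix being corrupted, then sets negative
#' values to 0.
#'
#' @param x a [PanCancerExperiment-class] or a samples x genes matrix.
#' @param k numeric noise ratio >= 0 (1 = noise sd equal to 100% of the gene
#'   mean).
#' @param seed integer RNG seed.
#' @return an object of the same type as `x`.
#' @export
setGeneric("addGaussianNoise", function(x, k, seed = 1L)
  standardGeneric("addGaussianNoise"))

#' Number of zero-padding pseudo-genes
#' @param x a [PanCancerExperiment-class].
#' @export
setGeneric("nPadding", function(x) standardGeneric("nPadding"))

#' Per-sample class labels
#' @param x a [PanCancerExperiment-class].
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))

#' Samples x genes input matrix for the CNN engine
#' @param x a [PanCancerExperiment-class].
#' @export
setGeneric("modelInput", function(x) standardGeneric("modelInput"))

#' Gene symbols (excluding padding placeholders by default)
#' @param x an object carrying gene symbols.
#' @param includePadding logical.
#' @export
setGeneric("geneSymbols", function(x, includePadding = FALSE)
  standardGeneric("geneSymbols"))

#' Gene-effect scores matrix
#' @param x a [GeneEffectMatrix-class].
#' @export
setGeneric("effectScores", function(x) standardGeneric("effectScores"))

#' Marker genes per class
#' @param x a [MarkerSet-class].
#' @export
setGeneric("markerList", function(x) standardGeneric("markerList"))

#' Unique marker genes across classes
#' @param x a [MarkerSet-class].
#' @export
setGeneric("uniqueGenes", function(x) standardGeneric("uniqueGenes"))
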