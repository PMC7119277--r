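#' Construct a PanCancerExperiment
#'
#' @param values numeric matrix, samples x genes (the orientation delimited
#'   expression tables usually arrive in) or genes x samples with
#'   `genesInRows = TRUE`.
#' @param geneSymbols character vector of unique gene symbols.
#' @param sampleIds character vector of unique sample identifiers.
#' @param labels optional per-sample class labels.
#' @param logTransformed logical; `TRUE` if values are already log2(FPKM+1).
#' @param genesInRows logical, orientation of `values`.
#' @return a [PanCancerExperiment-class].
#' @export
panCancerExperiment <- function(values, geneSymbols = colnames(values),
                                sampleIds = rownames(values), labels = NULL,
                                logTransformed = FALSE, genesInRows = FALSE) {
  values <- as.matrix(values)
  force(geneSymbols)                 # resolve defaults before transposing
  force(sampleIds)
  if (!genesInRows) values <- t(values)
  if (is.null(geneSymbols)) stop("gene symbols are required")
  if (is.null(sampleIds)) sampleIds <- sprintf("S%04d", seq_len(ncol(values)))
  if (anyDuplicated(geneSymbols)) stop("duplicate gene symbols")
  if (anyDuplicated(sampleIds)) stop("duplicate sample ids")
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop(sprintf("negative expression value at gene '%s', sample '%s'",
                 geneSymbols[neg[1, 1]], sampleIds[neg[1, 2]]))
  }
  dimnames(values) <- list(geneSymbols, sampleIds)
  cd <- S4Vectors::DataFrame(row.names = sampleIds)
  if (!is.null(labels)) {
    stopifnot(length(labels) == ncol(values))
    cd$label <- as.character(labels)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = values),
    rowData = S4Vectors::DataFrame(isPadding = rep(FALSE, nrow(values)),
                                   row.names = geneSymbols),
    colData = cd,
    metadata = list(nPadding = 0L))
  new("PanCancerExperiment", se, logTransformed = logTransformed)
}

#' Read a delimited expression table
#'
#' Reads TSV/CSV expression tables. With `orientation = "samples_in_rows"`
#' the first column holds sample ids and the remaining columns are genes;
#' with `"genes_in_rows"` the first column holds gene symbols and remaining
#' columns are samples.
#'
#' @param file path to a delimited text file (separator sniffed by
#'   [data.table::fread()]).
#' @param orientation table layout, see Details.
#' @param logTransformed logical; set `TRUE` when the file already stores
#'   log2(FPKM+1) values so that [logTransform()] can be skipped.
#' @param labelFile optional two-column (sample, label) delimited file.
#' @return a [PanCancerExperiment-class].
#' @export
readExpressionTable <- function(file,
                                orientation = c("samples_in_rows",
                                                "genes_in_rows"),
                                logTransformed = FALSE, labelFile = NULL) {
  orientation <- match.arg(orientation)
  dt <- data.table::fread(file, header = TRUE)
  ids <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (orientation == "samples_in_rows") {
    x <- panCancerExperiment(m, geneSymbols = colnames(m), sampleIds = ids,
                             logTransformed = logTransformed)
  } else {
    x <- panCancerExperiment(m, geneSymbols = ids, sampleIds = colnames(m),
                             logTransformed = logTransformed,
                             genesInRows = TRUE)
  }
  if (!is.null(labelFile)) {
    lab <- data.table::fread(labelFile, header = TRUE)
    idx <- match(colnames(x), as.character(lab[[1]]))
    if (anyNA(idx)) stop("label file is missing some samples")
    SummarizedExperiment::colData(x)$label <- as.character(lab[[2]])[idx]
  }
  x
}

#' Write an expression table (and labels) back to delimited text
#'
#' @param x a [PanCancerExperiment-class].
#' @param file output path (samples in rows, genes in columns).
#' @param labelFile optional output path for a (sample, label) table.
#' @return `file`, invisibly.
#' @export
writeExpressionTable <- function(x, file, labelFile = NULL) {
  m <- modelInput(x)
  dt <- data.table::data.table(sample = rownames(m))
  dt <- cbind(dt, data.table::as.data.table(m))
  data.table::fwrite(dt, file, sep = "\t")
  if (!is.null(labelFile)) {
    lab <- sampleLabels(x)
    if (is.null(lab)) stop("no labels to write")
    data.table::fwrite(
      data.table::data.table(sample = colnames(x), label = as.character(lab)),
      labelFile, sep = "\t")
  }
  invisible(file)
}

# ---- accessors ----

#' @rdname nPadding
#' @export
setMethod("nPadding", "PanCancerExperiment", function(x)
  S4Vectors::metadata(x)$nPadding %||% 0L)

#' @rdname sampleLabels
#' @export
setMethod("sampleLabels", "PanCancerExperiment", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if (!"label" %in% colnames(cd)) return(NULL)
  factor(cd$label, levels = orderClasses(cd$label))
})

#' @rdname modelInput
#' @export
setMethod("modelInput", "PanCancerExperiment", function(x)
  t(SummarizedExperiment::assay(x, "expr")))

#' @rdname geneSymbols
#' @export
setMethod("geneSymbols", "PanCancerExperiment",
  function(x, includePadding = FALSE) {
    if (includePadding) return(rownames(x))
    rownames(x)[!SummarizedExperiment::rowData(x)$isPadding]
  })

#' @export
setMethod("show", "PanCancerExperiment", function(object) {
  cat(sprintf("PanCancerExperiment: %d genes (%d padding) x %d samples [%s scale]\n",
              nrow(object), nPadding(object), ncol(object),
              if (object@logTransformed) "log2(FPKM+1)" else "FPKM"))
  lab <- sampleLabels(object)
  if (!is.null(lab))
    cat(sprintf("  %d classes: %s\n", nlevels(lab),
                paste(head(levels(lab), 6), collapse = ", ")))
})

# ---- transforms ----

#' @rdname logTransform
#' @export
setMethod("logTransform", "PanCancerExperiment", function(x) {
  if (x@logTransformed)
    stop("values are already on the log2(FPKM+1) scale")
  v <- SummarizedExperiment::assay(x, "expr")
  SummarizedExperiment::assay(x, "expr") <- log2(v + 1)
  x@logTransformed <- TRUE
  validObject(x)
  x
})

#' @rdname filterLowInformation
#' @export
setMethod("filterLowInformation", "PanCancerExperiment",
  function(x, meanThreshold = 0.5, sdThreshold = 0.8) {
    stopifnot(meanThreshold >= 0, sdThreshold >= 0)
    if (ncol(x) < 2)
      stop("at least 2 samples are required (gene sd undefined otherwise)")
    v <- SummarizedExperiment::assay(x, "expr")
    mu <- rowMeans(v)
    # sample (n-1 denominator) standard deviation per gene
    sdv <- sqrt(rowSums((v - mu)^2) / (ncol(v) - 1))
    keep <- mu >= meanThreshold & sdv >= sdThreshold
    x[keep, ]
  })

#' @rdname padAndOrder
#' @export
setMethod("padAndOrder", "PanCancerExperiment", function(x, targetLen) {
  targetLen <- as.integer(targetLen)
  if (nPadding(x) > 0) stop("object is already padded")
  if (targetLen < nrow(x))
    stop(sprintf("targetLen %d < gene count %d", targetLen, nrow(x)))
  x <- x[order(rownames(x)), ]
  nPad <- targetLen - nrow(x)
  md <- S4Vectors::metadata(x)
  if (nPad > 0) {
    padSymbols <- sprintf("_PAD%03d", seq_len(nPad))
    padValues <- matrix(0, nrow = nPad, ncol = ncol(x),
                        dimnames = list(padSymbols, colnames(x)))
    pad <- SummarizedExperiment::SummarizedExperiment(
      assays = list(expr = padValues),
      rowData = S4Vectors::DataFrame(isPadding = rep(TRUE, nPad),
                                     row.names = padSymbols),
      colData = SummarizedExperiment::colData(x))
    pad <- new("PanCancerExperiment", pad, logTransformed = x@logTransformed)
    x <- rbind(x, pad)
  }
  md$nPadding <- nPad
  S4Vectors::metadata(x) <- md
  validObject(x)
  x
})

#' Reshape a sample vector into the 2D input grid (row-major)
#'
#' Element (r, c) of the grid is `v[(r-1)*cols + c]`: the canonical row-major
#' fill used for the 2D architectures, chosen so that
#' `flattenGrid(reshapeToGrid(v))` is the identity.
#'
#' @param v numeric vector of length `rows * cols`.
#' @param rows,cols grid shape (defaults 100 x 71 for the 7100-gene vector).
#' @return a `rows` x `cols` matrix.
#' @export
reshapeToGrid <- function(v, rows = 100L, cols = 71L) {
  if (length(v) != rows * cols)
    stop(sprintf("vector length %d != rows*cols = %d", length(v), rows * cols))
  matrix(v, nrow = rows, ncol = cols, byrow = TRUE)
}

#' Flatten a grid back to the row-major sample vector
#' @param m matrix produced by [reshapeToGrid()].
#' @return numeric vector.
#' @export
flattenGrid <- function(m) as.vector(t(m))

#' Full preprocessing pipeline: log transform, filter, alphabetize, pad
#'
#' @param x a [PanCancerExperiment-class] (raw FPKM unless `logTransformed`).
#' @param meanThreshold,sdThreshold filter cutoffs.
#' @param targetLen padded vector length; `NULL` pads to the next multiple of
#'   `roundTo`.
#' @param roundTo used only when `targetLen` is `NULL`.
#' @return the processed [PanCancerExperiment-class].
#' @export
preprocessExpression <- function(x, meanThreshold = 0.5, sdThreshold = 0.8,
                                 targetLen = NULL, roundTo = 100L) {
  if (!x@logTransformed) x <- logTransform(x)
  x <- filterLowInformation(x, meanThreshold, sdThreshold)
  if (is.null(targetLen))
    targetLen <- as.integer(roundTo * ceiling(nrow(x) / roundTo))
  padAndOrder(x, targetLen)
}

#' Class display/encoding order: alphabetical with "Normal" last
#' @param labels character or factor class labels.
#' @return character vector of ordered unique class names.
#' @export
orderClasses <- function(labels) {
  cl <- sort(unique(as.character(labels)))
  if ("Normal" %in% cl) cl <- c(setdiff(cl, "Normal"), "Normal")
  cl
}

`%||%` <- function(a, b) if (is.null(a)) b else a
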