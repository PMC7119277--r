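#' Guided gradient saliency of one output class with respect to the input
#'
#' Backpropagates the target class's output (its softmax probability by
#' default, or its pre-softmax logit) to the input genes with guided rules:
#' at every rectifier, gradient is suppressed where
#' the unit was inactive or the incoming gradient is negative; max-pooling
#' routes gradient to the winning position; negative input-level values are
#' set to 0 so that only positive evidence for the class is reported.
#'
#' @param model trained [CNNModel-class].
#' @param x one sample vector, a samples x genes matrix, or a
#'   [PanCancerExperiment-class].
#' @param classIndex integer output node (1-based) or class name.
#' @param nPadding trailing padding features to drop from the result
#'   (taken from `x` automatically when it is a PanCancerExperiment).
#' @param wrt differentiate the class's `"softmax"` probability (default;
#'   class-discriminative, since competing classes enter negatively through
#'   the softmax Jacobian) or its pre-softmax `"logit"`.
#' @return samples x realGenes matrix of non-negative saliency values (a
#'   vector input returns a single-row matrix).
#' @export
guidedSaliency <- function(model, x, classIndex, nPadding = 0L,
                           wrt = c("softmax", "logit")) {
  wrt <- match.arg(wrt)
  if (!model@trained) warning("model is untrained; saliency reflects random weights")
  if (is(x, "PanCancerExperiment")) {
    nPadding <- nPadding(x)
    x <- modelInput(x)
  }
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (is.character(classIndex))
    classIndex <- match(classIndex, model@classNames)
  if (is.na(classIndex) || classIndex < 1 ||
      classIndex > length(model@classNames))
    stop("classIndex out of range")
  if (ncol(x) != modelInputLength(model))
    stop(sprintf("input has %d features but model expects %d", ncol(x),
                 modelInputLength(model)))
  s <- .guidedBackprop(model, x, as.integer(classIndex), wrt = wrt)
  if (nPadding > 0) s <- s[, seq_len(ncol(s) - nPadding), drop = FALSE]
  s
}

#' Gene-effect matrix: class-averaged guided saliency on the unit scale
#'
#' For each class, the guided saliency with respect to that class's output
#' node is averaged over all samples of the class; columns are then scaled so
#' the top gene of each class scores exactly 1 (`scaling = "perClass"`,
#' making the marker threshold comparable across classes) or jointly by the
#' global maximum (`scaling = "global"`). Padding pseudo-genes are excluded.
#'
#' @param model trained [CNNModel-class].
#' @param x labelled [PanCancerExperiment-class], or samples x genes matrix.
#' @param labels class labels (required for a matrix input).
#' @param scaling `"perClass"` (default) or `"global"`.
#' @param nPadding trailing padding features (automatic for a
#'   PanCancerExperiment).
#' @param batchSize samples per backprop batch.
#' @param wrt differentiated quantity, see [guidedSaliency()].
#' @return a [GeneEffectMatrix-class] (genes x classes).
#' @export
geneEffectMatrix <- function(model, x, labels = NULL,
                             scaling = c("perClass", "global"),
                             nPadding = 0L, batchSize = 256L,
                             wrt = c("softmax", "logit")) {
  scaling <- match.arg(scaling)
  wrt <- match.arg(wrt)
  geneNames <- NULL
  if (is(x, "PanCancerExperiment")) {
    nPadding <- nPadding(x)
    geneNames <- geneSymbols(x)
    if (is.null(labels)) labels <- sampleLabels(x)
    x <- modelInput(x)
  }
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(x))
  classNames <- model@classNames
  missing <- setdiff(classNames, labels)
  if (length(missing))
    stop(sprintf("class(es) with no samples: %s",
                 paste(missing, collapse = ", ")))
  nReal <- ncol(x) - nPadding
  if (is.null(geneNames)) geneNames <- sprintf("gene%05d", seq_len(nReal))
  scores <- matrix(0, nReal, length(classNames),
                   dimnames = list(geneNames, classNames))
  for (ci in seq_along(classNames)) {
    idx <- which(labels == classNames[ci])
    acc <- numeric(nReal)
    for (s in seq(1L, length(idx), by = batchSize)) {
      b <- idx[s:min(s + batchSize - 1L, length(idx))]
      sal <- guidedSaliency(model, x[b, , drop = FALSE], ci,
                            nPadding = nPadding, wrt = wrt)
      acc <- acc + colSums(sal)
    }
    scores[, ci] <- acc / length(idx)
  }
  if (scaling == "perClass") {
    mx <- apply(scores, 2, max)
    mx[mx == 0] <- 1
    scores <- sweep(scores, 2, mx, "/")
  } else {
    mx <- max(scores)
    if (mx > 0) scores <- scores / mx
  }
  new("GeneEffectMatrix", scores = scores, scaling = scaling)
}

#' @rdname effectScores
#' @export
setMethod("effectScores", "GeneEffectMatrix", function(x) x@scores)

#' @export
setMethod("show", "GeneEffectMatrix", function(object) {
  cat(sprintf("GeneEffectMatrix: %d genes x %d classes (%s scaling)\n",
              nrow(object@scores), ncol(object@scores), object@scaling))
})

#' Write a gene-effect matrix as TSV
#' @param x a [GeneEffectMatrix-class].
#' @param file output path.
#' @export
writeGeneEffectMatrix <- function(x, file) {
  dt <- data.table::data.table(gene = rownames(x@scores))
  dt <- cbind(dt, data.table::as.data.table(x@scores))
  data.table::fwrite(dt, file, sep = "\t")
  invisible(file)
}

#' Select marker genes from a gene-effect matrix
#'
#' A gene is a marker for a class when its gene-effect score exceeds
#' `threshold` (default 0.5, the published rule). A gene may mark several
#' classes; [uniqueGenes()] counts the union.
#'
#' @param gem a [GeneEffectMatrix-class].
#' @param threshold score cutoff in [0, 1).
#' @return a [MarkerSet-class].
#' @export
selectMarkers <- function(gem, threshold = 0.5) {
  stopifnot(threshold >= 0, threshold < 1)
  s <- effectScores(gem)
  markers <- lapply(colnames(s), function(cl) {
    sel <- which(s[, cl] > threshold)
    df <- data.frame(gene = rownames(s)[sel], score = s[sel, cl],
                     row.names = NULL)
    df[order(-df$score), , drop = FALSE]
  })
  names(markers) <- colnames(s)
  new("MarkerSet", markers = markers, threshold = threshold)
}

#' @rdname markerList
#' @export
setMethod("markerList", "MarkerSet", function(x) x@markers)

#' @rdname uniqueGenes
#' @export
setMethod("uniqueGenes", "MarkerSet", function(x)
  unique(unlist(lapply(x@markers, `[[`, "gene"), use.names = FALSE)))

#' Total marker count (with multiplicity across classes)
#' @param x a [MarkerSet-class].
#' @export
markerCount <- function(x) sum(vapply(x@markers, nrow, integer(1)))

#' @export
setMethod("show", "MarkerSet", function(object) {
  cat(sprintf(
    "MarkerSet (score > %.2f): %d markers across %d classes, %d unique genes\n",
    object@threshold, markerCount(object), length(object@markers),
    length(uniqueGenes(object))))
})

#' Write a marker set as TSV (class, gene, score)
#' @param x a [MarkerSet-class].
#' @param file output path.
#' @export
writeMarkerSet <- function(x, file) {
  dt <- data.table::rbindlist(
    lapply(names(x@markers), function(cl) {
      df <- x@markers[[cl]]
      if (nrow(df) == 0) return(NULL)
      data.table::data.table(class = cl, gene = df$gene, score = df$score)
    }))
  data.table::fwrite(dt, file, sep = "\t")
  invisible(file)
}

#' Differential-expression concordance of marker genes
#'
#' For every gene, computes the absolute difference between its mean
#' expression in `className` and in all other samples (log2(FPKM+1) scale),
#' then tests one-sidedly (Welch t-test) whether markers of that class have
#' larger differences than non-markers.
#'
#' @param markers a [MarkerSet-class] or character vector of marker genes.
#' @param x labelled [PanCancerExperiment-class] or samples x genes matrix.
#' @param labels class labels (if `x` is a matrix).
#' @param className the class whose markers are examined.
#' @return list with `differences` (named per-gene vector), `markerMean`,
#'   `nonMarkerMean`, `statistic`, `p.value` and `degenerate` (TRUE when the
#'   test is undefined, reported as non-significant with p = 1).
#' @export
markerConcordance <- function(markers, x, labels = NULL, className) {
  if (is(markers, "MarkerSet")) {
    if (!className %in% names(markers@markers))
      stop(sprintf("class '%s' absent from the marker set", className))
    markers <- markers@markers[[className]]$gene
  }
  geneNames <- NULL
  if (is(x, "PanCancerExperiment")) {
    geneNames <- geneSymbols(x)
    if (is.null(labels)) labels <- sampleLabels(x)
    x <- modelInput(x)[, seq_along(geneNames), drop = FALSE]
  }
  labels <- as.character(labels)
  if (!className %in% labels)
    stop(sprintf("class '%s' absent from labels", className))
  if (is.null(geneNames)) geneNames <- colnames(x)
  inClass <- labels == className
  diffs <- abs(colMeans(x[inClass, , drop = FALSE]) -
                 colMeans(x[!inClass, , drop = FALSE]))
  names(diffs) <- geneNames
  isMarker <- geneNames %in% markers
  if (!any(isMarker) || all(isMarker))
    stop("need at least one marker and one non-marker gene")
  mDiff <- diffs[isMarker]
  nDiff <- diffs[!isMarker]
  tt <- try(t.test(mDiff, nDiff, alternative = "greater"), silent = TRUE)
  degenerate <- inherits(tt, "try-error") || !is.finite(tt$p.value)
  list(differences = diffs,
       markerMean = mean(mDiff), nonMarkerMean = mean(nDiff),
       statistic = if (degenerate) NA_real_ else unname(tt$statistic),
       p.value = if (degenerate) 1 else tt$p.value,
       degenerate = degenerate)
}

#' Read a GMT gene-set collection
#'
#' @param file path to a GMT file (set name, description, tab-separated
#'   member symbols per line).
#' @return named list of character vectors.
#' @export
readGmt <- function(file) fgsea::gmtPathways(file)

#' One-tailed Fisher enrichment of marker genes in gene sets
#'
#' For each gene set, tests over-representation of `markerGenes` within
#' `universe` by a one-tailed (greater) Fisher exact test on the 2x2 table of
#' set membership x marker membership. Symbols are matched case-insensitively
#' after whitespace stripping. Sets with no overlap with the universe are
#' skipped with a warning.
#'
#' @param markerGenes character vector (must be contained in `universe`).
#' @param geneSets named list of character vectors (e.g. from [readGmt()]).
#' @param universe character vector of all candidate genes (e.g. all
#'   post-filter genes).
#' @param alpha significance cutoff for the `significant` flag
#'   (default 0.001).
#' @return data.frame with set, setSize, overlap, p and significant, ordered
#'   by increasing p.
#' @export
geneSetEnrichment <- function(markerGenes, geneSets, universe, alpha = 0.001) {
  norm <- function(v) toupper(trimws(v))
  universe <- unique(norm(universe))
  if (length(universe) == 0) stop("empty universe")
  markerGenes <- unique(norm(markerGenes))
  if (!all(markerGenes %in% universe))
    stop("markerGenes must be a subset of the universe")
  nU <- length(universe)
  nM <- length(markerGenes)
  rows <- lapply(names(geneSets), function(nm) {
    set <- intersect(norm(geneSets[[nm]]), universe)
    if (length(set) == 0) {
      warning(sprintf("gene set '%s' has no overlap with the universe; skipped",
                      nm))
      return(NULL)
    }
    a <- length(intersect(set, markerGenes))          # in set & marker
    tab <- matrix(c(a, length(set) - a,
                    nM - a, nU - length(set) - (nM - a)), nrow = 2)
    p <- fisher.test(tab, alternative = "greater")$p.value
    data.frame(set = nm, setSize = length(set), overlap = a, p = p)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(set = character(), setSize = integer(),
                      overlap = integer(), p = numeric(),
                      significant = logical()))
  out$significant <- out$p < alpha
  out[order(out$p), , drop = FALSE]
}
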