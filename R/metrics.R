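#' Multi-class classification metrics
#'
#' Micro-averaged accuracy (= trace of the confusion matrix over its total,
#' which in single-label multi-class problems equals micro precision and
#' micro recall) plus per-class precision, recall, F1 and support. Precision
#' of a class that is never predicted is undefined; it is reported as 0 and
#' the class is listed in `undefinedPrecision`.
#'
#' @param true,predicted equal-length label vectors.
#' @param classOrder character class ordering for the report; defaults to
#'   [orderClasses()] of the union of labels. All labels must be covered.
#' @return a [MetricsReport-class].
#' @export
computeMetrics <- function(true, predicted, classOrder = NULL) {
  true <- as.character(true)
  predicted <- as.character(predicted)
  stopifnot(length(true) == length(predicted))
  if (is.null(classOrder)) classOrder <- orderClasses(c(true, predicted))
  unknown <- setdiff(unique(c(true, predicted)), classOrder)
  if (length(unknown))
    stop(sprintf("label(s) not in classOrder: %s",
                 paste(unknown, collapse = ", ")))
  conf <- unclass(table(factor(true, levels = classOrder),
                        factor(predicted, levels = classOrder)))
  names(dimnames(conf)) <- c("truth", "predicted")
  diagv <- diag(conf)
  support <- rowSums(conf)
  predTot <- colSums(conf)
  precision <- ifelse(predTot > 0, diagv / predTot, 0)
  recall <- ifelse(support > 0, diagv / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  new("MetricsReport",
      accuracy = sum(diagv) / sum(conf),
      perClass = data.frame(class = classOrder, precision = precision,
                            recall = recall, f1 = f1,
                            support = as.integer(support), row.names = NULL),
      confusion = conf,
      undefinedPrecision = classOrder[predTot == 0])
}

#' @export
setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport: micro accuracy %.4f over %d samples\n",
              object@accuracy, sum(object@confusion)))
  print(object@perClass, row.names = FALSE, digits = 3)
  if (length(object@undefinedPrecision))
    cat("precision undefined (reported 0) for:",
        paste(object@undefinedPrecision, collapse = ", "), "\n")
})

#' Render a confusion-matrix heatmap and write the matrix as TSV
#'
#' @param report a [MetricsReport-class].
#' @param file output image path (.png); the matrix is written next to it
#'   with extension `.tsv`.
#' @param normalize `"none"` for raw counts or `"row"` for the recall view
#'   (rows scaled to sum to 1).
#' @return invisible list with `image` and `tsv` paths.
#' @export
confusionHeatmap <- function(report, file, normalize = c("none", "row")) {
  normalize <- match.arg(normalize)
  m <- report@confusion
  if (normalize == "row") {
    rs <- rowSums(m)
    rs[rs == 0] <- 1
    m <- m / rs
  }
  tsv <- sub("\\.[^.]+$", ".tsv", file)
  dt <- data.table::data.table(truth = rownames(m))
  dt <- cbind(dt, data.table::as.data.table(as.matrix(m)))
  data.table::fwrite(dt, tsv, sep = "\t")
  pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
                     filename = file, silent = TRUE)
  invisible(list(image = file, tsv = tsv))
}

#' Read a confusion matrix written by [confusionHeatmap()]
#' @param tsv path to the TSV file.
#' @return numeric matrix with truth rows and predicted columns.
#' @export
readConfusionTsv <- function(tsv) {
  dt <- data.table::fread(tsv, header = TRUE)
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- as.character(dt[[1]])
  m
}
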