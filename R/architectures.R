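#' 1D-CNN architecture constructor
#'
#' Canonical settings follow the selected grid-search configuration: 32
#' kernels of length 71 with stride equal to the kernel length
#' (non-overlapping windows over the 7100-gene vector), max-pooling of size 2,
#' and a 128-unit fully connected layer before the softmax prediction layer.
#'
#' @param inputLen padded gene-vector length (default 7100).
#' @param nFilters number of convolution kernels (default 32).
#' @param kernelLen kernel length = stride (default 71).
#' @param poolSize max-pooling window (default 2).
#' @param denseUnits fully connected layer width; 0 removes the layer
#'   (default 128).
#' @param nClasses number of output classes.
#' @return a [Conv1DArchitecture-class].
#' @examples
#' parameterCount(arch1DCNN(nClasses = 33L)) # 211489
#' @export
arch1DCNN <- function(inputLen = 7100L, nFilters = 32L, kernelLen = 71L,
                      poolSize = 2L, denseUnits = 128L, nClasses = 34L) {
  new("Conv1DArchitecture", inputLen = as.integer(inputLen),
      nFilters = as.integer(nFilters), kernelLen = as.integer(kernelLen),
      poolSize = as.integer(poolSize), denseUnits = as.integer(denseUnits),
      nClasses = as.integer(nClasses))
}

#' Breast-cancer subtype variant of the 1D-CNN
#'
#' The canonical 1D-CNN with the fully connected layer removed and (by
#' default) 5 output nodes: convolution, max-pooling, then the softmax
#' prediction layer directly.
#'
#' @param nClasses number of subtype classes (default 5).
#' @param inputLen,nFilters,kernelLen,poolSize as in [arch1DCNN()].
#' @return a [Conv1DArchitecture-class] with `denseUnits = 0`.
#' @examples
#' parameterCount(archBRCA1DCNN()) # 10309
#' @export
archBRCA1DCNN <- function(nClasses = 5L, inputLen = 7100L, nFilters = 32L,
                          kernelLen = 71L, poolSize = 2L) {
  arch1DCNN(inputLen = inputLen, nFilters = nFilters, kernelLen = kernelLen,
            poolSize = poolSize, denseUnits = 0L, nClasses = nClasses)
}

#' 2D-Vanilla-CNN architecture constructor
#'
#' One strided, valid-padding 2D convolution over the row-major 100 x 71 gene
#' grid, 2 x 2 max-pooling (floor semantics), a fully connected layer and the
#' softmax prediction layer. Defaults are the selected grid-search row:
#' 32 kernels of 10 x 10 with stride 2 x 2 and a 128-unit dense layer.
#'
#' @param inputRows,inputCols grid shape (defaults 100, 71).
#' @param nFilters number of kernels (default 32).
#' @param kernelRows,kernelCols kernel shape (defaults 10, 10).
#' @param strideRows,strideCols strides (defaults 2, 2).
#' @param poolRows,poolCols pooling window (defaults 2, 2).
#' @param denseUnits dense width (default 128).
#' @param nClasses number of output classes.
#' @return a [Conv2DVanillaArchitecture-class].
#' @examples
#' parameterCount(arch2DVanillaCNN(nClasses = 33L)) # 1420737
#' @export
arch2DVanillaCNN <- function(inputRows = 100L, inputCols = 71L,
                             nFilters = 32L, kernelRows = 10L,
                             kernelCols = 10L, strideRows = 2L,
                             strideCols = 2L, poolRows = 2L, poolCols = 2L,
                             denseUnits = 128L, nClasses = 34L) {
  new("Conv2DVanillaArchitecture", inputRows = as.integer(inputRows),
      inputCols = as.integer(inputCols), nFilters = as.integer(nFilters),
      kernelRows = as.integer(kernelRows), kernelCols = as.integer(kernelCols),
      strideRows = as.integer(strideRows), strideCols = as.integer(strideCols),
      poolRows = as.integer(poolRows), poolCols = as.integer(poolCols),
      denseUnits = as.integer(denseUnits), nClasses = as.integer(nClasses))
}

#' 2D-Hybrid-CNN architecture constructor
#'
#' Two parallel 1D kernels over the gene grid: a row-sized kernel sliding
#' vertically (one output per row) and a column-sized kernel sliding
#' horizontally (one output per column). Each branch is ReLU-activated,
#' max-pooled with window 2 (ceiling semantics on odd lengths: 100 -> 50,
#' 71 -> 36), then the branches are concatenated and fed to the fully
#' connected and prediction layers.
#'
#' @param inputRows,inputCols grid shape (defaults 100, 71).
#' @param nFilters kernels per branch (default 32).
#' @param poolSize per-branch pooling window (default 2).
#' @param denseUnits dense width (default 128).
#' @param nClasses number of output classes.
#' @return a [Conv2DHybridArchitecture-class].
#' @examples
#' parameterCount(arch2DHybridCNN(nClasses = 33L)) # 362177
#' @export
arch2DHybridCNN <- function(inputRows = 100L, inputCols = 71L, nFilters = 32L,
                            poolSize = 2L, denseUnits = 128L, nClasses = 34L) {
  new("Conv2DHybridArchitecture", inputRows = as.integer(inputRows),
      inputCols = as.integer(inputCols), nFilters = as.integer(nFilters),
      poolSize = as.integer(poolSize), denseUnits = as.integer(denseUnits),
      nClasses = as.integer(nClasses))
}

# ---- analytic parameter-count oracle ----

.denseAndOut <- function(flatLen, denseUnits, nClasses) {
  if (denseUnits > 0) {
    flatLen * denseUnits + denseUnits + denseUnits * nClasses + nClasses
  } else {
    flatLen * nClasses + nClasses
  }
}

#' @rdname parameterCount
#' @export
setMethod("parameterCount", "Conv1DArchitecture", function(object) {
  conv <- object@nFilters * (object@kernelLen + 1L)
  nWin <- object@inputLen %/% object@kernelLen
  flat <- (nWin %/% object@poolSize) * object@nFilters
  as.integer(conv + .denseAndOut(flat, object@denseUnits, object@nClasses))
})

#' @rdname parameterCount
#' @export
setMethod("parameterCount", "Conv2DVanillaArchitecture", function(object) {
  conv <- object@nFilters * (object@kernelRows * object@kernelCols + 1L)
  or <- (object@inputRows - object@kernelRows) %/% object@strideRows + 1L
  oc <- (object@inputCols - object@kernelCols) %/% object@strideCols + 1L
  flat <- (or %/% object@poolRows) * (oc %/% object@poolCols) * object@nFilters
  as.integer(conv + .denseAndOut(flat, object@denseUnits, object@nClasses))
})

#' @rdname parameterCount
#' @export
setMethod("parameterCount", "Conv2DHybridArchitecture", function(object) {
  convV <- object@nFilters * (object@inputCols + 1L)  # row-sized kernel
  convH <- object@nFilters * (object@inputRows + 1L)  # column-sized kernel
  pv <- as.integer(ceiling(object@inputRows / object@poolSize))
  ph <- as.integer(ceiling(object@inputCols / object@poolSize))
  flat <- (pv + ph) * object@nFilters
  as.integer(convV + convH +
               .denseAndOut(flat, object@denseUnits, object@nClasses))
})

# ---- model construction ----

# Pooling map over P positions with window `size`; "floor" drops a trailing
# partial window (keras valid pooling), "ceiling" keeps it (padding the group
# by repeating its first member, which leaves the max unchanged).
.poolMap <- function(P, size, rule = c("floor", "ceiling")) {
  rule <- match.arg(rule)
  G <- if (rule == "floor") P %/% size else as.integer(ceiling(P / size))
  members <- matrix(0L, G, size)
  for (g in seq_len(G)) {
    lo <- (g - 1L) * size + 1L
    hi <- min(g * size, P)
    mem <- lo:hi
    members[g, ] <- mem[c(seq_along(mem), rep(1L, size - length(mem)))]
  }
  list(G = G, members = members)
}

# 2D pooling over an or x oc grid of patches laid out row-major.
.poolMap2D <- function(or, oc, pr, pc) {
  Gr <- or %/% pr; Gc <- oc %/% pc
  members <- matrix(0L, Gr * Gc, pr * pc)
  for (qr in seq_len(Gr)) for (qc in seq_len(Gc)) {
    g <- (qr - 1L) * Gc + qc
    rows <- ((qr - 1L) * pr + 1L):(qr * pr)
    cols <- ((qc - 1L) * pc + 1L):(qc * pc)
    members[g, ] <- as.integer(outer((rows - 1L) * oc, cols, "+"))
  }
  list(G = Gr * Gc, members = members)
}

.glorot <- function(fanIn, fanOut, nr, nc) {
  lim <- sqrt(6 / (fanIn + fanOut))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

# Glorot-uniform for a convolution kernel with the receptive-field fan
# convention (fan_in = kernelLen * inChannels, fan_out = kernelLen * filters).
.glorotConv <- function(kernelLen, nFilters) {
  .glorot(kernelLen, kernelLen * nFilters, kernelLen, nFilters)
}

.makeBranch <- function(idx, W, b, pool) {
  list(idx = idx, idxVec = as.vector(t(idx)), K = ncol(idx), P = nrow(idx),
       Fn = ncol(W), W = W, b = b, poolMembers = pool$members, G = pool$G)
}

.finishModel <- function(arch, branches, flatLen, classNames, inputLen) {
  D <- arch@denseUnits; C <- arch@nClasses
  if (is.null(classNames)) classNames <- sprintf("Class%02d", seq_len(C))
  if (length(classNames) != C)
    stop(sprintf("classNames length %d != nClasses %d", length(classNames), C))
  if (D > 0) {
    denseW <- .glorot(flatLen, D, flatLen, D)
    denseB <- numeric(D)
    outW <- .glorot(D, C, D, C)
  } else {
    denseW <- matrix(numeric(0), 0, 0)
    denseB <- numeric(0)
    outW <- .glorot(flatLen, C, flatLen, C)
  }
  m <- new("CNNModel", architecture = arch, branches = branches,
           denseW = denseW, denseB = denseB, outW = outW, outB = numeric(C),
           classNames = classNames, trained = FALSE,
           history = data.frame())
  stopifnot(countParameters(m) == parameterCount(arch))
  m
}

#' @rdname buildModel
#' @export
setMethod("buildModel", "Conv1DArchitecture",
  function(object, classNames = NULL, seed = 1L) {
    validObject(object)
    if (!is.null(seed)) set.seed(as.integer(seed))
    K <- object@kernelLen
    P <- object@inputLen %/% K
    idx <- matrix(seq_len(object@inputLen), nrow = P, ncol = K, byrow = TRUE)
    Fn <- object@nFilters
    W <- .glorotConv(K, Fn)
    pool <- .poolMap(P, object@poolSize, "floor")
    br <- .makeBranch(idx, W, numeric(Fn), pool)
    .finishModel(object, list(br), pool$G * Fn, classNames, object@inputLen)
  })

#' @rdname buildModel
#' @export
setMethod("buildModel", "Conv2DVanillaArchitecture",
  function(object, classNames = NULL, seed = 1L) {
    validObject(object)
    if (!is.null(seed)) set.seed(as.integer(seed))
    R <- object@inputRows; Cc <- object@inputCols
    kr <- object@kernelRows; kc <- object@kernelCols
    or <- (R - kr) %/% object@strideRows + 1L
    oc <- (Cc - kc) %/% object@strideCols + 1L
    idx <- matrix(0L, or * oc, kr * kc)
    for (pr in seq_len(or)) for (pc in seq_len(oc)) {
      r0 <- (pr - 1L) * object@strideRows
      c0 <- (pc - 1L) * object@strideCols
      # row-major grid: feature of cell (r, c) is (r-1)*inputCols + c
      cell <- as.integer(t(outer((r0 + seq_len(kr) - 1L) * Cc,
                                 c0 + seq_len(kc), "+")))
      idx[(pr - 1L) * oc + pc, ] <- cell
    }
    Fn <- object@nFilters
    W <- .glorotConv(kr * kc, Fn)
    pool <- .poolMap2D(or, oc, object@poolRows, object@poolCols)
    br <- .makeBranch(idx, W, numeric(Fn), pool)
    .finishModel(object, list(br), pool$G * Fn, classNames,
                 R * Cc)
  })

#' @rdname buildModel
#' @export
setMethod("buildModel", "Conv2DHybridArchitecture",
  function(object, classNames = NULL, seed = 1L) {
    validObject(object)
    if (!is.null(seed)) set.seed(as.integer(seed))
    R <- object@inputRows; Cc <- object@inputCols
    Fn <- object@nFilters
    # vertical branch: row-sized kernel, one position per grid row
    idxV <- matrix(seq_len(R * Cc), nrow = R, ncol = Cc, byrow = TRUE)
    poolV <- .poolMap(R, object@poolSize, "ceiling")
    brV <- .makeBranch(idxV, .glorotConv(Cc, Fn), numeric(Fn), poolV)
    # horizontal branch: column-sized kernel, one position per grid column
    idxH <- matrix(0L, Cc, R)
    for (p in seq_len(Cc)) idxH[p, ] <- (seq_len(R) - 1L) * Cc + p
    poolH <- .poolMap(Cc, object@poolSize, "ceiling")
    brH <- .makeBranch(idxH, .glorotConv(R, Fn), numeric(Fn), poolH)
    .finishModel(object, list(brV, brH), (poolV$G + poolH$G) * Fn,
                 classNames, R * Cc)
  })

#' @rdname countParameters
#' @export
setMethod("countParameters", "CNNModel", function(object) {
  n <- sum(vapply(object@branches,
                  function(br) length(br$W) + length(br$b), numeric(1)))
  as.integer(n + length(object@denseW) + length(object@denseB) +
               length(object@outW) + length(object@outB))
})

# Dense-only softmax model (no convolution, no ReLU); used for closed-form
# gradient checks of the saliency machinery and available for baselines.
.denseSoftmaxModel <- function(W, b = NULL, classNames = NULL) {
  C <- ncol(W)
  if (is.null(b)) b <- numeric(C)
  if (is.null(classNames)) classNames <- sprintf("Class%02d", seq_len(C))
  arch <- arch1DCNN(inputLen = nrow(W), nFilters = 1L, kernelLen = 1L,
                    poolSize = 1L, denseUnits = 0L, nClasses = C)
  new("CNNModel", architecture = arch, branches = list(),
      denseW = matrix(numeric(0), 0, 0), denseB = numeric(0),
      outW = W, outB = as.numeric(b), classNames = classNames,
      trained = TRUE, history = data.frame())
}

#' Expected model input length of a built model
#' @param model a [CNNModel-class].
#' @return integer.
#' @export
modelInputLength <- function(model) {
  a <- model@architecture
  if (is(a, "Conv1DArchitecture")) return(a@inputLen)
  a@inputRows * a@inputCols
}

#' Layer-by-layer description of a model
#'
#' @param model a [CNNModel-class].
#' @return data.frame with layer, outputShape and nParameters columns; total
#'   parameter count as attribute `"total"`.
#' @export
describeModel <- function(model) {
  rows <- list()
  for (i in seq_along(model@branches)) {
    br <- model@branches[[i]]
    rows[[length(rows) + 1L]] <- data.frame(
      layer = sprintf("conv_branch%d (ReLU)", i),
      outputShape = sprintf("%d x %d", br$P, br$Fn),
      nParameters = length(br$W) + length(br$b))
    rows[[length(rows) + 1L]] <- data.frame(
      layer = sprintf("maxpool_branch%d", i),
      outputShape = sprintf("%d x %d", br$G, br$Fn),
      nParameters = 0L)
  }
  if (length(model@denseB) > 0)
    rows[[length(rows) + 1L]] <- data.frame(
      layer = "dense (ReLU)", outputShape = sprintf("%d", ncol(model@denseW)),
      nParameters = length(model@denseW) + length(model@denseB))
  rows[[length(rows) + 1L]] <- data.frame(
    layer = "prediction (softmax)",
    outputShape = sprintf("%d", length(model@classNames)),
    nParameters = length(model@outW) + length(model@outB))
  out <- do.call(rbind, rows)
  attr(out, "total") <- countParameters(model)
  out
}

#' @export
setMethod("show", "CNNModel", function(object) {
  cat(sprintf("CNNModel <%s>: %s parameters, %d classes, %s\n",
              class(object@architecture),
              format(countParameters(object), big.mark = ","),
              length(object@classNames),
              if (object@trained) "trained" else "untrained"))
  print(describeModel(object), row.names = FALSE)
})

#' @export
setMethod("show", "CNNArchitecture", function(object) {
  cat(sprintf("%s: %s trainable parameters (%d classes)\n", class(object),
              format(parameterCount(object), big.mark = ","), object@nClasses))
})
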