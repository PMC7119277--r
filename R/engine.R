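# Internal CNN engine.
#
# Every convolution in the three shallow topologies reduces to a gather +
# matrix multiply: a branch stores an index matrix `idx` (patches x patchLen)
# of positions into the flat input vector, a kernel matrix W (patchLen x
# nFilters) and a bias, plus a pooling map `poolMembers` (pooledLen x
# windowSize) of patch indices. Batches are processed with sample-major row
# blocks so that a whole batch is a single BLAS call per branch.

# Gather the (n*P) x K patch matrix for a batch X (n x inputLen).
.patchMatrix <- function(X, branch) {
  Xp <- X[, branch$idxVec, drop = FALSE]           # n x (P*K)
  matrix(t(Xp), ncol = branch$K, byrow = TRUE)     # (n*P) x K, sample-major
}

# Max-pool Z ((n*P) x F) into ((n*G) x F); returns pooled values and the
# winning member index per (pooled row, filter), used for gradient routing.
.poolForward <- function(Z, branch, n) {
  P <- branch$P; G <- branch$G
  members <- branch$poolMembers                    # G x m
  m <- ncol(members)
  offs <- (seq_len(n) - 1L) * P
  pooled <- NULL
  winner <- NULL
  for (j in seq_len(m)) {
    idx <- as.vector(outer(members[, j], offs, "+"))  # (G*n), sample-major
    cand <- Z[idx, , drop = FALSE]
    if (is.null(pooled)) {
      pooled <- cand
      winner <- matrix(1L, nrow(cand), ncol(cand))
    } else {
      upd <- cand > pooled
      pooled[upd] <- cand[upd]
      winner[upd] <- j
    }
  }
  list(values = pooled, winner = winner)
}

# Route pooled gradients back to patch rows: ((n*G) x F) -> ((n*P) x F).
.poolBackward <- function(dPooled, winner, branch, n) {
  P <- branch$P; G <- branch$G
  members <- branch$poolMembers
  offs <- (seq_len(n) - 1L) * P
  dZ <- matrix(0, n * P, ncol(dPooled))
  for (j in seq_len(ncol(members))) {
    sel <- winner == j
    if (!any(sel)) next
    tmp <- dPooled
    tmp[!sel] <- 0
    idx <- as.vector(outer(members[, j], offs, "+"))
    dZ[idx, ] <- dZ[idx, ] + tmp
  }
  dZ
}

# Flatten ((n*G) x F) pooled maps to (n x G*F); feature (g-1)*F + f.
.flattenPooled <- function(pooled, n) {
  matrix(t(pooled), nrow = n, byrow = TRUE)
}

.unflattenPooled <- function(flat, Fn, n) {
  matrix(t(flat), ncol = Fn, byrow = TRUE)
}

.softmax <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Full forward pass. Returns activations needed by the backward passes.
.forward <- function(model, X, keep = FALSE) {
  n <- nrow(X)
  acts <- list(branches = vector("list", length(model@branches)))
  flat <- NULL
  if (length(model@branches) == 0) {
    flat <- X
  } else {
    parts <- vector("list", length(model@branches))
    for (i in seq_along(model@branches)) {
      br <- model@branches[[i]]
      A <- .patchMatrix(X, br)
      Zpre <- A %*% br$W
      Zpre <- sweep(Zpre, 2, br$b, "+")
      Z <- pmax(Zpre, 0)
      pf <- .poolForward(Z, br, n)
      parts[[i]] <- .flattenPooled(pf$values, n)
      if (keep)
        acts$branches[[i]] <- list(A = A, Zpre = Zpre, winner = pf$winner)
    }
    flat <- do.call(cbind, parts)
  }
  hasDense <- length(model@denseB) > 0
  if (hasDense) {
    Hpre <- sweep(flat %*% model@denseW, 2, model@denseB, "+")
    H <- pmax(Hpre, 0)
  } else {
    Hpre <- NULL
    H <- flat
  }
  logits <- sweep(H %*% model@outW, 2, model@outB, "+")
  probs <- .softmax(logits)
  out <- list(probs = probs, logits = logits)
  if (keep) {
    out$flat <- flat; out$H <- H; out$Hpre <- Hpre; out$acts <- acts
  }
  out
}

# Backward pass for training: returns gradients for every weight array.
# dLogits is (n x C), typically (probs - Y)/n for cross-entropy.
.backward <- function(model, X, fw, dLogits) {
  n <- nrow(X)
  grads <- list()
  grads$outW <- crossprod(fw$H, dLogits)
  grads$outB <- colSums(dLogits)
  dH <- dLogits %*% t(model@outW)
  hasDense <- length(model@denseB) > 0
  if (hasDense) {
    dH[fw$Hpre <= 0] <- 0
    grads$denseW <- crossprod(fw$flat, dH)
    grads$denseB <- colSums(dH)
    dFlat <- dH %*% t(model@denseW)
  } else {
    dFlat <- dH
  }
  grads$branches <- vector("list", length(model@branches))
  col0 <- 0L
  for (i in seq_along(model@branches)) {
    br <- model@branches[[i]]
    width <- br$G * br$Fn
    dPart <- dFlat[, col0 + seq_len(width), drop = FALSE]
    col0 <- col0 + width
    a <- fw$acts$branches[[i]]
    dPooled <- .unflattenPooled(dPart, br$Fn, n)
    dZ <- .poolBackward(dPooled, a$winner, br, n)
    dZ[a$Zpre <= 0] <- 0
    grads$branches[[i]] <- list(W = crossprod(a$A, dZ), b = colSums(dZ))
  }
  grads
}

# Guided backpropagation to the input for one output class.
# At every rectifier, gradients are zeroed where the activation was inactive
# OR the incoming gradient is negative; the final input-level gradient is
# clipped at zero. `wrt` selects the differentiated quantity: the class's
# softmax probability (class-discriminative: competing classes contribute
# negatively through the softmax Jacobian) or its pre-softmax logit.
.guidedBackprop <- function(model, X, classIndex, wrt = "softmax") {
  n <- nrow(X)
  fw <- .forward(model, X, keep = TRUE)
  C <- length(model@classNames)
  if (wrt == "softmax") {
    # d p_c / d logit_k = p_c (1[k = c] - p_k)
    p <- fw$probs
    dLogits <- -p * p[, classIndex]
    dLogits[, classIndex] <- dLogits[, classIndex] + p[, classIndex]
  } else {
    dLogits <- matrix(0, n, C)
    dLogits[, classIndex] <- 1
  }
  dH <- dLogits %*% t(model@outW)
  hasDense <- length(model@denseB) > 0
  if (hasDense) {
    dH[fw$Hpre <= 0] <- 0
    dH[dH < 0] <- 0                       # guided rule at the dense ReLU
    dFlat <- dH %*% t(model@denseW)
  } else {
    dFlat <- dH
  }
  dX <- matrix(0, n, ncol(X))
  if (length(model@branches) == 0) {
    dX <- dFlat
  } else {
    col0 <- 0L
    for (i in seq_along(model@branches)) {
      br <- model@branches[[i]]
      width <- br$G * br$Fn
      dPart <- dFlat[, col0 + seq_len(width), drop = FALSE]
      col0 <- col0 + width
      a <- fw$acts$branches[[i]]
      dPooled <- .unflattenPooled(dPart, br$Fn, n)
      dZ <- .poolBackward(dPooled, a$winner, br, n)
      dZ[a$Zpre <= 0] <- 0
      dZ[dZ < 0] <- 0                     # guided rule at the conv ReLU
      dA <- dZ %*% t(br$W)                # (n*P) x K
      # scatter-add patch gradients back to flat input positions
      dFlatIn <- matrix(t(dA), nrow = n, byrow = TRUE)  # n x (P*K)
      rs <- rowsum(t(dFlatIn), group = br$idxVec)
      dX[, as.integer(rownames(rs))] <- dX[, as.integer(rownames(rs))] + t(rs)
    }
  }
  dX[dX < 0] <- 0                         # keep positive evidence only
  dX
}

# ---- Adam optimizer ----

.adamInit <- function(shapes) {
  lapply(shapes, function(s) list(m = array(0, dim = s), v = array(0, dim = s)))
}

.adamStep <- function(value, grad, state, t, lr, beta1, beta2, eps) {
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  list(value = value - lr * mhat / (sqrt(vhat) + eps), state = state)
}

# Flatten model weights to a named list for generic optimizer updates.
.getWeights <- function(model) {
  w <- list()
  for (i in seq_along(model@branches)) {
    w[[sprintf("convW%d", i)]] <- model@branches[[i]]$W
    w[[sprintf("convB%d", i)]] <- model@branches[[i]]$b
  }
  if (length(model@denseB) > 0) {
    w$denseW <- model@denseW
    w$denseB <- model@denseB
  }
  w$outW <- model@outW
  w$outB <- model@outB
  w
}

.setWeights <- function(model, w) {
  for (i in seq_along(model@branches)) {
    model@branches[[i]]$W <- w[[sprintf("convW%d", i)]]
    model@branches[[i]]$b <- as.numeric(w[[sprintf("convB%d", i)]])
  }
  if (length(model@denseB) > 0) {
    model@denseW <- w$denseW
    model@denseB <- as.numeric(w$denseB)
  }
  model@outW <- w$outW
  model@outB <- as.numeric(w$outB)
  model
}

.gradList <- function(model, grads) {
  g <- list()
  for (i in seq_along(model@branches)) {
    g[[sprintf("convW%d", i)]] <- grads$branches[[i]]$W
    g[[sprintf("convB%d", i)]] <- grads$branches[[i]]$b
  }
  if (length(model@denseB) > 0) {
    g$denseW <- grads$denseW
    g$denseB <- grads$denseB
  }
  g$outW <- grads$outW
  g$outB <- grads$outB
  g
}

.crossEntropy <- function(probs, Y) {
  eps <- 1e-12
  -mean(rowSums(Y * log(pmax(probs, eps))))
}

.accuracyFromProbs <- function(probs, yIdx) {
  mean(max.col(probs, ties.method = "first") == yIdx)
}
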