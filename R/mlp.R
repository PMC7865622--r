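#' @include utils.R
NULL

# Minimal two-hidden-layer feed-forward network for binary classification.
# Architecture is fixed by design: ReLU hidden layers, logistic output,
# cross-entropy loss, full-batch Adam, early stopping on a held-out split.
# Written in plain matrix algebra; sized for feature matrices of a few
# thousand rows by a few dozen columns.

#' @keywords internal
mlpInit <- function(p, hidden) {
  sizes <- c(p, hidden, 1L)
  lapply(seq_len(length(sizes) - 1L), function(i) {
    list(W = matrix(stats::rnorm(sizes[i] * sizes[i + 1L],
                                 sd = sqrt(2 / sizes[i])),
                    nrow = sizes[i]),
         b = rep(0, sizes[i + 1L]))
  })
}

#' @keywords internal
mlpForward <- function(layers, X) {
  acts <- list(X)
  nl <- length(layers)
  for (i in seq_len(nl)) {
    Z <- sweep(acts[[i]] %*% layers[[i]]$W, 2L, layers[[i]]$b, "+")
    acts[[i + 1L]] <- if (i < nl) pmax(Z, 0) else 1 / (1 + exp(-Z))
  }
  acts
}

#' @keywords internal
mlpLoss <- function(p, y) {
  eps <- 1e-12
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}

#' @keywords internal
mlpTrain <- function(X, y, hidden = c(32L, 16L), maxEpochs = 500L,
                     learningRate = 0.01, validationFraction = 0.1,
                     patience = 25L) {
  n <- nrow(X)
  nVal <- floor(validationFraction * n)
  useVal <- nVal >= 5L && (n - nVal) >= 10L
  if (useVal) {
    # stratified-ish split: sample within each class
    valIdx <- unlist(lapply(split(seq_len(n), y), function(ix)
      sample(ix, max(1L, round(validationFraction * length(ix))))))
    trIdx <- setdiff(seq_len(n), valIdx)
  } else {
    trIdx <- seq_len(n); valIdx <- integer(0)
  }
  Xtr <- X[trIdx, , drop = FALSE]; ytr <- y[trIdx]
  Xv <- X[valIdx, , drop = FALSE]; yv <- y[valIdx]

  layers <- mlpInit(ncol(X), hidden)
  mom <- lapply(layers, function(l) list(mW = l$W * 0, vW = l$W * 0,
                                         mb = l$b * 0, vb = l$b * 0))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  best <- list(loss = Inf, layers = layers, epoch = 0L)
  wait <- 0L
  nl <- length(layers)
  for (epoch in seq_len(maxEpochs)) {
    acts <- mlpForward(layers, Xtr)
    pHat <- acts[[nl + 1L]]
    delta <- (pHat - ytr) / length(ytr)   # dL/dZ for logistic + BCE
    for (i in rev(seq_len(nl))) {
      gW <- crossprod(acts[[i]], delta)
      gb <- colSums(delta)
      if (i > 1L) {
        delta <- delta %*% t(layers[[i]]$W)
        delta <- delta * (acts[[i]] > 0)
      }
      m <- mom[[i]]
      m$mW <- beta1 * m$mW + (1 - beta1) * gW
      m$vW <- beta2 * m$vW + (1 - beta2) * gW^2
      m$mb <- beta1 * m$mb + (1 - beta1) * gb
      m$vb <- beta2 * m$vb + (1 - beta2) * gb^2
      mom[[i]] <- m
      c1 <- 1 - beta1^epoch; c2 <- 1 - beta2^epoch
      layers[[i]]$W <- layers[[i]]$W -
        learningRate * (m$mW / c1) / (sqrt(m$vW / c2) + eps)
      layers[[i]]$b <- layers[[i]]$b -
        learningRate * (m$mb / c1) / (sqrt(m$vb / c2) + eps)
    }
    monitor <- if (useVal)
      mlpLoss(mlpForward(layers, Xv)[[nl + 1L]], yv)
    else mlpLoss(mlpForward(layers, Xtr)[[nl + 1L]], ytr)
    if (monitor < best$loss - 1e-6) {
      best <- list(loss = monitor, layers = layers, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (useVal && wait >= patience) break
    }
  }
  structure(list(layers = best$layers, hidden = hidden,
                 epochs = best$epoch), class = "curlfatigueMLP")
}

#' @keywords internal
mlpPredictProb <- function(model, X) {
  nl <- length(model$layers)
  as.vector(mlpForward(model$layers, X)[[nl + 1L]])
}
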