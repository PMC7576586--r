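## Long short-term memory sequence classifier over windowed multichannel
## signals: stacked (optionally bidirectional) LSTM layers, final-state
## softmax head, minibatch Adam, fixed epoch budget, fully seeded.
## Implemented in plain matrix algebra; the input-to-hidden projections of
## all timesteps are batched into single BLAS calls so only the recurrence
## itself loops over time.  Gradients are verified against numerical
## differentiation in the test suite.

.sigm <- function(x) 1 / (1 + exp(-x))

## one directional LSTM layer pass over a batch
## X: array (B, C, T); W: (C+H) x 4H with gate column blocks i, f, o, g
.lstmLayerForward <- function(X, W, b, reverse = FALSE) {
  B <- dim(X)[1]; C <- dim(X)[2]; T <- dim(X)[3]
  H <- ncol(W) / 4L
  ## row (t-1)*B + b holds sample b at time t
  Xmat <- matrix(aperm(X, c(1, 3, 2)), B * T, C)
  Zx <- sweep(Xmat %*% W[seq_len(C), , drop = FALSE], 2, b, "+")
  Wh <- W[C + seq_len(H), , drop = FALSE]
  ts <- if (reverse) rev(seq_len(T)) else seq_len(T)
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  Hs <- array(0, c(B, H, T)); Cs <- array(0, c(B, H, T))
  Gi <- array(0, c(B, H, T)); Gf <- array(0, c(B, H, T))
  Go <- array(0, c(B, H, T)); Gg <- array(0, c(B, H, T))
  iH <- seq_len(H)
  for (t in ts) {
    rows <- (t - 1L) * B + seq_len(B)
    z <- Zx[rows, , drop = FALSE] + h %*% Wh
    i <- .sigm(z[, iH, drop = FALSE])
    f <- .sigm(z[, H + iH, drop = FALSE])
    o <- .sigm(z[, 2L * H + iH, drop = FALSE])
    g <- tanh(z[, 3L * H + iH, drop = FALSE])
    cc <- f * cc + i * g
    h <- o * tanh(cc)
    Hs[, , t] <- h; Cs[, , t] <- cc
    Gi[, , t] <- i; Gf[, , t] <- f; Go[, , t] <- o; Gg[, , t] <- g
  }
  list(Hs = Hs, Cs = Cs, Gi = Gi, Gf = Gf, Go = Go, Gg = Gg,
       hFinal = h, Xmat = Xmat, dims = c(B = B, C = C, T = T),
       reverse = reverse)
}

## backward pass; dHs: gradient wrt the per-time outputs (original time
## order), dhFinal: extra gradient into the last processed hidden state
.lstmLayerBackward <- function(fwd, W, dHs, dhFinal) {
  B <- fwd$dims[["B"]]; C <- fwd$dims[["C"]]; T <- fwd$dims[["T"]]
  H <- ncol(W) / 4L
  Wh <- W[C + seq_len(H), , drop = FALSE]
  procOrder <- if (fwd$reverse) rev(seq_len(T)) else seq_len(T)
  lastT <- procOrder[T]
  dZall <- matrix(0, B * T, 4L * H)
  dWh <- matrix(0, H, 4L * H)
  dhCarry <- matrix(0, B, H); dcCarry <- matrix(0, B, H)
  for (k in rev(seq_len(T))) {
    t <- procOrder[k]
    dh <- matrix(dHs[, , t], B, H) + dhCarry
    if (t == lastT) dh <- dh + dhFinal
    i <- matrix(fwd$Gi[, , t], B, H); f <- matrix(fwd$Gf[, , t], B, H)
    o <- matrix(fwd$Go[, , t], B, H); g <- matrix(fwd$Gg[, , t], B, H)
    tc <- tanh(matrix(fwd$Cs[, , t], B, H))
    if (k > 1L) {
      pt <- procOrder[k - 1L]
      cprev <- matrix(fwd$Cs[, , pt], B, H)
      hprev <- matrix(fwd$Hs[, , pt], B, H)
    } else {
      cprev <- matrix(0, B, H); hprev <- matrix(0, B, H)
    }
    dc <- dcCarry + dh * o * (1 - tc^2)
    dz <- cbind(dc * g * i * (1 - i),
                dc * cprev * f * (1 - f),
                dh * tc * o * (1 - o),
                dc * i * (1 - g^2))
    dZall[(t - 1L) * B + seq_len(B), ] <- dz
    dWh <- dWh + crossprod(hprev, dz)
    dhCarry <- tcrossprod(dz, Wh)
    dcCarry <- dc * f
  }
  dWx <- crossprod(fwd$Xmat, dZall)
  dXmat <- tcrossprod(dZall, W[seq_len(C), , drop = FALSE])
  dX <- aperm(array(dXmat, c(B, T, C)), c(1, 3, 2))
  list(dX = dX, dW = rbind(dWx, dWh), db = colSums(dZall))
}

## stack forward: returns per-layer forwards, final feature matrix
.lstmForward <- function(X, par) {
  inp <- X
  layers <- vector("list", length(par$layers))
  for (l in seq_along(par$layers)) {
    lp <- par$layers[[l]]
    fw <- .lstmLayerForward(inp, lp$fwd$W, lp$fwd$b, reverse = FALSE)
    if (par$bidirectional) {
      bw <- .lstmLayerForward(inp, lp$rev$W, lp$rev$b, reverse = TRUE)
      B <- dim(fw$Hs)[1]; H <- dim(fw$Hs)[2]; T <- dim(fw$Hs)[3]
      seqOut <- array(0, c(B, 2L * H, T))
      seqOut[, seq_len(H), ] <- fw$Hs
      seqOut[, H + seq_len(H), ] <- bw$Hs
      feat <- cbind(fw$hFinal, bw$hFinal)
      layers[[l]] <- list(fwd = fw, rev = bw)
    } else {
      seqOut <- fw$Hs
      feat <- fw$hFinal
      layers[[l]] <- list(fwd = fw)
    }
    inp <- seqOut
  }
  scores <- sweep(feat %*% par$head$W, 2, par$head$b, "+")
  P <- .softmax(scores)
  list(layers = layers, feat = feat, P = P)
}

## full backward; Y logical index matrix of true classes
.lstmGrad <- function(X, Y, par) {
  fwd <- .lstmForward(X, par)
  B <- nrow(Y)
  dS <- (fwd$P - Y) / B
  grad <- list(layers = vector("list", length(par$layers)),
               head = list(W = crossprod(fwd$feat, dS), b = colSums(dS)))
  dFeat <- tcrossprod(dS, par$head$W)
  nL <- length(par$layers)
  H <- par$width
  dSeqNext <- NULL  # gradient wrt the output sequence of the layer below
  for (l in rev(seq_len(nL))) {
    lf <- fwd$layers[[l]]
    dims <- dim(lf$fwd$Hs)
    dHsF <- array(0, dims)
    if (!is.null(dSeqNext))
      dHsF <- dHsF + dSeqNext[, seq_len(H), , drop = FALSE]
    dhFinF <- matrix(0, dims[1], H)
    if (l == nL) dhFinF <- dFeat[, seq_len(H), drop = FALSE]
    bkF <- .lstmLayerBackward(lf$fwd, par$layers[[l]]$fwd$W, dHsF, dhFinF)
    gl <- list(fwd = list(W = bkF$dW, b = bkF$db))
    dInp <- bkF$dX
    if (par$bidirectional) {
      dHsB <- array(0, dims)
      if (!is.null(dSeqNext))
        dHsB <- dHsB + dSeqNext[, H + seq_len(H), , drop = FALSE]
      dhFinB <- matrix(0, dims[1], H)
      if (l == nL) dhFinB <- dFeat[, H + seq_len(H), drop = FALSE]
      bkB <- .lstmLayerBackward(lf$rev, par$layers[[l]]$rev$W, dHsB, dhFinB)
      gl$rev <- list(W = bkB$dW, b = bkB$db)
      dInp <- dInp + bkB$dX
    }
    grad$layers[[l]] <- gl
    dSeqNext <- dInp
  }
  grad$loss <- .ceLoss(fwd$P, Y)
  grad
}

.lstmInitPar <- function(C, width, nLayers, bidirectional, K) {
  mk <- function(cin, H) {
    list(W = matrix(stats::rnorm((cin + H) * 4L * H, 0,
                                 1 / sqrt(cin + H)), cin + H, 4L * H),
         ## forget-gate bias starts at 1, the usual stabilizing init
         b = c(numeric(H), rep(1, H), numeric(2L * H)))
  }
  layers <- vector("list", nLayers)
  cin <- C
  for (l in seq_len(nLayers)) {
    lp <- list(fwd = mk(cin, width))
    if (bidirectional) lp$rev <- mk(cin, width)
    layers[[l]] <- lp
    cin <- if (bidirectional) 2L * width else width
  }
  featDim <- if (bidirectional) 2L * width else width
  list(layers = layers,
       head = list(W = matrix(stats::rnorm(featDim * K, 0,
                                           1 / sqrt(featDim)), featDim, K),
                   b = numeric(K)),
       width = width, bidirectional = bidirectional)
}

## apply fun(value, companion) across the nested parameter structure
.parWalk <- function(par, other, fun) {
  for (l in seq_along(par$layers)) {
    for (dir in names(par$layers[[l]])) {
      for (nm in c("W", "b")) {
        par$layers[[l]][[dir]][[nm]] <-
          fun(par$layers[[l]][[dir]][[nm]], other$layers[[l]][[dir]][[nm]])
      }
    }
  }
  for (nm in c("W", "b"))
    par$head[[nm]] <- fun(par$head[[nm]], other$head[[nm]])
  par
}

.parWalk2 <- function(par, a, b, fun) {
  for (l in seq_along(par$layers)) {
    for (dir in names(par$layers[[l]])) {
      for (nm in c("W", "b")) {
        par$layers[[l]][[dir]][[nm]] <-
          fun(par$layers[[l]][[dir]][[nm]],
              a$layers[[l]][[dir]][[nm]], b$layers[[l]][[dir]][[nm]])
      }
    }
  }
  for (nm in c("W", "b"))
    par$head[[nm]] <- fun(par$head[[nm]], a$head[[nm]], b$head[[nm]])
  par
}

## assemble a batch array (B, C, T) from a list of T x C window matrices
.stackWindows <- function(windows, idx) {
  T <- nrow(windows[[idx[1L]]]$x); C <- ncol(windows[[idx[1L]]]$x)
  X <- array(0, c(length(idx), C, T))
  for (b in seq_along(idx)) X[b, , ] <- t(windows[[idx[b]]]$x)
  X
}

## model-side input preprocessing: optional temporal subsampling (keep
## every timeStride-th sample) and centering of the unit-interval inputs
## around zero; uncentered all-positive inputs give sigmoid/tanh units
## strongly correlated gradients and a long training plateau
.lstmPreprocess <- function(windows, timeStride) {
  lapply(windows, function(w) {
    x <- w$x
    if (timeStride > 1L)
      x <- x[seq(1L, nrow(x), by = timeStride), , drop = FALSE]
    w$x <- x - 0.5
    w
  })
}

.lstmFit <- function(windows, y, width = 64L, nLayers = 2L,
                     bidirectional = FALSE, epochs = 30L, lr = 0.01,
                     batchSize = 16L, timeStride = 1L, seed = 1L) {
  windows <- .lstmPreprocess(windows, timeStride)
  shapes <- vapply(windows, function(w) dim(w$x), integer(2))
  if (length(unique(shapes[1, ])) != 1L ||
      length(unique(shapes[2, ])) != 1L)
    stop("all windows must have identical dimensions")
  classes <- levels(y)
  K <- length(classes)
  C <- shapes[2, 1]
  n <- length(windows)
  withr::local_seed(as.integer(seed %% 2147483647))
  par <- .lstmInitPar(C, width, nLayers, bidirectional, K)
  mState <- .parWalk(par, par, function(p, q) p * 0)
  vState <- mState
  tStep <- 0L
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = batchSize)) {
      idx <- ord[start:min(start + batchSize - 1L, n)]
      X <- .stackWindows(windows, idx)
      Y <- matrix(FALSE, length(idx), K)
      Y[cbind(seq_along(idx), as.integer(y[idx]))] <- TRUE
      grad <- .lstmGrad(X, Y, par)
      tStep <- tStep + 1L
      mState <- .parWalk(mState, grad,
                         function(m, g) beta1 * m + (1 - beta1) * g)
      vState <- .parWalk(vState, grad,
                         function(v, g) beta2 * v + (1 - beta2) * g^2)
      corr1 <- 1 - beta1^tStep; corr2 <- 1 - beta2^tStep
      par <- .parWalk2(par, mState, vState, function(p, m, v)
        p - lr * (m / corr1) / (sqrt(v / corr2) + eps))
    }
  }
  list(par = par, classes = classes, width = width, nLayers = nLayers,
       bidirectional = bidirectional, epochs = epochs,
       timeStride = timeStride)
}

.lstmPredict <- function(fit, windows, batchSize = 64L) {
  windows <- .lstmPreprocess(windows, fit$timeStride)
  n <- length(windows)
  out <- character(n)
  for (start in seq(1L, n, by = batchSize)) {
    idx <- start:min(start + batchSize - 1L, n)
    X <- .stackWindows(windows, idx)
    P <- .lstmForward(X, fit$par)$P
    out[idx] <- fit$classes[max.col(P, ties.method = "first")]
  }
  out
}

## number of parameters in the recurrent layers (excludes the head)
.lstmRecurrentParamCount <- function(par) {
  tot <- 0L
  for (l in par$layers)
    for (dir in names(l))
      tot <- tot + length(l[[dir]]$W) + length(l[[dir]]$b)
  tot
}
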