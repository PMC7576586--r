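## One-hidden-layer fully connected softmax classifier, trained by
## full-batch Adam gradient descent with early stopping on a held-out
## slice of the training data.  Written in plain matrix algebra so the
## training contract (seeded determinism, early stopping, fixed epoch
## budget) is fully under the package's control.

.softmax <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

.fcForward <- function(par, X) {
  A1 <- tanh(sweep(X %*% par$W1, 2, par$b1, "+"))
  P <- .softmax(sweep(A1 %*% par$W2, 2, par$b2, "+"))
  list(A1 = A1, P = P)
}

.ceLoss <- function(P, Y) -mean(log(pmax(P[Y], 1e-12)))

## analytic gradients of the cross-entropy loss; Y is a logical index
## matrix of the true classes
.fcGrad <- function(par, X, Y) {
  n <- nrow(X)
  fwd <- .fcForward(par, X)
  D2 <- (fwd$P - Y) / n
  dW2 <- t(fwd$A1) %*% D2
  db2 <- colSums(D2)
  D1 <- (D2 %*% t(par$W2)) * (1 - fwd$A1^2)
  dW1 <- t(X) %*% D1
  db1 <- colSums(D1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
       loss = .ceLoss(fwd$P, Y))
}

.adamStep <- function(par, grad, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(par)) {
    g <- grad[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = state)
}

## X standardized numeric matrix, y factor
.fcFit <- function(X, y, hidden = 40L, maxEpochs = 200L, lr = 0.05,
                   holdout = 0.1, patience = 20L, seed = 1L) {
  classes <- levels(y)
  K <- length(classes)
  p <- ncol(X)
  n <- nrow(X)
  withr::local_seed(as.integer(seed %% 2147483647))

  nVal <- max(1L, round(holdout * n))
  val <- sample.int(n, nVal)
  tr <- setdiff(seq_len(n), val)
  ## degenerate split guard: keep every class in the training slice
  if (length(unique(y[tr])) < K) { tr <- seq_len(n); val <- seq_len(n) }

  Ytr <- matrix(FALSE, length(tr), K)
  Ytr[cbind(seq_along(tr), as.integer(y[tr]))] <- TRUE
  Yval <- matrix(FALSE, length(val), K)
  Yval[cbind(seq_along(val), as.integer(y[val]))] <- TRUE

  par <- list(
    W1 = matrix(stats::rnorm(p * hidden, 0, 1 / sqrt(p)), p, hidden),
    b1 = numeric(hidden),
    W2 = matrix(stats::rnorm(hidden * K, 0, 1 / sqrt(hidden)), hidden, K),
    b2 = numeric(K)
  )
  state <- list(m = lapply(par, function(z) z * 0),
                v = lapply(par, function(z) z * 0))
  best <- list(par = par, loss = Inf, epoch = 0L)
  since <- 0L
  for (ep in seq_len(maxEpochs)) {
    g <- .fcGrad(par, X[tr, , drop = FALSE], Ytr)
    st <- .adamStep(par, g[c("W1", "b1", "W2", "b2")], state, lr, ep)
    par <- st$par; state <- st$state
    vl <- .ceLoss(.fcForward(par, X[val, , drop = FALSE])$P, Yval)
    if (vl < best$loss - 1e-6) {
      best <- list(par = par, loss = vl, epoch = ep)
      since <- 0L
    } else {
      since <- since + 1L
      if (since >= patience) break
    }
  }
  list(par = best$par, classes = classes, hidden = hidden,
       epochs = best$epoch, valLoss = best$loss)
}

.fcPredict <- function(fit, X) {
  P <- .fcForward(fit$par, X)$P
  fit$classes[max.col(P, ties.method = "first")]
}
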