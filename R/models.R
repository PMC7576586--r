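## The classifier suite: six feature-table model kinds (LDA, QDA, decision
## tree, random forest, SVM, one-hidden-layer FC network) plus the LSTM
## sequence model, behind a uniform train/predict surface.

.featureKinds <- c("lda", "qda", "tree", "forest", "svm", "fc")

## z-score standardization helpers; statistics frozen at fit time
.standardizeFit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  list(center = ctr, scale = scl)
}

.standardizeApply <- function(X, st) {
  sweep(sweep(X, 2, st$center, "-"), 2, st$scale, "/")
}

## drop exactly collinear columns (e.g. the five support percentages sum
## to 100) via rank-revealing QR with pivoting
.dropLinearCombos <- function(X) {
  if (ncol(X) < 2L) return(seq_len(ncol(X)))
  q <- qr(X)
  sort(q$pivot[seq_len(q$rank)])
}

## columns usable by QDA: every class covariance must be full rank at the
## tolerance QDA itself applies (within-group centering and sd scaling,
## QR at tol 1e-4); iterates because dropping a column can expose another
## deficient group
.qdaSafeColumns <- function(X, y, tol = 1e-4) {
  keep <- seq_len(ncol(X))
  repeat {
    changed <- FALSE
    for (cl in levels(y)) {
      Xi <- X[y == cl, keep, drop = FALSE]
      if (nrow(Xi) < 2L) next
      Xi <- scale(Xi)
      sds <- attr(Xi, "scaled:scale")
      flat <- which(sds < 1e-10)
      if (length(flat)) {
        keep <- keep[-flat]
        changed <- TRUE
        break
      }
      q <- qr(Xi, tol = tol)
      if (q$rank < ncol(Xi)) {
        keep <- keep[sort(q$pivot[seq_len(q$rank)])]
        changed <- TRUE
        break
      }
    }
    if (!changed || length(keep) < 2L) break
  }
  keep
}

#' Train a feature-table gait classifier
#'
#' Fits one of the six feature-model kinds on the selected feature columns
#' of a stride feature table.  Discriminant, margin and network models
#' (\code{lda}, \code{qda}, \code{svm}, \code{fc}) see per-column z-scored
#' features (statistics frozen at fit time) with exactly collinear columns
#' removed; tree and forest consume raw features.  \code{qda} additionally
#' drops columns that are constant within any training class, which would
#' make a class covariance singular.  The FC network has one hidden layer
#' (default 40 tanh units), a softmax output, and is trained by full-batch
#' Adam with early stopping on a 10 % held-out slice of the training data
#' (at most 200 epochs).  All kinds are deterministic given \code{seed}.
#'
#' @param kind model kind: \code{"lda"}, \code{"qda"}, \code{"tree"},
#'   \code{"forest"}, \code{"svm"} or \code{"fc"}.
#' @param table stride feature table (see \code{\link{featureTable}}) with
#'   a \code{gait} column.
#' @param subset feature subset name or explicit character vector of
#'   feature columns (see \code{\link{featureSubset}}).
#' @param seed integer RNG seed.
#' @param hidden hidden-layer width of the FC network.
#' @param numTrees number of trees of the random forest.
#' @return A \code{\linkS4class{GaitModel}}.
#' @examples
#' coh <- simulateCohort(cohortConfig(c(warmblood = 2L), stridesPerTrial = 8L),
#'                       seed = 1)
#' ft <- featureTable(coh$timelines)
#' m <- trainFeatureModel("lda", ft, "all", seed = 1)
#' mean(predictGait(m, ft) == ft$gait)
#' @export
trainFeatureModel <- function(kind, table, subset = "all", seed = 1L,
                              hidden = 40L, numTrees = 100L) {
  kind <- match.arg(kind, .featureKinds)
  if (!nrow(table)) stop("training table is empty")
  cols <- if (length(subset) == 1L && subset %in%
                c("all", "stride_only", "hildebrand2"))
    featureSubset(subset) else subset
  missing <- setdiff(cols, names(table))
  if (length(missing))
    stop("missing feature column(s): ", paste(missing, collapse = ", "))
  y <- factor(as.character(table$gait))
  if (nlevels(y) < 2L) stop("training data holds a single class")
  X <- as.matrix(table[, cols, drop = FALSE])

  scaling <- list(columns = cols)
  if (kind %in% c("lda", "qda", "svm", "fc")) {
    st <- .standardizeFit(X)
    Xs <- .standardizeApply(X, st)
    keep <- .dropLinearCombos(Xs)
    if (kind == "qda")
      keep <- keep[.qdaSafeColumns(Xs[, keep, drop = FALSE], y)]
    Xs <- Xs[, keep, drop = FALSE]
    scaling <- c(scaling, list(center = st$center, scale = st$scale,
                               keep = keep))
  }

  withr::local_seed(as.integer(seed %% 2147483647))
  fit <- switch(kind,
    lda = MASS::lda(Xs, grouping = y),
    qda = MASS::qda(Xs, grouping = y),
    tree = {
      d <- data.frame(gait = y, X)
      rpart::rpart(gait ~ ., data = d, method = "class")
    },
    forest = {
      d <- data.frame(gait = y, X)
      ranger::ranger(gait ~ ., data = d, num.trees = numTrees,
                     seed = as.integer(seed %% 2147483647))
    },
    svm = e1071::svm(Xs, y, kernel = "radial", scale = FALSE),
    fc = .fcFit(Xs, y, hidden = hidden, seed = seed)
  )
  new("GaitModel", kind = kind,
      spec = list(subset = subset, seed = seed, hidden = hidden,
                  numTrees = numTrees),
      fit = fit, classes = levels(y), inputs = cols, scaling = scaling)
}

#' Train the LSTM sequence classifier on labeled signal windows
#'
#' Stacked LSTM layers read the windowed multichannel signal and the final
#' hidden state feeds a softmax classification layer.  The reference
#' architecture uses two recurrent layers; the width defaults to 64 units
#' for desk-scale CPU training (larger widths, e.g. 500, are supported via
#' \code{width}).  With \code{bidirectional = TRUE} a second parameter set
#' reads the window back-to-front and both final states are concatenated,
#' roughly doubling the recurrent parameter count.  Training runs a fixed
#' epoch budget of minibatch Adam and is deterministic given \code{seed}.
#'
#' @param windows list of labeled windows from \code{\link{windowSignals}}
#'   (uniform dimensions).
#' @param width LSTM layer width.
#' @param nLayers number of stacked LSTM layers.
#' @param bidirectional logical.
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param batchSize minibatch size.
#' @param timeStride keep every \code{timeStride}-th sample of each window
#'   before the recurrence (1 = use the full 200 Hz resolution).  A stride
#'   of 4-8 shortens the recurrence correspondingly and is the recommended
#'   desk-scale setting; gait fundamentals live below 10 Hz, far under the
#'   resulting Nyquist limit.  Inputs are internally centered around zero.
#' @param seed integer RNG seed.
#' @return A \code{\linkS4class{GaitModel}} of kind \code{"sequence"}.
#' @export
trainSequenceModel <- function(windows, width = 64L, nLayers = 2L,
                               bidirectional = FALSE, epochs = 30L,
                               lr = 0.01, batchSize = 16L, timeStride = 1L,
                               seed = 1L) {
  if (!length(windows)) stop("no training windows")
  y <- factor(vapply(windows, function(w) w$gait, character(1)))
  if (nlevels(y) < 2L) stop("training data holds a single class")
  fit <- .lstmFit(windows, y, width = width, nLayers = nLayers,
                  bidirectional = bidirectional, epochs = epochs,
                  lr = lr, batchSize = batchSize, timeStride = timeStride,
                  seed = seed)
  new("GaitModel", kind = "sequence",
      spec = list(width = width, nLayers = nLayers,
                  bidirectional = bidirectional, epochs = epochs,
                  lr = lr, batchSize = batchSize, timeStride = timeStride,
                  seed = seed),
      fit = fit, classes = levels(y),
      inputs = colnames(windows[[1L]]$x), scaling = list())
}

#' Number of parameters in the recurrent layers of a sequence model
#'
#' @param model a \code{\linkS4class{GaitModel}} of kind
#'   \code{"sequence"}.
#' @return Integer parameter count (excludes the classification head).
#' @export
recurrentParamCount <- function(model) {
  stopifnot(is(model, "GaitModel"), model@kind == "sequence")
  .lstmRecurrentParamCount(model@fit$par)
}

#' Predict gait labels
#'
#' Dispatches on the model kind; feature models take a feature table (or
#' any data.frame holding the training columns), sequence models a list of
#' windows shaped like the training windows.  Predictions are drawn only
#' from the classes seen in training and are stable under repeated calls.
#'
#' @param model a \code{\linkS4class{GaitModel}}.
#' @param newdata feature table or window list.
#' @return Character vector of gait labels, one per row / window.
#' @export
predictGait <- function(model, newdata) {
  stopifnot(is(model, "GaitModel"))
  if (model@kind == "sequence") {
    if (!length(newdata)) return(character(0))
    return(.lstmPredict(model@fit, newdata))
  }
  if (!nrow(newdata)) return(character(0))
  missing <- setdiff(model@inputs, names(newdata))
  if (length(missing))
    stop("newdata lacks feature column(s): ",
         paste(missing, collapse = ", "))
  X <- as.matrix(newdata[, model@inputs, drop = FALSE])
  sc <- model@scaling
  if (model@kind %in% c("lda", "qda", "svm", "fc")) {
    Xs <- .standardizeApply(X, sc)
    Xs <- Xs[, sc$keep, drop = FALSE]
  }
  as.character(switch(model@kind,
    lda = stats::predict(model@fit, Xs)$class,
    qda = stats::predict(model@fit, Xs)$class,
    tree = {
      cls <- stats::predict(model@fit, data.frame(X), type = "class")
      as.character(cls)
    },
    forest = stats::predict(model@fit, data.frame(X))$predictions,
    svm = stats::predict(model@fit, Xs),
    fc = .fcPredict(model@fit, Xs)
  ))
}
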