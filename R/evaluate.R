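## Horse-disjoint splitting, 5-fold cross-validation, confusion matrices
## and the experiment grids over model kinds, feature subsets and sensor
## subsets.

#' Grouped k-fold split plan over horses
#'
#' Partitions horses into k validation folds so that no horse's strides
#' ever cross a train/validation boundary.  Fold balancing targets stride
#' counts, not horse counts, because breeds contribute very different
#' stride totals: horses are assiged greedily (largest count first, ties
#' in seeded random order) to the currently lightest fold.  Optionally a
#' held-out test set of roughly \code{testFraction} of the strides is
#' carved off first and never enters any fold.
#'
#' @param strideCounts named numeric vector: strides per horse id (e.g.
#'   \code{table(features$horse_id)}).
#' @param k number of folds (default 5).
#' @param seed integer RNG seed.
#' @param testFraction fraction of strides held out entirely (default 0).
#' @return A \code{"splitPlan"}: list with \code{folds} (list of k
#'   character vectors of validation horse ids), \code{test} (character
#'   vector), \code{horses} (all ids covered by the folds).
#' @examples
#' counts <- c(a = 30, b = 28, c = 25, d = 31, e = 27,
#'             f = 29, g = 30, h = 26, i = 24, j = 32)
#' plan <- groupedKFold(counts, k = 5, seed = 1)
#' lengths(plan$folds)
#' @export
groupedKFold <- function(strideCounts, k = 5L, seed = 1L,
                         testFraction = 0) {
  ids <- names(strideCounts)
  if (is.null(ids) || anyDuplicated(ids))
    stop("'strideCounts' must be named by unique horse ids")
  withr::local_seed(as.integer(seed %% 2147483647))

  test <- character(0)
  if (testFraction > 0) {
    target <- testFraction * sum(strideCounts)
    ord <- sample(ids)
    cum <- cumsum(strideCounts[ord])
    nTest <- max(1L, which(cum >= target)[1L])
    test <- ord[seq_len(nTest)]
    strideCounts <- strideCounts[setdiff(ids, test)]
    ids <- names(strideCounts)
  }
  if (length(ids) < k)
    stop(sprintf("need at least %d horses for %d folds, have %d",
                 k, k, length(ids)))
  ## greedy longest-processing-time assignment balances stride counts
  ord <- ids[order(-strideCounts, sample.int(length(ids)))]
  folds <- vector("list", k)
  load <- numeric(k)
  for (id in ord) {
    j <- which.min(load)
    folds[[j]] <- c(folds[[j]], id)
    load[j] <- load[j] + strideCounts[[id]]
  }
  structure(list(folds = folds, test = test, horses = ids),
            class = "splitPlan")
}

#' Tabulate a confusion matrix
#'
#' @param truth,predicted equal-length label vectors.
#' @param classes ordered class list; defaults to the union of observed
#'   labels.  A label outside \code{classes} is an error.
#' @return Integer matrix \code{[n_class x n_class]}, rows = truth.
#' @export
confusionTable <- function(truth, predicted, classes = NULL) {
  if (length(truth) != length(predicted))
    stop("'truth' and 'predicted' must have equal length")
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  bad <- setdiff(unique(c(truth, predicted)), classes)
  if (length(bad))
    stop("label(s) outside the class list: ", paste(bad, collapse = ", "))
  tt <- table(factor(truth, classes), factor(predicted, classes))
  m <- matrix(as.integer(tt), nrow(tt), ncol(tt),
              dimnames = list(truth = classes, predicted = classes))
  m
}

#' Micro-averaged accuracy of a confusion matrix
#'
#' @param cm square confusion matrix (rows = truth).
#' @return \code{trace / total}, a fraction in [0, 1].
#' @export
accuracy <- function(cm) {
  if (!sum(cm)) return(NA_real_)
  sum(diag(cm)) / sum(cm)
}

.assertDisjoint <- function(trainIds, valIds) {
  leak <- intersect(unique(trainIds), unique(valIds))
  if (length(leak))
    stop("protocol violation: horse(s) on both sides of a fold: ",
         paste(leak, collapse = ", "))
  invisible(TRUE)
}

.mkCVResult <- function(accs, ns, cm) {
  new("GaitCVResult",
      foldAccuracy = accs,
      meanAccuracy = mean(accs),
      sdAccuracy = if (length(accs) > 1L) stats::sd(accs) else 0,
      confusion = cm,
      detail = data.frame(fold = seq_along(accs), n = ns, accuracy = accs))
}

#' Horse-disjoint cross-validation of a feature model
#'
#' For each fold: training strides (all horses outside the fold and the
#' test set) are balanced by duplication, the model is fitted, and the
#' fold's validation strides are predicted.  Horse-disjointness of every
#' fold is asserted before fitting.  A class absent from a fold's training
#' strides is logged and simply never predicted by that fold's model.
#'
#' @param kind feature model kind (see \code{\link{trainFeatureModel}}).
#' @param features stride feature table.
#' @param plan a \code{\link{groupedKFold}} split plan.
#' @param subset feature subset name or column vector.
#' @param seed integer RNG seed (fold-level child seeds are derived).
#' @param excludeGaits gait labels dropped from the data before the run
#'   (e.g. \code{"trocha"}).
#' @param ... passed to \code{\link{trainFeatureModel}}.
#' @return A \code{\linkS4class{GaitCVResult}}.
#' @export
crossValidate <- function(kind, features, plan, subset = "all", seed = 1L,
                          excludeGaits = NULL, ...) {
  stopifnot(inherits(plan, "splitPlan"))
  if (length(excludeGaits))
    features <- features[!features$gait %in% excludeGaits, , drop = FALSE]
  classes <- sort(unique(as.character(features$gait)))
  cm <- matrix(0L, length(classes), length(classes),
               dimnames = list(truth = classes, predicted = classes))
  accs <- numeric(0); ns <- integer(0)
  for (f in seq_along(plan$folds)) {
    valIds <- plan$folds[[f]]
    trainIds <- setdiff(plan$horses, valIds)
    .assertDisjoint(trainIds, valIds)
    tr <- features[features$horse_id %in% trainIds, , drop = FALSE]
    va <- features[features$horse_id %in% valIds, , drop = FALSE]
    if (!nrow(va)) next
    missingCls <- setdiff(classes, unique(tr$gait))
    if (length(missingCls))
      message(sprintf("fold %d: class(es) %s absent from training", f,
                      paste(missingCls, collapse = ", ")))
    tr <- balanceByDuplication(tr, seed = childSeed(seed,
                                                    paste0("balance/", f)))
    model <- trainFeatureModel(kind, tr, subset,
                               seed = childSeed(seed, paste0("fit/", f)),
                               ...)
    pred <- predictGait(model, va)
    cmF <- confusionTable(va$gait, pred, classes)
    cm <- cm + cmF
    accs <- c(accs, accuracy(cmF)); ns <- c(ns, nrow(va))
  }
  if (!length(accs)) stop("no fold produced validation predictions")
  .mkCVResult(accs, ns, cm)
}

#' Horse-disjoint cross-validation of the sequence model
#'
#' Window-list analogue of \code{\link{crossValidate}}: per fold the
#' training windows are balanced by duplication and an LSTM is trained;
#' validation windows are predicted and pooled into the confusion matrix.
#'
#' @param windows list of labeled windows (with \code{horse_id} fields).
#' @param plan a \code{\link{groupedKFold}} split plan.
#' @param seed integer RNG seed.
#' @param excludeGaits gait labels dropped before the run.
#' @param ... passed to \code{\link{trainSequenceModel}} (width, epochs,
#'   bidirectional, ...).
#' @return A \code{\linkS4class{GaitCVResult}}.
#' @export
crossValidateSignals <- function(windows, plan, seed = 1L,
                                 excludeGaits = NULL, ...) {
  stopifnot(inherits(plan, "splitPlan"))
  wGait <- vapply(windows, function(w) w$gait, character(1))
  if (length(excludeGaits)) {
    windows <- windows[!wGait %in% excludeGaits]
    wGait <- wGait[!wGait %in% excludeGaits]
  }
  wHorse <- vapply(windows, function(w) w$horse_id, character(1))
  classes <- sort(unique(wGait))
  cm <- matrix(0L, length(classes), length(classes),
               dimnames = list(truth = classes, predicted = classes))
  accs <- numeric(0); ns <- integer(0)
  for (f in seq_along(plan$folds)) {
    valIds <- plan$folds[[f]]
    trainIds <- setdiff(plan$horses, valIds)
    .assertDisjoint(trainIds, valIds)
    trW <- windows[wHorse %in% trainIds]
    vaW <- windows[wHorse %in% valIds]
    if (!length(vaW)) next
    trW <- balanceWindowsByDuplication(
      trW, seed = childSeed(seed, paste0("balance/", f)))
    model <- trainSequenceModel(trW,
                                seed = childSeed(seed, paste0("fit/", f)),
                                ...)
    pred <- predictGait(model, vaW)
    cmF <- confusionTable(vapply(vaW, function(w) w$gait, character(1)),
                          pred, classes)
    cm <- cm + cmF
    accs <- c(accs, accuracy(cmF)); ns <- c(ns, length(vaW))
  }
  if (!length(accs)) stop("no fold produced validation predictions")
  .mkCVResult(accs, ns, cm)
}

#' Run the (model kind x feature subset) experiment grid
#'
#' One cross-validated cell per combination; the same split plan is used
#' throughout so cells are comparable.  Deterministic given \code{seed}.
#'
#' @param features stride feature table.
#' @param kinds character vector of feature model kinds.
#' @param subsets character vector of feature subset names.
#' @param plan optional \code{\link{groupedKFold}} plan; built from
#'   \code{features} when NULL.
#' @param k folds used when building the plan.
#' @param seed integer RNG seed.
#' @param excludeGaits gait labels dropped from the whole grid.
#' @param ... passed to \code{\link{crossValidate}}.
#' @return List with \code{summary} (data.frame: kind, subset,
#'   mean_accuracy, sd_accuracy), \code{folds} (per-fold long table) and
#'   \code{results} (named list of \code{GaitCVResult}).
#' @export
runExperimentGrid <- function(features,
                              kinds = .featureKinds,
                              subsets = c("all", "stride_only",
                                          "hildebrand2"),
                              plan = NULL, k = 5L, seed = 1L,
                              excludeGaits = NULL, ...) {
  bad <- setdiff(kinds, .featureKinds)
  if (length(bad))
    stop("not a feature model kind: ", paste(bad, collapse = ", "))
  if (is.null(plan))
    plan <- groupedKFold(table(features$horse_id), k = k,
                         seed = childSeed(seed, "plan"))
  cells <- expand.grid(kind = kinds, subset = subsets,
                       stringsAsFactors = FALSE)
  results <- vector("list", nrow(cells))
  names(results) <- paste(cells$kind, cells$subset, sep = "/")
  for (i in seq_len(nrow(cells))) {
    results[[i]] <- crossValidate(cells$kind[i], features, plan,
                                  subset = cells$subset[i],
                                  seed = childSeed(seed, names(results)[i]),
                                  excludeGaits = excludeGaits, ...)
  }
  summary <- data.frame(
    kind = cells$kind, subset = cells$subset,
    mean_accuracy = vapply(results, function(r) r@meanAccuracy, numeric(1)),
    sd_accuracy = vapply(results, function(r) r@sdAccuracy, numeric(1)),
    row.names = NULL
  )
  folds <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    d <- results[[i]]@detail
    cbind(kind = cells$kind[i], subset = cells$subset[i], d)
  }))
  list(summary = summary, folds = folds, results = results)
}

#' Run the sensor-subset grid for the sequence model
#'
#' Normalizes each block per recording, crops it into windows per sensor
#' subset, and cross-validates the LSTM per subset with a shared split
#' plan.
#'
#' @param blocks list of \code{\linkS4class{SignalBlock}} objects.
#' @param subsets character vector of sensor subset names (see
#'   \code{\link{sensorSubset}}).
#' @param lengthS window length in seconds (1, 2 or 3).
#' @param plan optional split plan over the blocks' horses.
#' @param k folds used when building the plan.
#' @param seed integer RNG seed.
#' @param ... passed to \code{\link{trainSequenceModel}}.
#' @return List with \code{summary} (subset, mean_accuracy, sd_accuracy)
#'   and \code{results} (named list of \code{GaitCVResult}).
#' @export
runSensorGrid <- function(blocks, subsets = c("all", "upper_body",
                                              "single"),
                          lengthS = 1, plan = NULL, k = 5L, seed = 1L,
                          ...) {
  norm <- lapply(blocks, normalizeSignals)
  allWindows <- lapply(norm, windowSignals, lengthS = lengthS,
                       sites = sensorSites())
  allWindows <- unlist(allWindows, recursive = FALSE)
  wHorse <- vapply(allWindows, function(w) w$horse_id, character(1))
  if (is.null(plan))
    plan <- groupedKFold(table(wHorse), k = k,
                         seed = childSeed(seed, "plan"))
  results <- vector("list", length(subsets))
  names(results) <- subsets
  for (s in subsets) {
    keep <- as.vector(t(outer(sensorSubset(s), sensorAxes(), paste,
                              sep = ".")))
    wins <- lapply(allWindows, function(w) {
      w$x <- w$x[, keep, drop = FALSE]; w
    })
    results[[s]] <- crossValidateSignals(
      wins, plan, seed = childSeed(seed, paste0("sensor/", s)), ...)
  }
  summary <- data.frame(
    subset = subsets,
    mean_accuracy = vapply(results, function(r) r@meanAccuracy, numeric(1)),
    sd_accuracy = vapply(results, function(r) r@sdAccuracy, numeric(1)),
    row.names = NULL
  )
  list(summary = summary, results = results)
}
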