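## Feature / sensor subsets, class balancing, signal normalization and
## windowing: the data machinery in front of the classifier suite.

#' Feature subsets
#'
#' Named column subsets of the stride feature table used in the
#' classification experiments: \code{"all"} (the full per-stride variable
#' set, four-limb means for stance duration and duty factor),
#' \code{"stride_only"} (stride-timing variables only) and
#' \code{"hildebrand2"} (the two classical gait-diagram variables: duty
#' factor and lateral advanced placement).
#'
#' @param name one of \code{"all"}, \code{"stride_only"},
#'   \code{"hildebrand2"}.
#' @return Character vector of feature column names.
#' @examples
#' featureSubset("hildebrand2")
#' @export
featureSubset <- function(name = c("all", "stride_only", "hildebrand2")) {
  name <- match.arg(name)
  strideVars <- c("stride_duration", "stance_duration_mean",
                  "stride_frequency", "duty_factor_mean")
  switch(name,
    all = c(strideVars, "dap", "lap", "min_limbs", "max_limbs",
            "median_limbs", "pct_quadrupedal", "pct_tripedal",
            "pct_bipedal", "pct_single", "pct_suspension",
            names(.overlapPairs)),
    stride_only = strideVars,
    hildebrand2 = c("duty_factor_mean", "lap")
  )
}

#' Sensor subsets
#'
#' Named subsets of the seven sensor sites used in the raw-signal
#' experiments: a single site, the upper body (head, withers, pelvis),
#' upper body plus the left hind limb, the four limbs, or all seven.
#'
#' @param name subset name.
#' @param singleSite site used for \code{"single"} (default \code{"LH"}).
#' @return Character vector of site names.
#' @examples
#' sensorSubset("upper_body")
#' @export
sensorSubset <- function(name = c("all", "upper_body", "ub_plus_lh",
                                  "four_limbs", "single"),
                         singleSite = "LH") {
  name <- match.arg(name)
  stopifnot(singleSite %in% sensorSites())
  ub <- c("head", "withers", "pelvis")
  switch(name,
    all = sensorSites(),
    upper_body = ub,
    ub_plus_lh = c(ub, "LH"),
    four_limbs = limbIds(),
    single = singleSite
  )
}

#' Balance classes by duplication
#'
#' Upsamples every class with replacement to the majority-class count, the
#' standard cure for class imbalance before training.  Apply to training
#' folds only, never to validation data.
#'
#' @param table data.frame with a \code{gait} column (or the column named
#'   by \code{classColumn}).
#' @param seed integer RNG seed.
#' @param classColumn name of the class column.
#' @return data.frame in which every class has the majority count.
#' @examples
#' d <- data.frame(gait = rep(c("walk", "pace"), c(10, 4)), x = rnorm(14))
#' table(balanceByDuplication(d, seed = 1)$gait)
#' @export
balanceByDuplication <- function(table, seed = 1L, classColumn = "gait") {
  if (!nrow(table)) stop("cannot balance an empty dataset")
  cls <- as.character(table[[classColumn]])
  counts <- table(cls)
  target <- max(counts)
  withr::local_seed(as.integer(seed %% 2147483647))
  idx <- unlist(lapply(names(counts), function(cl) {
    rows <- which(cls == cl)
    if (length(rows) == target) rows
    else c(rows, sample(rows, target - length(rows), replace = TRUE))
  }))
  out <- table[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Balance a list of labeled windows by duplication
#'
#' List analogue of \code{\link{balanceByDuplication}} for windowed signal
#' data (each element carries a \code{gait} field).
#'
#' @param windows list of labeled windows from \code{\link{windowSignals}}.
#' @param seed integer RNG seed.
#' @return List of windows with equal per-class counts.
#' @export
balanceWindowsByDuplication <- function(windows, seed = 1L) {
  if (!length(windows)) stop("cannot balance an empty window list")
  cls <- vapply(windows, function(w) w$gait, character(1))
  counts <- table(cls)
  target <- max(counts)
  withr::local_seed(as.integer(seed %% 2147483647))
  idx <- unlist(lapply(names(counts), function(cl) {
    rows <- which(cls == cl)
    if (length(rows) == target) rows
    else c(rows, sample(rows, target - length(rows), replace = TRUE))
  }))
  windows[idx]
}

#' Min-max normalize the channels of a signal block
#'
#' Scales every channel to [0, 1].  With \code{stats = NULL} the per-channel
#' minimum and maximum of this recording are used (per-recording
#' normalization, the default policy); when frozen training statistics are
#' supplied they are applied instead and the result is clipped to [0, 1].
#' A constant channel maps to 0.5 with a warning.
#'
#' @param block a \code{\linkS4class{SignalBlock}}.
#' @param stats optional list with numeric vectors \code{min} and
#'   \code{max} per channel, as returned in the \code{"scaling"} attribute
#'   of a previous call.
#' @return A normalized \code{\linkS4class{SignalBlock}}; the statistics
#'   used are attached as \code{attr(x, "scaling")}.
#' @export
normalizeSignals <- function(block, stats = NULL) {
  stopifnot(is(block, "SignalBlock"))
  v <- block@values
  if (is.null(stats)) {
    stats <- list(min = apply(v, 2, min), max = apply(v, 2, max))
  }
  rng <- stats$max - stats$min
  flat <- rng <= 0
  if (any(flat)) {
    warning(sprintf("%d constant channel(s) mapped to 0.5", sum(flat)))
    rng[flat] <- 1
  }
  out <- sweep(sweep(v, 2, stats$min, "-"), 2, rng, "/")
  if (any(flat)) out[, flat] <- 0.5
  out[out < 0] <- 0
  out[out > 1] <- 1
  res <- new("SignalBlock", horseId = block@horseId, gait = block@gait,
             sampleRate = block@sampleRate, values = out)
  attr(res, "scaling") <- stats
  res
}

#' Crop a signal block into fixed-length labeled windows
#'
#' Cuts the block into consecutive non-overlapping windows of
#' \code{lengthS} seconds (\code{lengthS * sampleRate} samples), dropping
#' the trailing remainder, keeping only the channels of the requested
#' sensor subset.  Every window inherits the block's gait label and horse.
#'
#' @param block a \code{\linkS4class{SignalBlock}} (normalize first for
#'   training, see \code{\link{normalizeSignals}}).
#' @param lengthS window length in seconds, one of 1, 2 or 3.
#' @param sites character vector of sensor sites to retain (see
#'   \code{\link{sensorSubset}}).
#' @return List of windows, each a list with \code{x} (samples x channels
#'   matrix), \code{gait}, \code{horse_id}.  A block shorter than one
#'   window gives an empty list with a warning.
#' @export
windowSignals <- function(block, lengthS = 1, sites = sensorSites()) {
  stopifnot(is(block, "SignalBlock"))
  if (!lengthS %in% c(1, 2, 3))
    stop("'lengthS' must be 1, 2 or 3 seconds")
  stopifnot(all(sites %in% sensorSites()))
  wlen <- as.integer(round(lengthS * block@sampleRate))
  v <- block@values
  nWin <- nrow(v) %/% wlen
  if (nWin < 1L) {
    warning("block shorter than one window; returning empty list")
    return(list())
  }
  keep <- as.vector(t(outer(sites, sensorAxes(), paste, sep = ".")))
  lapply(seq_len(nWin), function(w) {
    rows <- ((w - 1L) * wlen + 1L):(w * wlen)
    list(x = v[rows, keep, drop = FALSE],
         gait = block@gait, horse_id = block@horseId)
  })
}
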