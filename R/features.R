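## Stride segmentation and extraction of the stride-timing and
## interlimb-coordination variables, plus the Hildebrand-diagram
## projection (duty factor vs advanced placements).

#' Segment a footfall timeline into stride windows
#'
#' A stride is the unit between two consecutive hoof-on events of the
#' reference limb (hind-limb based by default, consistent with the
#' hind-centric convention of the classical gait diagram).  Stance
#' intervals crossing a window edge are clipped to it; a window is
#' \emph{complete} when every limb has at least one hoof-on inside it, and
#' only complete windows enter feature tables.
#'
#' @param timeline a \code{\linkS4class{FootfallTimeline}}.
#' @param referenceLimb limb whose hoof-on events delimit strides
#'   (default \code{"LH"}).
#' @return List of \code{StrideWindow} objects (lists with elements
#'   \code{start}, \code{end}, \code{reference_limb}, \code{intervals}
#'   (matrix: limb index, clipped on, clipped off), \code{onset} (named
#'   first hoof-on per limb inside the window, NA if absent),
#'   \code{complete}).  Fewer than two reference onsets give an empty
#'   list with a warning.
#' @examples
#' tl <- simulateTimeline(gaitPresets()$walk, HorseProfile("h1", "warmblood"),
#'                        6, seed = 1)
#' length(segmentStrides(tl))
#' @export
segmentStrides <- function(timeline, referenceLimb = "LH") {
  stopifnot(is(timeline, "FootfallTimeline"))
  stopifnot(referenceLimb %in% limbIds())
  iv <- timeline@intervals
  limbs <- limbIds()
  refOn <- sort(iv$on_time[iv$limb == referenceLimb])
  if (length(refOn) < 2L) {
    warning("fewer than 2 reference-limb onsets; no strides segmented")
    return(list())
  }
  ## per-limb sorted on/off arrays + sweep pointers
  byLimb <- lapply(limbs, function(l) {
    sub <- iv[iv$limb == l, , drop = FALSE]
    o <- order(sub$on_time)
    list(on = sub$on_time[o], off = sub$off_time[o])
  })
  names(byLimb) <- limbs
  ptr <- setNames(rep(1L, 4L), limbs)
  ## index-anchored event pairing: periodic limb onsets are matched to
  ## strides by index (the k-th onset belongs to the k-th stride), not by
  ## window containment, so an onset that jitters marginally across a
  ## window edge still pairs with its own stride.  The anchor is the
  ## first onset within half a stride of the first window's start, and it
  ## re-locks locally if an assignment drifts out of band (irregular
  ## external data).
  T1 <- refOn[2L] - refOn[1L]
  anchor <- setNames(rep(NA_integer_, 4L), limbs)
  for (l in limbs) {
    cand <- which(byLimb[[l]]$on >= refOn[1L] - 0.5 * T1)
    if (length(cand)) anchor[[l]] <- cand[1L]
  }

  out <- vector("list", length(refOn) - 1L)
  for (w in seq_len(length(refOn) - 1L)) {
    s <- refOn[w]; e <- refOn[w + 1L]
    segLimb <- integer(); segOn <- numeric(); segOff <- numeric()
    onset <- setNames(rep(NA_real_, 4L), limbs)
    onsetOff <- setNames(rep(NA_real_, 4L), limbs)
    for (k in seq_along(limbs)) {
      l <- limbs[k]
      on <- byLimb[[l]]$on; off <- byLimb[[l]]$off
      i <- ptr[[l]]
      while (i <= length(on) && off[i] <= s) i <- i + 1L
      ptr[[l]] <- i
      j <- i
      while (j <= length(on) && on[j] < e) {
        segLimb <- c(segLimb, k)
        segOn <- c(segOn, max(on[j], s))
        segOff <- c(segOff, min(off[j], e))
        j <- j + 1L
      }
      ## the stance event belonging to this stride, by onset index; kept
      ## unclipped (stance duration is an event-level variable)
      if (!is.na(anchor[[l]])) {
        half <- 0.5 * (e - s)
        idx <- anchor[[l]] + w - 1L
        hit <- NA_integer_
        for (try in c(idx, idx + 1L, idx - 1L)) {
          if (try >= 1L && try <= length(on) &&
              on[try] >= s - half && on[try] < e + half) {
            hit <- try
            break
          }
        }
        if (!is.na(hit)) {
          onset[[l]] <- on[hit]
          onsetOff[[l]] <- off[hit]
          if (hit != idx) anchor[[l]] <- anchor[[l]] + (hit - idx)
        }
      }
    }
    out[[w]] <- structure(
      list(start = s, end = e, reference_limb = referenceLimb,
           intervals = cbind(limb = segLimb, on = segOn, off = segOff),
           onset = onset, onsetOff = onsetOff, complete = !anyNA(onset)),
      class = "StrideWindow")
  }
  out
}

#' Support profile: limbs in stance over a stride window
#'
#' Event-sweep over the sorted hoof-on/hoof-off boundaries of a window,
#' yielding the piecewise-constant count of limbs in ground contact.
#' Segment lengths sum to the stride duration exactly.
#'
#' @param window a \code{StrideWindow} from \code{\link{segmentStrides}}.
#' @return data.frame with columns \code{start}, \code{end}, \code{count}
#'   covering \code{[window$start, window$end)}.
#' @export
supportProfile <- function(window) {
  stopifnot(inherits(window, "StrideWindow"))
  m <- window$intervals
  s <- window$start; e <- window$end
  if (!nrow(m))
    return(data.frame(start = s, end = e, count = 0L))
  ev <- c(m[, "on"], m[, "off"])
  dv <- c(rep(1L, nrow(m)), rep(-1L, nrow(m)))
  o <- order(ev)
  ev <- ev[o]; dv <- dv[o]
  bp <- unique(c(s, ev, e))
  bp <- bp[bp >= s & bp <= e]
  cnt <- integer(length(bp) - 1L)
  run <- 0L; k <- 1L
  for (seg in seq_along(cnt)) {
    while (k <= length(ev) && ev[k] <= bp[seg] + 1e-15) {
      run <- run + dv[k]; k <- k + 1L
    }
    cnt[seg] <- run
  }
  if (any(cnt < 0L) || any(cnt > 4L))
    stop("invalid support profile; overlapping same-limb intervals upstream")
  data.frame(start = bp[-length(bp)], end = bp[-1L], count = cnt)
}

## signed circular difference (fore - hind) as % of stride in (-50, 50]
.circDiff <- function(fore, hind, T) {
  d <- ((fore - hind) / T * 100) %% 100
  if (d > 50) d <- d - 100
  d
}

## circular mean of values on the 100-unit circle, mapped to (-50, 50]
.circMean <- function(x) {
  th <- 2 * pi * x / 100
  m <- atan2(mean(sin(th)), mean(cos(th))) / (2 * pi) * 100
  if (m <= -50) m <- m + 100
  if (m > 50 - 1e-12 && m <= 50) m <- 50
  m
}

#' Advanced placements of a stride
#'
#' Diagonal and lateral advanced placement: the temporal dissociation at
#' hoof contact between each hind limb and its fore partner (contralateral
#' fore for DAP, ipsilateral fore for LAP), expressed as a signed circular
#' percentage of stride duration in (-50, 50] and averaged (circularly)
#' over the left and right pairs.  Positive values mean the fore contact
#' follows the hind contact.
#'
#' @param window a complete \code{StrideWindow}.
#' @return Named numeric: \code{dap}, \code{lap} (percent of stride).
#' @examples
#' tl <- simulateTimeline(gaitPresets()$pace, HorseProfile("h1", "icelandic"),
#'                        4, seed = 1)
#' advancedPlacements(segmentStrides(tl)[[2]])
#' @export
advancedPlacements <- function(window) {
  stopifnot(inherits(window, "StrideWindow"))
  if (!window$complete)
    stop("advanced placements need a complete stride window")
  on <- window$onset
  T <- window$end - window$start
  lap <- .circMean(c(.circDiff(on[["LF"]], on[["LH"]], T),
                     .circDiff(on[["RF"]], on[["RH"]], T)))
  dap <- .circMean(c(.circDiff(on[["RF"]], on[["LH"]], T),
                     .circDiff(on[["LF"]], on[["RH"]], T)))
  c(dap = dap, lap = lap)
}

## ordered limb pairs for the overlap variables
.overlapPairs <- list(
  overlap_LF_RF = c("LF", "RF"), overlap_LH_RH = c("LH", "RH"),
  overlap_LF_LH = c("LF", "LH"), overlap_RF_RH = c("RF", "RH"),
  overlap_LF_RH = c("LF", "RH"), overlap_RF_LH = c("RF", "LH")
)

## measure of intersection of two small sets of disjoint intervals
.pairOverlap <- function(onA, offA, onB, offB) {
  tot <- 0
  for (i in seq_along(onA)) {
    lo <- pmax(onA[i], onB); hi <- pmin(offA[i], offB)
    pos <- hi > lo
    if (any(pos)) tot <- tot + sum(hi[pos] - lo[pos])
  }
  tot
}

#' Feature column names
#'
#' The numeric columns produced per stride: the stride-timing variables
#' (per-limb and four-limb mean stance duration and duty factor), the
#' advanced placements, the support-phase statistics and the six limb-pair
#' overlaps.
#'
#' @return character vector of column names, in fixed order.
#' @export
featureNames <- function() {
  c("stride_duration", "stride_frequency",
    paste0("stance_duration_", limbIds()), "stance_duration_mean",
    paste0("duty_factor_", limbIds()), "duty_factor_mean",
    "dap", "lap",
    "min_limbs", "max_limbs", "median_limbs",
    "pct_quadrupedal", "pct_tripedal", "pct_bipedal", "pct_single",
    "pct_suspension",
    names(.overlapPairs))
}

#' Compute all stride variables for one window
#'
#' Populates the full per-stride variable set: stride duration and
#' frequency, per-limb and mean stance durations and duty factors,
#' diagonal and lateral advanced placement, minimum / maximum /
#' time-weighted median number of supporting limbs, the percentage of the
#' stride spent in quadrupedal, tripedal, bipedal, single-limb support and
#' suspension (these five sum to 100), and the six limb-pair overlap
#' percentages (synchronous ground contact, computed on the window-clipped
#' stance sets so phases split by the window edge are fully counted).
#'
#' @param window a complete \code{StrideWindow}.
#' @return Named numeric vector over \code{\link{featureNames}}.
#' @examples
#' tl <- simulateTimeline(gaitPresets()$trot, HorseProfile("h1", "warmblood"),
#'                        4, seed = 1)
#' computeFeatures(segmentStrides(tl)[[2]])
#' @export
computeFeatures <- function(window) {
  stopifnot(inherits(window, "StrideWindow"))
  if (!window$complete)
    stop("cannot compute features for an incomplete stride window")
  s <- window$start; e <- window$end
  T <- e - s
  m <- window$intervals
  limbs <- limbIds()

  ## stance duration is event-based: the full (unclipped) duration of the
  ## stance each limb initiates in this stride.  Summing window-clipped
  ## pieces instead would mix in the neighbouring strides' durations and
  ## bias duty factors on variable-duration strides.
  stance <- window$onsetOff[limbs] - window$onset[limbs]
  duty <- stance / T * 100

  prof <- supportProfile(window)
  len <- prof$end - prof$start
  byCount <- vapply(0:4, function(k) sum(len[prof$count == k]), numeric(1))
  pct <- byCount / T * 100
  ## time-weighted median: smallest count whose cumulative time >= half
  o <- order(prof$count)
  cum <- cumsum(len[o])
  medLimbs <- prof$count[o][which(cum >= T / 2 - 1e-12)[1L]]

  ap <- advancedPlacements(window)

  ov <- vapply(.overlapPairs, function(p) {
    a <- m[, "limb"] == match(p[1L], limbs)
    b <- m[, "limb"] == match(p[2L], limbs)
    .pairOverlap(m[a, "on"], m[a, "off"], m[b, "on"], m[b, "off"]) / T * 100
  }, numeric(1))

  out <- c(
    stride_duration = T, stride_frequency = 1 / T,
    setNames(stance, paste0("stance_duration_", limbs)),
    stance_duration_mean = mean(stance),
    setNames(duty, paste0("duty_factor_", limbs)),
    duty_factor_mean = mean(duty),
    ap["dap"], ap["lap"],
    min_limbs = min(prof$count), max_limbs = max(prof$count),
    median_limbs = as.numeric(medLimbs),
    pct_quadrupedal = pct[5L], pct_tripedal = pct[4L],
    pct_bipedal = pct[3L], pct_single = pct[2L],
    pct_suspension = pct[1L],
    ov
  )
  out[featureNames()]
}

#' Hildebrand gait-diagram coordinates
#'
#' The classical two-dimensional gait projection: x = diagonal advanced
#' placement, y = lateral advanced placement (percent of stride).  Pure
#' accessor over an extracted feature vector or table row.
#'
#' @param features named numeric vector or one-row data.frame containing
#'   \code{dap} and \code{lap}.
#' @return Named numeric \code{c(x, y)}.
#' @examples
#' hildebrandCoordinates(c(dap = 0, lap = 50))  # trot
#' @export
hildebrandCoordinates <- function(features) {
  if (is.data.frame(features)) features <- unlist(features[1L, ])
  c(x = unname(features[["dap"]]), y = unname(features[["lap"]]))
}

#' Build a per-stride feature table from timelines
#'
#' Segments every timeline, drops incomplete strides, and returns one row
#' per complete stride with the full variable set plus \code{horse_id},
#' \code{gait} and \code{stride_index}.  Deterministic; column order
#' fixed (\code{horse_id}, \code{gait}, \code{stride_index}, then
#' \code{\link{featureNames}}).
#'
#' @param timelines a \code{\linkS4class{FootfallTimeline}} or list of
#'   them (e.g. \code{simulateCohort(...)$timelines}).
#' @param referenceLimb stride segmentation reference limb.
#' @return data.frame, one row per complete stride.
#' @examples
#' coh <- simulateCohort(cohortConfig(c(warmblood = 1L), stridesPerTrial = 5L),
#'                       seed = 1)
#' head(featureTable(coh$timelines))
#' @export
featureTable <- function(timelines, referenceLimb = "LH") {
  if (is(timelines, "FootfallTimeline")) timelines <- list(timelines)
  stopifnot(length(timelines) >= 1L)
  rows <- vector("list", length(timelines))
  for (i in seq_along(timelines)) {
    tl <- timelines[[i]]
    wins <- segmentStrides(tl, referenceLimb)
    keep <- Filter(function(w) w$complete, wins)
    if (!length(keep)) next
    feats <- t(vapply(keep, computeFeatures,
                      numeric(length(featureNames()))))
    rows[[i]] <- data.frame(
      horse_id = tl@horseId, gait = tl@gait,
      stride_index = seq_len(nrow(feats)),
      feats, row.names = NULL
    )
  }
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows))
    stop("no complete strides in any timeline")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export Hildebrand coordinates for a feature table
#'
#' @param features a feature table from \code{\link{featureTable}}.
#' @return data.frame with columns \code{gait}, \code{x} (dap), \code{y}
#'   (lap), one row per stride.
#' @export
hildebrandTable <- function(features) {
  data.frame(gait = features$gait, x = features$dap, y = features$lap)
}
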