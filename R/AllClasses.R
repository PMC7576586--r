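#' @import methods
NULL

#' Limb and gait vocabularies
#'
#' The four limbs are labelled \code{LF}, \code{RF} (left/right fore) and
#' \code{LH}, \code{RH} (left/right hind).  Eight gait classes are supported:
#' the standard gaits of warmblood-type horses (walk, trot, left and right
#' canter) plus the specialty gaits of gaited breeds (toelt, pace) and of
#' Colombian breeds (paso fino, trocha).
#'
#' @return Character vector of valid limb or gait labels.
#' @examples
#' limbIds()
#' gaitLabels()
#' @export
limbIds <- function() c("LF", "RF", "LH", "RH")

#' @rdname limbIds
#' @export
gaitLabels <- function() {
  c("walk", "trot", "lcanter", "rcanter", "tolt", "pace", "paso", "trocha")
}

#' @rdname limbIds
#' @export
breedLabels <- function() {
  c("warmblood", "icelandic", "franches_montagnes", "colombian_criollo")
}

#' Sensor site names
#'
#' Seven inertial sensor attachment sites: three on the upper body midline
#' (head, withers, pelvis) and one on each distal limb.
#' Each site carries six channels (3 accelerometer + 3 gyroscope axes),
#' named \code{"<site>.<axis>"}, e.g. \code{"LF.acc_x"}.
#'
#' @return Character vector of site or axis names.
#' @export
sensorSites <- function() c("head", "withers", "pelvis", "LF", "RF", "LH", "RH")

#' @rdname sensorSites
#' @export
sensorAxes <- function() c("acc_x", "acc_y", "acc_z", "gyr_x", "gyr_y", "gyr_z")

## ---------------------------------------------------------------------------
## GaitPreset
## ---------------------------------------------------------------------------

#' GaitPreset: generative parameterization of one gait
#'
#' A \code{GaitPreset} holds everything needed to synthesize footfall
#' timelines for one gait: the phase offset of each limb's hoof-on event
#' within the stride (fraction of stride in [0,1)), the duty-factor
#' distribution (percent of stride spent in stance), the stride-duration
#' distribution (seconds), and the per-limb hoof-on timing jitter
#' (fraction of stride).
#'
#' @slot gait single gait label, see \code{\link{gaitLabels}}.
#' @slot phaseOffset named numeric(4), hoof-on phase per limb in [0,1).
#' @slot dutyFactorMean,dutyFactorSd moments of the per-stride duty-factor
#'   draw, percent of stride.
#' @slot dutyFactorLimbSd sd of the small independent per-limb perturbation
#'   added on top of the shared stride-level duty draw, percent.
#' @slot strideDurationMean,strideDurationSd moments of the per-stride
#'   duration draw, seconds.
#' @slot phaseJitterSd sd of per-limb hoof-on jitter, fraction of stride.
#' @exportClass GaitPreset
setClass("GaitPreset",
  representation(
    gait = "character",
    phaseOffset = "numeric",
    dutyFactorMean = "numeric",
    dutyFactorSd = "numeric",
    dutyFactorLimbSd = "numeric",
    strideDurationMean = "numeric",
    strideDurationSd = "numeric",
    phaseJitterSd = "numeric"
  )
)

setValidity("GaitPreset", function(object) {
  msg <- character()
  if (length(object@gait) != 1L || !object@gait %in% gaitLabels())
    msg <- c(msg, "'gait' must be one of gaitLabels()")
  po <- object@phaseOffset
  if (length(po) != 4L || !setequal(names(po), limbIds()))
    msg <- c(msg, "'phaseOffset' must be a named numeric(4) over limbIds()")
  else if (any(po < 0 | po >= 1))
    msg <- c(msg, "phase offsets must lie in [0, 1)")
  if (!(object@dutyFactorMean > 0 && object@dutyFactorMean < 100))
    msg <- c(msg, "'dutyFactorMean' must lie in (0, 100)")
  if (object@dutyFactorSd < 0 || object@dutyFactorLimbSd < 0)
    msg <- c(msg, "duty-factor sds must be >= 0")
  if (object@strideDurationMean <= 0)
    msg <- c(msg, "'strideDurationMean' must be > 0")
  if (object@strideDurationSd < 0)
    msg <- c(msg, "'strideDurationSd' must be >= 0")
  if (object@phaseJitterSd < 0)
    msg <- c(msg, "'phaseJitterSd' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a GaitPreset
#'
#' @param gait gait label.
#' @param phaseOffset named numeric(4) of hoof-on phases over
#'   \code{limbIds()}.
#' @param dutyFactorMean,dutyFactorSd duty factor moments (percent).
#' @param strideDurationMean,strideDurationSd stride duration moments
#'   (seconds).
#' @param phaseJitterSd per-limb hoof-on jitter sd (fraction of stride).
#' @param dutyFactorLimbSd per-limb duty perturbation sd (percent).
#' @return A \code{\linkS4class{GaitPreset}}.
#' @examples
#' GaitPreset("trot", c(LF = 0.5, RF = 0, LH = 0, RH = 0.5), 44.2, 4.76,
#'            0.63, 0.12)
#' @export
GaitPreset <- function(gait, phaseOffset, dutyFactorMean, dutyFactorSd,
                       strideDurationMean, strideDurationSd,
                       phaseJitterSd = 0.015, dutyFactorLimbSd = 0.5) {
  new("GaitPreset",
    gait = gait,
    phaseOffset = phaseOffset[limbIds()],
    dutyFactorMean = dutyFactorMean,
    dutyFactorSd = dutyFactorSd,
    dutyFactorLimbSd = dutyFactorLimbSd,
    strideDurationMean = strideDurationMean,
    strideDurationSd = strideDurationSd,
    phaseJitterSd = phaseJitterSd
  )
}

setMethod("show", "GaitPreset", function(object) {
  cat(sprintf(
    "GaitPreset '%s': stride %.3f +/- %.3f s, duty %.1f +/- %.2f %%\n",
    object@gait, object@strideDurationMean, object@strideDurationSd,
    object@dutyFactorMean, object@dutyFactorSd
  ))
  po <- object@phaseOffset
  cat("  phase offsets:",
      paste(sprintf("%s=%.2f", names(po), po), collapse = " "), "\n")
})

## ---------------------------------------------------------------------------
## HorseProfile
## ---------------------------------------------------------------------------

#' HorseProfile: per-individual generative modifiers
#'
#' Individual horses differ systematically in stride duration (conformation,
#' size, training) and in how noisy their sensor traces are.  A
#' \code{HorseProfile} captures this as a multiplicative stride-duration
#' factor and an additive Gaussian signal-noise sd applied to every channel.
#'
#' @slot horseId character identifier, unique within a cohort.
#' @slot breed one of \code{breedLabels()}.
#' @slot strideDurationMultiplier dimensionless, > 0.
#' @slot signalNoiseSd Gaussian noise sd in signal units, >= 0.
#' @exportClass HorseProfile
setClass("HorseProfile",
  representation(
    horseId = "character",
    breed = "character",
    strideDurationMultiplier = "numeric",
    signalNoiseSd = "numeric"
  )
)

setValidity("HorseProfile", function(object) {
  msg <- character()
  if (length(object@horseId) != 1L || !nzchar(object@horseId))
    msg <- c(msg, "'horseId' must be a non-empty string")
  if (length(object@breed) != 1L || !object@breed %in% breedLabels())
    msg <- c(msg, "'breed' must be one of breedLabels()")
  if (!(object@strideDurationMultiplier > 0))
    msg <- c(msg, "'strideDurationMultiplier' must be > 0")
  if (object@signalNoiseSd < 0)
    msg <- c(msg, "'signalNoiseSd' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a HorseProfile
#'
#' @param horseId identifier string.
#' @param breed breed label.
#' @param strideDurationMultiplier multiplicative stride-duration factor.
#' @param signalNoiseSd sensor noise sd (signal units).
#' @return A \code{\linkS4class{HorseProfile}}.
#' @examples
#' HorseProfile("ice01", "icelandic")
#' @export
HorseProfile <- function(horseId, breed, strideDurationMultiplier = 1,
                         signalNoiseSd = 0.3) {
  new("HorseProfile",
    horseId = horseId, breed = breed,
    strideDurationMultiplier = strideDurationMultiplier,
    signalNoiseSd = signalNoiseSd
  )
}

setMethod("show", "HorseProfile", function(object) {
  cat(sprintf("HorseProfile '%s' (%s): duration x%.3f, noise sd %.2f\n",
              object@horseId, object@breed,
              object@strideDurationMultiplier, object@signalNoiseSd))
})

## ---------------------------------------------------------------------------
## FootfallTimeline
## ---------------------------------------------------------------------------

#' FootfallTimeline: per-limb stance intervals for one trial
#'
#' The ground-truth footfall representation: for each limb, the ordered,
#' pairwise-disjoint stance (ground contact) intervals
#' \code{[on_time, off_time]} in seconds, over \code{[0, totalDuration]}.
#'
#' @slot horseId identifier of the horse.
#' @slot gait gait label of the trial.
#' @slot intervals data.frame with columns \code{limb}, \code{on_time},
#'   \code{off_time}.
#' @slot totalDuration trial length in seconds.
#' @exportClass FootfallTimeline
setClass("FootfallTimeline",
  representation(
    horseId = "character",
    gait = "character",
    intervals = "data.frame",
    totalDuration = "numeric"
  )
)

setValidity("FootfallTimeline", function(object) {
  msg <- character()
  iv <- object@intervals
  need <- c("limb", "on_time", "off_time")
  if (!all(need %in% names(iv)))
    return("'intervals' must have columns limb, on_time, off_time")
  if (!object@gait %in% gaitLabels())
    msg <- c(msg, "'gait' must be one of gaitLabels()")
  if (length(object@totalDuration) != 1L || object@totalDuration < 0)
    msg <- c(msg, "'totalDuration' must be a single non-negative number")
  if (nrow(iv)) {
    if (!all(iv$limb %in% limbIds()))
      msg <- c(msg, "interval limbs must be in limbIds()")
    if (any(iv$on_time >= iv$off_time))
      msg <- c(msg, "every stance interval needs on_time < off_time")
    if (any(iv$on_time < 0) || any(iv$off_time > object@totalDuration + 1e-9))
      msg <- c(msg, "intervals must lie within [0, totalDuration]")
    for (l in unique(iv$limb)) {
      sub <- iv[iv$limb == l, , drop = FALSE]
      o <- order(sub$on_time)
      if (is.unsorted(sub$on_time))
        sub <- sub[o, , drop = FALSE]
      n <- nrow(sub)
      if (n > 1L && any(sub$off_time[-n] > sub$on_time[-1L] + 1e-12)) {
        msg <- c(msg, sprintf("limb %s has overlapping stance intervals", l))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a FootfallTimeline
#'
#' @param horseId horse identifier.
#' @param gait gait label.
#' @param intervals data.frame with columns \code{limb}, \code{on_time},
#'   \code{off_time} (seconds).  Rows are sorted per limb on construction.
#' @param totalDuration trial length in seconds; defaults to the largest
#'   \code{off_time}.
#' @return A \code{\linkS4class{FootfallTimeline}}.
#' @export
FootfallTimeline <- function(horseId, gait, intervals, totalDuration = NULL) {
  if (is.null(totalDuration))
    totalDuration <- if (nrow(intervals)) max(intervals$off_time) else 0
  intervals <- intervals[order(intervals$limb, intervals$on_time), ,
                         drop = FALSE]
  rownames(intervals) <- NULL
  new("FootfallTimeline",
    horseId = horseId, gait = gait,
    intervals = intervals, totalDuration = totalDuration
  )
}

setMethod("show", "FootfallTimeline", function(object) {
  iv <- object@intervals
  cat(sprintf("FootfallTimeline: horse '%s', gait '%s', %.2f s, %d stances\n",
              object@horseId, object@gait, object@totalDuration, nrow(iv)))
  if (nrow(iv)) {
    tab <- table(iv$limb)
    cat("  stances per limb:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = " "),
        "\n")
  }
})

## ---------------------------------------------------------------------------
## SignalBlock
## ---------------------------------------------------------------------------

#' SignalBlock: multichannel fixed-rate sensor stream
#'
#' A dense real matrix of \code{n_samples x 42} sensor values: 7 sites
#' (\code{\link{sensorSites}}) times 6 axes (\code{\link{sensorAxes}}),
#' sampled at \code{sampleRate} Hz.  Column names are \code{"site.axis"}.
#'
#' @slot horseId horse identifier.
#' @slot gait gait label.
#' @slot sampleRate sampling frequency, Hz.
#' @slot values numeric matrix \code{[n_samples x 42]}.
#' @exportClass SignalBlock
setClass("SignalBlock",
  representation(
    horseId = "character",
    gait = "character",
    sampleRate = "numeric",
    values = "matrix"
  )
)

#' Channel names of a 7-site, 6-axis sensor array
#'
#' @return character(42), \code{"site.axis"} in site-major order.
#' @export
channelNames <- function() {
  as.vector(t(outer(sensorSites(), sensorAxes(), paste, sep = ".")))
}

setValidity("SignalBlock", function(object) {
  msg <- character()
  if (!object@gait %in% gaitLabels())
    msg <- c(msg, "'gait' must be one of gaitLabels()")
  if (length(object@sampleRate) != 1L || object@sampleRate <= 0)
    msg <- c(msg, "'sampleRate' must be a positive number")
  v <- object@values
  if (ncol(v) != 42L)
    msg <- c(msg, "'values' must have 42 columns (7 sites x 6 axes)")
  else if (!identical(colnames(v), channelNames()))
    msg <- c(msg, "'values' columns must be named as channelNames()")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SignalBlock", function(object) {
  cat(sprintf(
    "SignalBlock: horse '%s', gait '%s', %d samples x %d channels @ %g Hz (%.2f s)\n",
    object@horseId, object@gait, nrow(object@values), ncol(object@values),
    object@sampleRate, nrow(object@values) / object@sampleRate
  ))
})

## ---------------------------------------------------------------------------
## GaitModel / GaitCVResult
## ---------------------------------------------------------------------------

#' GaitModel: a fitted gait classifier
#'
#' Wraps a fitted model of any supported kind together with the class list
#' and the normalization statistics frozen at fit time, so that prediction
#' is self-contained.
#'
#' @slot kind model kind, one of \code{"lda"}, \code{"qda"}, \code{"tree"},
#'   \code{"forest"}, \code{"svm"}, \code{"fc"}, \code{"sequence"}.
#' @slot spec list of hyperparameters as resolved at fit time.
#' @slot fit opaque fitted object.
#' @slot classes character vector of classes seen in training.
#' @slot inputs character vector of feature columns (feature models) or
#'   channel names (sequence models).
#' @slot scaling list of normalization statistics frozen at fit time.
#' @exportClass GaitModel
setClass("GaitModel",
  representation(
    kind = "character",
    spec = "list",
    fit = "ANY",
    classes = "character",
    inputs = "character",
    scaling = "list"
  )
)

setValidity("GaitModel", function(object) {
  kinds <- c("lda", "qda", "tree", "forest", "svm", "fc", "sequence")
  if (length(object@kind) != 1L || !object@kind %in% kinds)
    return(sprintf("'kind' must be one of: %s", paste(kinds, collapse = ", ")))
  if (!length(object@classes))
    return("'classes' must be non-empty")
  TRUE
})

setMethod("show", "GaitModel", function(object) {
  cat(sprintf("GaitModel kind '%s': %d classes, %d inputs\n",
              object@kind, length(object@classes), length(object@inputs)))
})

#' GaitCVResult: grouped cross-validation summary
#'
#' @slot foldAccuracy numeric vector of per-fold accuracies (fractions).
#' @slot meanAccuracy,sdAccuracy mean and sd over folds.
#' @slot confusion pooled confusion matrix (rows = truth).
#' @slot detail data.frame with one row per fold (fold, n, accuracy).
#' @exportClass GaitCVResult
setClass("GaitCVResult",
  representation(
    foldAccuracy = "numeric",
    meanAccuracy = "numeric",
    sdAccuracy = "numeric",
    confusion = "matrix",
    detail = "data.frame"
  )
)

setValidity("GaitCVResult", function(object) {
  msg <- character()
  if (any(object@foldAccuracy < 0 | object@foldAccuracy > 1))
    msg <- c(msg, "fold accuracies must lie in [0, 1]")
  if (abs(object@meanAccuracy - mean(object@foldAccuracy)) > 1e-8)
    msg <- c(msg, "'meanAccuracy' must equal mean(foldAccuracy)")
  if (length(object@foldAccuracy) > 1L &&
      abs(object@sdAccuracy - stats::sd(object@foldAccuracy)) > 1e-8)
    msg <- c(msg, "'sdAccuracy' must equal sd(foldAccuracy)")
  cm <- object@confusion
  if (nrow(cm) != ncol(cm) || any(cm < 0))
    msg <- c(msg, "'confusion' must be a square non-negative matrix")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GaitCVResult", function(object) {
  cat(sprintf("GaitCVResult: %d folds, accuracy %.3f +/- %.3f\n",
              length(object@foldAccuracy), object@meanAccuracy,
              object@sdAccuracy))
})

## Accessor generics ---------------------------------------------------------

#' Accessors for equigait S4 objects
#'
#' \code{gaitLabel} returns the gait of a timeline, signal block or preset;
#' \code{horseId} the horse identifier; \code{stanceIntervals} the interval
#' table of a timeline; \code{signalValues} the sample matrix of a
#' \code{SignalBlock}; \code{sampleRate} its sampling frequency;
#' \code{foldAccuracies}, \code{meanAccuracy} and \code{confusionCounts}
#' the components of a \code{GaitCVResult}; \code{modelClasses} the class
#' list of a \code{GaitModel}.
#'
#' @param x an equigait S4 object.
#' @return The slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("gaitLabel", function(x) standardGeneric("gaitLabel"))
#' @rdname accessors
#' @export
setGeneric("horseId", function(x) standardGeneric("horseId"))
#' @rdname accessors
#' @export
setGeneric("stanceIntervals", function(x) standardGeneric("stanceIntervals"))
#' @rdname accessors
#' @export
setGeneric("signalValues", function(x) standardGeneric("signalValues"))
#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))
#' @rdname accessors
#' @export
setGeneric("foldAccuracies", function(x) standardGeneric("foldAccuracies"))
#' @rdname accessors
#' @export
setGeneric("meanAccuracy", function(x) standardGeneric("meanAccuracy"))
#' @rdname accessors
#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))
#' @rdname accessors
#' @export
setGeneric("modelClasses", function(x) standardGeneric("modelClasses"))

#' @rdname accessors
setMethod("gaitLabel", "FootfallTimeline", function(x) x@gait)
#' @rdname accessors
setMethod("gaitLabel", "SignalBlock", function(x) x@gait)
#' @rdname accessors
setMethod("gaitLabel", "GaitPreset", function(x) x@gait)
#' @rdname accessors
setMethod("horseId", "FootfallTimeline", function(x) x@horseId)
#' @rdname accessors
setMethod("horseId", "SignalBlock", function(x) x@horseId)
#' @rdname accessors
setMethod("horseId", "HorseProfile", function(x) x@horseId)
#' @rdname accessors
setMethod("stanceIntervals", "FootfallTimeline", function(x) x@intervals)
#' @rdname accessors
setMethod("signalValues", "SignalBlock", function(x) x@values)
#' @rdname accessors
setMethod("sampleRate", "SignalBlock", function(x) x@sampleRate)
#' @rdname accessors
setMethod("foldAccuracies", "GaitCVResult", function(x) x@foldAccuracy)
#' @rdname accessors
setMethod("meanAccuracy", "GaitCVResult", function(x) x@meanAccuracy)
#' @rdname accessors
setMethod("confusionCounts", "GaitCVResult", function(x) x@confusion)
#' @rdname accessors
setMethod("modelClasses", "GaitModel", function(x) x@classes)
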