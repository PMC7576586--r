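#' Built-in gait presets
#'
#' Returns the generative parameterization of the eight supported gaits.
#' Stride-duration and duty-factor moments follow published descriptive
#' statistics for a large multi-breed equine cohort; phase offsets encode
#' the classical footfall orderings:
#' \itemize{
#'   \item \emph{trot}: two-beat, synchronous diagonal pairs (LH+RF at 0,
#'     RH+LF at 0.5);
#'   \item \emph{pace}: two-beat, synchronous lateral pairs (LH+LF at 0,
#'     RH+RF at 0.5);
#'   \item \emph{walk}, \emph{toelt}, \emph{paso fino}: lateral-sequence
#'     four-beat, equally spaced (LH, LF, RH, RF at 0, 0.25, 0.5, 0.75);
#'   \item \emph{trocha}: diagonal-sequence four-beat, a trot whose diagonal
#'     fore contact is dissociated by \code{trochaDissociation} of a stride
#'     (fore lands slightly before its diagonal hind partner);
#'   \item \emph{canters}: three-beat with one synchronous diagonal pair
#'     (right lead: LH at 0, RH+LF at 0.3, RF at 0.45; left lead mirrored).
#' }
#'
#' The walk preset's stride duration defaults to 1.07 s, the value implied
#' by the cohort's walk stance duration (0.65 s) and duty factor (60.6 %);
#' the cohort table also prints a walk stride duration of 1.80 s which is
#' inconsistent with those two (and with the printed 0.95 Hz stride
#' frequency) and can be selected with \code{walkPrinted = TRUE}.
#'
#' Trocha carries a larger phase jitter than the other gaits (0.03 vs
#' 0.015 stride) because its footfall timing is characteristically less
#' regular than the trot it derives from.
#'
#' @param walkPrinted logical; use the printed 1.80 s walk stride duration
#'   instead of the internally consistent 1.07 s.
#' @param trochaDissociation diagonal dissociation of the trocha, fraction
#'   of stride (default 0.08).
#' @return Named list of \code{\linkS4class{GaitPreset}} objects, one per
#'   \code{\link{gaitLabels}} entry.
#' @examples
#' gaitPresets()$trot
#' @export
gaitPresets <- function(walkPrinted = FALSE, trochaDissociation = 0.08) {
  lateral4 <- c(LH = 0, LF = 0.25, RH = 0.5, RF = 0.75)
  stopifnot(trochaDissociation > 0, trochaDissociation < 0.5)
  d <- trochaDissociation
  list(
    walk = GaitPreset("walk", lateral4,
      dutyFactorMean = 60.60, dutyFactorSd = 1.85,
      strideDurationMean = if (walkPrinted) 1.80 else 1.07,
      strideDurationSd = 0.17),
    trot = GaitPreset("trot", c(LH = 0, RF = 0, RH = 0.5, LF = 0.5),
      dutyFactorMean = 44.20, dutyFactorSd = 4.76,
      strideDurationMean = 0.63, strideDurationSd = 0.12),
    lcanter = GaitPreset("lcanter", c(RH = 0, LH = 0.3, RF = 0.3, LF = 0.45),
      dutyFactorMean = 39.10, dutyFactorSd = 3.58,
      strideDurationMean = 0.50, strideDurationSd = 0.05),
    rcanter = GaitPreset("rcanter", c(LH = 0, RH = 0.3, LF = 0.3, RF = 0.45),
      dutyFactorMean = 40.00, dutyFactorSd = 3.28,
      strideDurationMean = 0.49, strideDurationSd = 0.04),
    tolt = GaitPreset("tolt", lateral4,
      dutyFactorMean = 36.10, dutyFactorSd = 2.63,
      strideDurationMean = 0.42, strideDurationSd = 0.04),
    pace = GaitPreset("pace", c(LH = 0, LF = 0, RH = 0.5, RF = 0.5),
      dutyFactorMean = 44.20, dutyFactorSd = 3.78,
      strideDurationMean = 0.54, strideDurationSd = 0.04),
    paso = GaitPreset("paso", lateral4,
      dutyFactorMean = 53.70, dutyFactorSd = 2.49,
      strideDurationMean = 0.39, strideDurationSd = 0.03),
    trocha = GaitPreset("trocha",
      c(LH = 0, RF = 1 - d, RH = 0.5, LF = 0.5 - d),
      dutyFactorMean = 51.00, dutyFactorSd = 3.34,
      strideDurationMean = 0.39, strideDurationSd = 0.04,
      phaseJitterSd = 0.03)
  )
}

#' Reference stride counts per gait
#'
#' Stride counts of the descriptive cohort the presets were parameterized
#' from; used to build synthetic cohorts with realistic class imbalance.
#'
#' @return Named integer vector over \code{\link{gaitLabels}}.
#' @export
referenceStrideCounts <- function() {
  c(walk = 1966L, trot = 1932L, lcanter = 519L, rcanter = 483L,
    tolt = 1572L, pace = 277L, paso = 401L, trocha = 426L)
}

#' Breed-to-gait legality table
#'
#' Which gaits each breed performs: warmbloods walk, trot and canter;
#' Icelandic horses additionally toelt and pace; Franches-Montagnes walk
#' and trot only; Colombian criollo horses trot, paso fino and trocha.
#'
#' @return Named list mapping each \code{\link{breedLabels}} entry to a
#'   character vector of legal gaits.
#' @export
breedGaits <- function() {
  list(
    warmblood = c("walk", "trot", "lcanter", "rcanter"),
    icelandic = c("walk", "trot", "lcanter", "rcanter", "tolt", "pace"),
    franches_montagnes = c("walk", "trot"),
    colombian_criollo = c("trot", "paso", "trocha")
  )
}
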