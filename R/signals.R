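## Synthetic IMU signal model.  This is deliberately simple plumbing to
## exercise the raw-signal classification path, not a biomechanical
## simulation: each limb channel carries an exponentially decaying impact
## transient at every hoof-on plus a swing-phase sinusoid; upper-body
## channels carry attenuated sums of the limb transients plus a vertical
## harmonic locked to stride phase; Gaussian noise is added per channel.

## per-axis gains, so the six channels of a site differ deterministically
.axisGain <- c(acc_x = 1.0, acc_y = 0.6, acc_z = 0.8,
               gyr_x = 0.5, gyr_y = 0.9, gyr_z = 0.7)

## attenuation of limb l's transient at upper-body site u
.upperWeight <- rbind(
  head    = c(LF = 0.40, RF = 0.40, LH = 0.12, RH = 0.12),
  withers = c(LF = 0.35, RF = 0.35, LH = 0.20, RH = 0.20),
  pelvis  = c(LF = 0.15, RF = 0.15, LH = 0.40, RH = 0.40)
)

## lateral axes carry limb side as a sign, so midline sensors can
## distinguish left- from right-lead gaits (as real roll/sway channels do)
.lateralAxes <- c("acc_y", "gyr_x")
.limbSign <- c(LF = 1, LH = 1, RF = -1, RH = -1)

.impactTau <- 0.030   # transient decay constant, s
.impactScale <- 0.5   # impact amplitude = .impactScale / stance duration
.swingAmp <- 0.3      # swing-phase sinusoid amplitude
.harmonicAmp <- 0.8   # upper-body stride-locked harmonic amplitude

## sum of decaying transients from the stance onsets of one limb,
## amplitude inversely proportional to that stance's duration
.limbTransient <- function(t, iv) {
  y <- numeric(length(t))
  for (r in seq_len(nrow(iv))) {
    on <- iv$on_time[r]
    amp <- .impactScale / (iv$off_time[r] - on)
    sel <- t >= on
    if (any(sel)) y[sel] <- y[sel] + amp * exp(-(t[sel] - on) / .impactTau)
  }
  y
}

## swing-phase protraction arc between consecutive stances of one limb
.swingWave <- function(t, iv) {
  y <- numeric(length(t))
  n <- nrow(iv)
  if (n < 2L) return(y)
  for (r in seq_len(n - 1L)) {
    a <- iv$off_time[r]; b <- iv$on_time[r + 1L]
    sel <- t >= a & t < b
    if (any(sel)) y[sel] <- y[sel] + .swingAmp * sin(pi * (t[sel] - a) / (b - a))
  }
  y
}

## gaits with a synchronous limb pair have a double-frequency vertical
## oscillation (two impacts per stride look-alike); pure four-beat gaits
## oscillate once per stride
.harmonicOrder <- function(gait) {
  if (gait %in% c("trot", "pace", "lcanter", "rcanter")) 2 else 1
}

## piecewise-linear stride phase from the reference-limb onsets
.stridePhase <- function(t, refOn) {
  n <- length(refOn)
  if (n < 2L) return(t / max(t[length(t)], 1e-9))
  ph <- stats::approx(refOn, seq(0, n - 1), xout = t, rule = 2)$y
  ph
}

#' Simulate multichannel IMU-like signals from a footfall timeline
#'
#' Renders a \code{\linkS4class{SignalBlock}} (7 sites x 6 axes, see
#' \code{\link{channelNames}}) from the stance intervals of a timeline.
#' Limb-mounted channels receive an exponentially decaying transient at
#' each hoof-on whose amplitude scales inversely with that stance's
#' duration (so faster gaits peak higher), plus a swing-phase sinusoid.
#' Upper-body channels (head, withers, pelvis) receive attenuated sums of
#' the limb transients plus a vertical harmonic locked to stride phase
#' (twice per stride for gaits with a synchronous limb pair, once per
#' stride otherwise).  Gaussian noise of sd \code{noiseSd} is added to all
#' channels.  Lateral axes carry the limb side as a sign so that midline
#' sensors retain left/right information.
#'
#' @param timeline a \code{\linkS4class{FootfallTimeline}} with at least
#'   one stance interval.
#' @param sampleRate sampling frequency in Hz (default 200).
#' @param seed integer RNG seed (noise); equal seeds give bit-identical
#'   output.
#' @param noiseSd Gaussian noise sd; typically the horse profile's
#'   \code{signalNoiseSd}.
#' @param referenceLimb limb whose onsets define stride phase.
#' @return A \code{\linkS4class{SignalBlock}}.
#' @examples
#' tl <- simulateTimeline(gaitPresets()$trot, HorseProfile("h1", "warmblood"),
#'                        5, seed = 1)
#' sb <- simulateSignals(tl, seed = 1, noiseSd = 0)
#' dim(signalValues(sb))
#' @export
simulateSignals <- function(timeline, sampleRate = 200, seed = 1L,
                            noiseSd = 0.3, referenceLimb = "LH") {
  stopifnot(is(timeline, "FootfallTimeline"))
  iv <- timeline@intervals
  if (!nrow(iv)) stop("timeline has no stance intervals")
  if (sampleRate <= 0) stop("'sampleRate' must be > 0")

  nSamples <- round(timeline@totalDuration * sampleRate)
  t <- (seq_len(nSamples) - 1L) / sampleRate

  limbs <- limbIds()
  trans <- sapply(limbs, function(l)
    .limbTransient(t, iv[iv$limb == l, , drop = FALSE]))
  swing <- sapply(limbs, function(l)
    .swingWave(t, iv[iv$limb == l, , drop = FALSE]))

  refOn <- sort(iv$on_time[iv$limb == referenceLimb])
  phase <- .stridePhase(t, refOn)
  harm <- .harmonicAmp * sin(2 * pi * .harmonicOrder(timeline@gait) * phase)

  withr::local_seed(as.integer(seed %% 2147483647))
  vals <- matrix(0, nSamples, 42L, dimnames = list(NULL, channelNames()))
  for (site in sensorSites()) {
    if (site %in% limbs) {
      base <- trans[, site] + swing[, site]
      side <- .limbSign[[site]]
    } else {
      base <- as.vector(trans %*% .upperWeight[site, limbs]) + harm
      side <- 1
    }
    for (ax in sensorAxes()) {
      g <- .axisGain[[ax]]
      if (site %in% limbs && ax %in% .lateralAxes) g <- g * side
      ch <- paste(site, ax, sep = ".")
      ## lateral upper-body axes see the signed limb mix instead of the
      ## unsigned sum, preserving left/right asymmetry at the midline
      if (!site %in% limbs && ax %in% .lateralAxes) {
        sig <- as.vector(trans %*% (.upperWeight[site, limbs] *
                                      .limbSign[limbs]))
        vals[, ch] <- g * sig
      } else {
        vals[, ch] <- g * base
      }
      if (noiseSd > 0)
        vals[, ch] <- vals[, ch] + stats::rnorm(nSamples, 0, noiseSd)
    }
  }
  new("SignalBlock", horseId = timeline@horseId, gait = timeline@gait,
      sampleRate = sampleRate, values = vals)
}

#' Simulate timelines and signal blocks for a whole cohort
#'
#' Convenience wrapper: runs \code{\link{simulateCohort}} and renders one
#' \code{\linkS4class{SignalBlock}} per timeline with each horse's own
#' noise level.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @param seed integer root seed.
#' @param sampleRate sampling frequency in Hz.
#' @return List with \code{horses}, \code{timelines}, \code{signals}
#'   (parallel named lists).
#' @export
simulateCohortSignals <- function(config = cohortConfig(), seed = 1L,
                                  sampleRate = 200) {
  coh <- simulateCohort(config, seed)
  noise <- vapply(coh$horses, function(h) h@signalNoiseSd, numeric(1))
  signals <- lapply(names(coh$timelines), function(nm) {
    tl <- coh$timelines[[nm]]
    simulateSignals(tl, sampleRate,
                    seed = childSeed(seed, paste0("signal/", nm)),
                    noiseSd = noise[[tl@horseId]])
  })
  names(signals) <- names(coh$timelines)
  c(coh, list(signals = signals))
}
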