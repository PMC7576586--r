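## Seed derivation: child streams are derived from the root seed and a
## string identifier by a small multiplicative hash, so adding a horse to a
## cohort config never reshuffles another horse's draws.

#' Derive a child RNG seed from a root seed and an identifier
#'
#' @param rootSeed integer root seed.
#' @param id character identifier (e.g. \code{"ice01/trot/1"}).
#' @return A single integer in [0, 2^31).
#' @export
childSeed <- function(rootSeed, id) {
  h <- 0
  for (k in utf8ToInt(as.character(id))) h <- (h * 31 + k) %% 2147483647
  as.integer((h + (as.numeric(rootSeed) %% 2147483647) * 48271) %% 2147483647)
}

## truncated-normal draw, lower bound only (resampling; bounds are several
## sd away from the mean for every preset so rejection is rare)
rtruncnorm_low <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower)
  guard <- 0L
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower]
    guard <- guard + 1L
    if (guard > 1000L) { x[bad] <- lower; break }
  }
  x
}

#' Simulate a footfall timeline for one trial
#'
#' Generates \code{nStrides} complete stride cycles for one horse in one
#' gait.  Per stride, the duration is drawn from
#' Normal(\code{strideDurationMean} \eqn{\times} multiplier,
#' \code{strideDurationSd}) truncated below at 0.2 s; a shared duty factor
#' is drawn from Normal(\code{dutyFactorMean}, \code{dutyFactorSd}) with an
#' independent Normal(0, \code{dutyFactorLimbSd}) perturbation per limb, so
#' stance and stride durations stay correlated across limbs; each limb's
#' hoof-on lands at its phase offset plus Normal(0, \code{phaseJitterSd})
#' jitter (fractions of the stride), and its hoof-off at hoof-on + duty
#' \eqn{\times} stride duration.
#'
#' @param preset a \code{\linkS4class{GaitPreset}}.
#' @param horse a \code{\linkS4class{HorseProfile}}.
#' @param nStrides number of stride cycles, >= 1.
#' @param seed integer RNG seed; equal seeds give identical timelines.
#' @return A \code{\linkS4class{FootfallTimeline}}.
#' @examples
#' tl <- simulateTimeline(gaitPresets()$trot, HorseProfile("h1", "warmblood"),
#'                        nStrides = 5, seed = 1)
#' stanceIntervals(tl)
#' @export
simulateTimeline <- function(preset, horse, nStrides, seed) {
  stopifnot(is(preset, "GaitPreset"), is(horse, "HorseProfile"))
  if (length(nStrides) != 1L || nStrides < 1 || nStrides != round(nStrides))
    stop("'nStrides' must be a positive integer")
  if (preset@dutyFactorMean >= 100)
    stop("duty factor must be < 100 %")
  nStrides <- as.integer(nStrides)

  withr::local_seed(as.integer(seed %% 2147483647))
  mu <- preset@strideDurationMean * horse@strideDurationMultiplier
  durs <- rtruncnorm_low(nStrides, mu, preset@strideDurationSd, 0.2)
  starts <- c(0, cumsum(durs))

  limbs <- limbIds()
  po <- preset@phaseOffset[limbs]
  ## stride-level duty draw shared by all limbs + small per-limb noise,
  ## clamped well inside (0, 100)
  dutyStride <- stats::rnorm(nStrides, preset@dutyFactorMean,
                             preset@dutyFactorSd)
  duty <- matrix(dutyStride, nStrides, 4) +
    matrix(stats::rnorm(nStrides * 4L, 0, preset@dutyFactorLimbSd),
           nStrides, 4)
  duty <- pmin(pmax(duty, 1), 99)
  jit <- matrix(stats::rnorm(nStrides * 4L, 0, preset@phaseJitterSd),
                nStrides, 4)

  on <- starts[seq_len(nStrides)] +
    (matrix(po, nStrides, 4, byrow = TRUE) + jit) * durs
  on <- pmax(on, 0)
  off <- on + duty / 100 * durs

  iv <- data.frame(
    limb = rep(limbs, each = nStrides),
    on_time = as.vector(on),
    off_time = as.vector(off)
  )
  ## with large jitter, consecutive stances of one limb can collide; clip
  ## the earlier hoof-off just before the later hoof-on
  iv <- iv[order(iv$limb, iv$on_time), , drop = FALSE]
  for (l in limbs) {
    idx <- which(iv$limb == l)
    n <- length(idx)
    if (n > 1L) {
      ov <- which(iv$off_time[idx[-n]] >= iv$on_time[idx[-1L]])
      if (length(ov))
        iv$off_time[idx[ov]] <- iv$on_time[idx[ov + 1L]] - 1e-9
    }
  }
  total <- max(iv$off_time, starts[nStrides + 1L])
  FootfallTimeline(horse@horseId, preset@gait, iv, total)
}

#' Cohort configuration
#'
#' @param horsesPerBreed named integer vector over (a subset of)
#'   \code{breedLabels()}: number of horses per breed.
#' @param stridesPerTrial strides generated per (horse, gait) trial.
#' @param gaits optional named list overriding \code{\link{breedGaits}} per
#'   breed.
#' @param multiplierSd sd of the per-horse stride-duration multiplier
#'   (mean 1, truncated to [0.6, 1.4]).
#' @param signalNoiseSd sensor noise sd assigned to every horse.
#' @param allowIllegal logical; permit (breed, gait) pairs outside
#'   \code{\link{breedGaits}}.
#' @return A list of class \code{"cohortConfig"}.
#' @export
cohortConfig <- function(horsesPerBreed = c(warmblood = 4L, icelandic = 5L,
                                            franches_montagnes = 2L,
                                            colombian_criollo = 5L),
                         stridesPerTrial = 25L,
                         gaits = NULL,
                         multiplierSd = 0.12,
                         signalNoiseSd = 0.3,
                         allowIllegal = FALSE) {
  if (is.null(names(horsesPerBreed)) ||
      !all(names(horsesPerBreed) %in% breedLabels()))
    stop("'horsesPerBreed' must be named by breedLabels()")
  legal <- breedGaits()
  if (is.null(gaits)) {
    gaits <- legal[names(horsesPerBreed)]
  } else {
    for (b in names(gaits)) {
      bad <- setdiff(gaits[[b]], legal[[b]])
      if (length(bad) && !allowIllegal)
        stop(sprintf("gait(s) %s are not performed by breed '%s'",
                     paste(bad, collapse = ", "), b))
    }
  }
  structure(list(horsesPerBreed = horsesPerBreed,
                 stridesPerTrial = as.integer(stridesPerTrial),
                 gaits = gaits, multiplierSd = multiplierSd,
                 signalNoiseSd = signalNoiseSd),
            class = "cohortConfig")
}

#' Simulate the horse profiles of a cohort
#'
#' Each horse's stride-duration multiplier is drawn once (from its own
#' seeded stream) and reused for all of that horse's trials.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @param seed integer root seed.
#' @return List of \code{\linkS4class{HorseProfile}} objects.
#' @export
simulateHorses <- function(config, seed) {
  stopifnot(inherits(config, "cohortConfig"))
  profiles <- list()
  for (b in names(config$horsesPerBreed)) {
    nb <- config$horsesPerBreed[[b]]
    if (nb < 1L) next
    for (i in seq_len(nb)) {
      id <- sprintf("%s%02d", substr(b, 1, 3), i)
      withr::local_seed(childSeed(seed, paste0("horse/", b, "/", id)))
      mult <- min(max(stats::rnorm(1, 1, config$multiplierSd), 0.6), 1.4)
      profiles[[id]] <- HorseProfile(id, b, mult, config$signalNoiseSd)
    }
  }
  profiles
}

#' Simulate a cohort of footfall timelines
#'
#' Generates one trial (timeline) per horse per legal gait.  Only
#' breed-legal gaits are produced (see \code{\link{breedGaits}}) unless the
#' config was built with \code{allowIllegal = TRUE}.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @param seed integer root seed; child streams are derived per horse and
#'   per trial, so the same seed always reproduces the same cohort.
#' @return List with elements \code{horses} (profiles) and
#'   \code{timelines} (list of \code{\linkS4class{FootfallTimeline}}).
#' @examples
#' coh <- simulateCohort(cohortConfig(c(warmblood = 2L), stridesPerTrial = 5L),
#'                       seed = 1)
#' length(coh$timelines)
#' @export
simulateCohort <- function(config = cohortConfig(), seed = 1L) {
  stopifnot(inherits(config, "cohortConfig"))
  horses <- simulateHorses(config, seed)
  presets <- gaitPresets()
  timelines <- list()
  for (h in horses) {
    gs <- config$gaits[[h@breed]]
    for (g in gs) {
      tl <- simulateTimeline(presets[[g]], h, config$stridesPerTrial,
                             childSeed(seed, paste0("trial/", h@horseId,
                                                    "/", g)))
      timelines[[paste(h@horseId, g, sep = "/")]] <- tl
    }
  }
  list(horses = horses, timelines = timelines)
}
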