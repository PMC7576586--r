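## Shared fixtures: ideal (noise-free) presets with known closed-form
## feature values, and a dense-grid brute-force oracle for support-phase
## statistics.

idealPreset <- function(gait, offsets, duty, strideDuration = 1) {
  GaitPreset(gait, offsets, dutyFactorMean = duty, dutyFactorSd = 0,
             strideDurationMean = strideDuration, strideDurationSd = 0,
             phaseJitterSd = 0, dutyFactorLimbSd = 0)
}

idealTrot <- function(duty = 44.2, strideDuration = 1)
  idealPreset("trot", c(LH = 0, RF = 0, RH = 0.5, LF = 0.5), duty,
              strideDuration)

idealWalk <- function(duty = 60, strideDuration = 1)
  idealPreset("walk", c(LH = 0, LF = 0.25, RH = 0.5, RF = 0.75), duty,
              strideDuration)

idealPace <- function(duty = 44.2, strideDuration = 1)
  idealPreset("pace", c(LH = 0, LF = 0, RH = 0.5, RF = 0.5), duty,
              strideDuration)

quietHorse <- function(id = "h1", breed = "warmblood")
  HorseProfile(id, breed, strideDurationMultiplier = 1, signalNoiseSd = 0)

## dense-grid oracle: sample the limbs-in-stance count on a fine grid over
## a stride window and integrate by the rectangle rule
gridSupportOracle <- function(timeline, start, end, nGrid = 1e4) {
  iv <- stanceIntervals(timeline)
  tt <- seq(start, end, length.out = nGrid + 1L)[-(nGrid + 1L)]
  counts <- integer(length(tt))
  for (r in seq_len(nrow(iv)))
    counts <- counts + as.integer(tt >= iv$on_time[r] & tt < iv$off_time[r])
  counts
}

## fraction of grid time spent at each support count 0..4, in percent
gridSupportPct <- function(timeline, start, end, nGrid = 1e4) {
  counts <- gridSupportOracle(timeline, start, end, nGrid)
  vapply(0:4, function(k) mean(counts == k) * 100, numeric(1))
}

## a small randomized timeline (random gait preset, jittered)
randomTimeline <- function(seed) {
  withr::local_seed(seed)
  gait <- sample(gaitLabels(), 1)
  preset <- gaitPresets()[[gait]]
  horse <- HorseProfile("rh", "icelandic",
                        strideDurationMultiplier = runif(1, 0.8, 1.2),
                        signalNoiseSd = 0)
  simulateTimeline(preset, horse, nStrides = sample(3:6, 1), seed = seed)
}
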