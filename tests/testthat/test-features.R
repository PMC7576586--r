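test_that("segmentation is fencepost-correct and telescopes", {
  tl <- simulateTimeline(gaitPresets()$trot,
                         HorseProfile("h1", "warmblood", 1, 0),
                         11, seed = 3)
  wins <- segmentStrides(tl)
  nOn <- sum(stanceIntervals(tl)$limb == "LH")
  expect_length(wins, nOn - 1L)
  ## sum of window durations equals the span of reference onsets
  refOn <- sort(stanceIntervals(tl)$on_time[stanceIntervals(tl)$limb == "LH"])
  spans <- vapply(wins, function(w) w$end - w$start, numeric(1))
  expect_equal(sum(spans), max(refOn) - min(refOn))
})

test_that("zero-jitter timelines segment into complete windows only", {
  tl <- simulateTimeline(idealTrot(), quietHorse(), 8, seed = 1)
  wins <- segmentStrides(tl)
  expect_true(all(vapply(wins, function(w) w$complete, logical(1))))
})

test_that("a too-short timeline warns and yields no strides", {
  iv <- data.frame(limb = c("LH", "LF", "RF", "RH"),
                   on_time = c(0, 0.2, 0.4, 0.6),
                   off_time = c(0.1, 0.3, 0.5, 0.7))
  tl <- FootfallTimeline("h1", "walk", iv)
  expect_warning(wins <- segmentStrides(tl), "fewer than 2")
  expect_length(wins, 0)
})

test_that("ideal trot support phases match the closed form", {
  ## duty d < 50 with synchronous diagonal pairs: bipedal = 2d,
  ## suspension = 100 - 2d, support alternates between 0 and 2 limbs
  d <- 44.2
  tl <- simulateTimeline(idealTrot(duty = d), quietHorse(), 6, seed = 1)
  f <- computeFeatures(segmentStrides(tl)[[3]])
  expect_equal(unname(f["pct_bipedal"]), 2 * d, tolerance = 1e-9)
  expect_equal(unname(f["pct_suspension"]), 100 - 2 * d, tolerance = 1e-9)
  expect_equal(unname(f[c("min_limbs", "max_limbs", "median_limbs")]),
               c(0, 2, 2))
  prof <- supportProfile(segmentStrides(tl)[[3]])
  expect_setequal(unique(prof$count), c(0L, 2L))
})

test_that("ideal walk support phases match the closed form", {
  ## duty 60, spacing 25: tripedal 40 %, bipedal 60 %
  tl <- simulateTimeline(idealWalk(), quietHorse(), 6, seed = 1)
  f <- computeFeatures(segmentStrides(tl)[[3]])
  expect_equal(unname(f["pct_tripedal"]), 40, tolerance = 1e-9)
  expect_equal(unname(f["pct_bipedal"]), 60, tolerance = 1e-9)
  expect_equal(unname(f["overlap_LF_LH"]), 35, tolerance = 1e-9)
  expect_equal(unname(f[c("min_limbs", "max_limbs")]), c(2, 3))
})

test_that("advanced placements give the canonical gait-diagram corners", {
  h <- quietHorse()
  trot <- computeFeatures(segmentStrides(
    simulateTimeline(idealTrot(), h, 5, seed = 1))[[2]])
  expect_equal(unname(hildebrandCoordinates(trot)), c(0, 50))
  pace <- computeFeatures(segmentStrides(
    simulateTimeline(idealPace(), h, 5, seed = 1))[[2]])
  expect_equal(unname(hildebrandCoordinates(pace)), c(50, 0))
  walk <- computeFeatures(segmentStrides(
    simulateTimeline(idealWalk(), h, 5, seed = 1))[[2]])
  expect_equal(unname(hildebrandCoordinates(walk)), c(-25, 25))
})

test_that("event-sweep support profile agrees with the dense-grid oracle", {
  for (seed in 1:20) {
    tl <- randomTimeline(seed + 100)
    wins <- Filter(function(w) w$complete, segmentStrides(tl))
    if (!length(wins)) next
    w <- wins[[max(1L, length(wins) %/% 2L)]]
    f <- computeFeatures(w)
    oracle <- gridSupportPct(tl, w$start, w$end, nGrid = 1e4)
    sweep <- unname(f[c("pct_suspension", "pct_single", "pct_bipedal",
                        "pct_tripedal", "pct_quadrupedal")])
    expect_equal(sweep, oracle, tolerance = 0.05)
  }
})

test_that("per-stride feature invariants hold on jittered cohorts", {
  coh <- simulateCohort(cohortConfig(c(icelandic = 2L),
                                     stridesPerTrial = 10L), seed = 5)
  ft <- featureTable(coh$timelines)
  pctSum <- ft$pct_quadrupedal + ft$pct_tripedal + ft$pct_bipedal +
    ft$pct_single + ft$pct_suspension
  expect_equal(pctSum, rep(100, nrow(ft)), tolerance = 1e-6)
  expect_true(all(ft$min_limbs <= ft$median_limbs))
  expect_true(all(ft$median_limbs <= ft$max_limbs))
  for (l in limbIds())
    expect_equal(ft[[paste0("duty_factor_", l)]],
                 ft[[paste0("stance_duration_", l)]] /
                   ft$stride_duration * 100,
                 tolerance = 1e-9)
  expect_equal(ft$stride_frequency, 1 / ft$stride_duration,
               tolerance = 1e-9)
})

test_that("features are invariant to a global time translation", {
  tl <- randomTimeline(7)
  iv <- stanceIntervals(tl)
  iv$on_time <- iv$on_time + 3.5
  iv$off_time <- iv$off_time + 3.5
  shifted <- FootfallTimeline(horseId(tl), gaitLabel(tl), iv,
                              tl@totalDuration + 3.5)
  fa <- featureTable(tl)
  fb <- featureTable(shifted)
  expect_equal(fa[, featureNames()], fb[, featureNames()],
               tolerance = 1e-9)
})

test_that("left-right mirroring preserves symmetric-gait placements and swaps canter leads", {
  mirror <- function(tl) {
    iv <- stanceIntervals(tl)
    swap <- c(LF = "RF", RF = "LF", LH = "RH", RH = "LH")
    iv$limb <- unname(swap[iv$limb])
    FootfallTimeline(horseId(tl), gaitLabel(tl), iv, tl@totalDuration)
  }
  h <- quietHorse()
  ## symmetric gait: dap/lap unchanged under mirroring
  tl <- simulateTimeline(idealWalk(), h, 6, seed = 1)
  fa <- computeFeatures(segmentStrides(tl)[[3]])
  fb <- computeFeatures(segmentStrides(mirror(tl))[[3]])
  expect_equal(fa[c("dap", "lap")], fb[c("dap", "lap")], tolerance = 1e-9)
  ## mirrored right canter reproduces the left canter's placements
  p <- gaitPresets()
  pr <- GaitPreset("rcanter", p$rcanter@phaseOffset, 40, 0, 0.49, 0,
                   phaseJitterSd = 0, dutyFactorLimbSd = 0)
  pl <- GaitPreset("lcanter", p$lcanter@phaseOffset, 40, 0, 0.49, 0,
                   phaseJitterSd = 0, dutyFactorLimbSd = 0)
  fr <- computeFeatures(segmentStrides(
    mirror(simulateTimeline(pr, h, 6, seed = 2)))[[3]])
  fl <- computeFeatures(segmentStrides(
    simulateTimeline(pl, h, 6, seed = 2))[[3]])
  expect_equal(fr[c("dap", "lap")], fl[c("dap", "lap")], tolerance = 1e-9)
})

test_that("zero-noise round trip recovers the preset parameters exactly", {
  d <- 51
  p <- idealPreset("trocha", c(LH = 0, RF = 0.92, RH = 0.5, LF = 0.42), d,
                   strideDuration = 0.39)
  tl <- simulateTimeline(p, quietHorse(), 8, seed = 1)
  ft <- featureTable(tl)
  ## the opening window has no preceding stride to wrap stance in from,
  ## so restrict to steady-state strides
  ft <- ft[-1L, ]
  expect_equal(ft$stride_duration, rep(0.39, nrow(ft)), tolerance = 1e-9)
  expect_equal(ft$duty_factor_mean, rep(d, nrow(ft)), tolerance = 1e-9)
  ## lap = (0.42 - 0) * 100 = 42; dap = -8 (fore lands before the hind)
  expect_equal(ft$lap, rep(42, nrow(ft)), tolerance = 1e-9)
  expect_equal(ft$dap, rep(-8, nrow(ft)), tolerance = 1e-9)
})

test_that("feature tables have fixed shape and drop incomplete strides", {
  coh <- simulateCohort(cohortConfig(c(franches_montagnes = 2L),
                                     stridesPerTrial = 10L), seed = 2)
  ft <- featureTable(coh$timelines)
  expect_identical(names(ft),
                   c("horse_id", "gait", "stride_index", featureNames()))
  ## zero-jitter timelines: 3 timelines x 10 strides -> 9 windows each
  tls <- lapply(1:3, function(i)
    simulateTimeline(idealTrot(), quietHorse(paste0("h", i)), 11, seed = i))
  expect_equal(nrow(featureTable(tls)), 30)
})

test_that("toelt sits between pace and trot on the lateral-placement axis", {
  cfg <- cohortConfig(c(icelandic = 3L), stridesPerTrial = 15L)
  ft <- featureTable(simulateCohort(cfg, seed = 8)$timelines)
  hb <- hildebrandTable(ft)
  ## trot's lap sits on the +/-50 wrap of the circular scale, so compare
  ## lateral dissociation magnitudes
  med <- tapply(abs(hb$y), hb$gait, stats::median)
  expect_gt(med[["tolt"]], med[["pace"]])
  expect_lt(med[["tolt"]], med[["trot"]])
})
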