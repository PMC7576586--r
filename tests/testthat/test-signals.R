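test_that("signal generation is bit-reproducible given the seed", {
  tl <- simulateTimeline(gaitPresets()$trot,
                         HorseProfile("h1", "warmblood", 1, 0.4),
                         6, seed = 2)
  a <- simulateSignals(tl, seed = 7, noiseSd = 0.4)
  b <- simulateSignals(tl, seed = 7, noiseSd = 0.4)
  expect_identical(signalValues(a), signalValues(b))
  expect_equal(dim(signalValues(a)),
               c(round(tl@totalDuration * 200), 42))
  expect_identical(colnames(signalValues(a)), channelNames())
})

test_that("limb channels carry one impact transient per stance", {
  ## noiseless LF channel: peaks above half-max count the LF stances
  tl <- simulateTimeline(gaitPresets()$trot, quietHorse(), 9, seed = 4)
  v <- signalValues(simulateSignals(tl, seed = 1, noiseSd = 0))
  ch <- v[, "LF.acc_x"]
  above <- ch > max(ch) / 2
  nPeaks <- sum(diff(above) == 1) + above[1]
  expect_equal(nPeaks, sum(stanceIntervals(tl)$limb == "LF"))
})

test_that("faster gaits produce larger impact amplitudes", {
  h <- quietHorse()
  trot <- simulateSignals(simulateTimeline(gaitPresets()$trot, h, 8,
                                           seed = 3), seed = 1, noiseSd = 0)
  walk <- simulateSignals(simulateTimeline(gaitPresets()$walk, h, 8,
                                           seed = 3), seed = 1, noiseSd = 0)
  for (ch in c("LF.acc_x", "withers.acc_z"))
    expect_gt(max(abs(signalValues(trot)[, ch])),
              max(abs(signalValues(walk)[, ch])))
})

test_that("midline sensors keep left/right lead information", {
  ## the lateral axes flip sign between mirrored canter leads, so a
  ## pelvis-mounted sensor can separate them
  h <- quietHorse()
  l <- simulateSignals(simulateTimeline(gaitPresets()$lcanter, h, 10,
                                        seed = 5), seed = 1, noiseSd = 0)
  r <- simulateSignals(simulateTimeline(gaitPresets()$rcanter, h, 10,
                                        seed = 5), seed = 1, noiseSd = 0)
  skewL <- mean(signalValues(l)[, "pelvis.acc_y"]^3)
  skewR <- mean(signalValues(r)[, "pelvis.acc_y"]^3)
  expect_true(sign(skewL) != sign(skewR) || abs(skewL - skewR) > 1e-6)
})

test_that("an empty timeline is rejected", {
  tl <- FootfallTimeline("h1", "trot",
                         data.frame(limb = character(0),
                                    on_time = numeric(0),
                                    off_time = numeric(0)),
                         totalDuration = 1)
  expect_error(simulateSignals(tl, seed = 1), "no stance")
})

test_that("min-max normalization maps channels into [0, 1]", {
  tl <- simulateTimeline(gaitPresets()$pace,
                         HorseProfile("h1", "icelandic", 1, 0.5),
                         6, seed = 2)
  sb <- simulateSignals(tl, seed = 3, noiseSd = 0.5)
  nb <- normalizeSignals(sb)
  v <- signalValues(nb)
  expect_gte(min(v), 0)
  expect_lte(max(v), 1)
  ## applying the frozen stats to already-normalized data is idempotent
  st <- attr(nb, "scaling")
  expect_equal(range(signalValues(normalizeSignals(sb, st))), c(0, 1))
  ## explicit three-point contract
  toy <- sb
  toy@values[, 1] <- rep(c(-2, 0, 2), length.out = nrow(toy@values))
  tv <- signalValues(normalizeSignals(toy))[1:3, 1]
  expect_equal(tv, c(0, 0.5, 1))
})

test_that("a constant channel maps to 0.5 with a warning", {
  tl <- simulateTimeline(gaitPresets()$trot, quietHorse(), 4, seed = 1)
  sb <- simulateSignals(tl, seed = 1, noiseSd = 0)
  sb@values[, "head.gyr_x"] <- 3.3
  expect_warning(nb <- normalizeSignals(sb), "constant")
  expect_true(all(signalValues(nb)[, "head.gyr_x"] == 0.5))
})

test_that("windowing crops to floor(duration / length) labeled windows", {
  tl <- simulateTimeline(idealWalk(duty = 60, strideDuration = 1),
                         quietHorse(), 10, seed = 1)
  sb <- simulateSignals(tl, seed = 1, noiseSd = 0)
  dur <- nrow(signalValues(sb)) / 200
  w3 <- windowSignals(sb, 3, sensorSites())
  expect_length(w3, floor(dur / 3))
  expect_true(all(vapply(w3, function(w) nrow(w$x), integer(1)) == 600L))
  wub <- windowSignals(sb, 1, sensorSubset("upper_body"))
  expect_equal(ncol(wub[[1]]$x), 18L)
  expect_true(all(vapply(wub, function(w) w$gait, character(1)) == "walk"))
  ## too-short block: empty with a warning
  short <- new("SignalBlock", horseId = "h1", gait = "walk",
               sampleRate = 200,
               values = signalValues(sb)[1:100, , drop = FALSE])
  expect_warning(we <- windowSignals(short, 1), "shorter")
  expect_length(we, 0)
})
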