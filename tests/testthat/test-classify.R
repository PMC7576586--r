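test_that("duplication balancing equalizes class counts", {
  d <- data.frame(gait = rep(c("walk", "pace", "trot"), c(10, 4, 7)),
                  x = seq_len(21))
  b <- balanceByDuplication(d, seed = 1)
  expect_true(all(table(b$gait) == 10))
  ## duplicated rows are genuine copies of original rows
  expect_true(all(b$x %in% d$x))
  ## already balanced data pass through unchanged
  e <- data.frame(gait = rep(c("walk", "trot"), each = 5), x = 1:10)
  expect_equal(sort(balanceByDuplication(e, seed = 2)$x), e$x)
  expect_error(balanceByDuplication(d[0, ], seed = 1), "empty")
})

test_that("cohort-proportioned class imbalance is removed before training", {
  ## stride shares mirror the reference cohort (e.g. pace is ~14x rarer
  ## than walk); after balancing all present classes are equal
  counts <- round(referenceStrideCounts() / 20)
  d <- data.frame(gait = rep(names(counts), counts))
  b <- balanceByDuplication(d, seed = 3)
  expect_length(unique(table(b$gait)), 1L)
  expect_true(all(table(b$gait) == max(counts)))
})

test_that("feature subsets are nested and correctly sized", {
  expect_setequal(featureSubset("hildebrand2"),
                  c("duty_factor_mean", "lap"))
  expect_true(all(featureSubset("stride_only") %in% featureSubset("all")))
  expect_length(featureSubset("all"), 20L)
  expect_setequal(sensorSubset("upper_body"),
                  c("head", "withers", "pelvis"))
  expect_length(sensorSubset("all"), 7L)
  expect_setequal(sensorSubset("ub_plus_lh"),
                  c("head", "withers", "pelvis", "LH"))
})

test_that("every feature model separates two well-separated gaits", {
  cfg <- cohortConfig(c(icelandic = 3L), stridesPerTrial = 12L,
                      gaits = list(icelandic = c("walk", "trot")))
  ft <- featureTable(simulateCohort(cfg, seed = 4)$timelines)
  for (kind in c("lda", "qda", "tree", "forest", "svm", "fc")) {
    m <- trainFeatureModel(kind, ft, "all", seed = 1)
    expect_equal(mean(predictGait(m, ft) == ft$gait), 1,
                 info = kind)
    expect_true(all(predictGait(m, ft) %in% modelClasses(m)))
  }
})

test_that("feature-model training is deterministic given the seed", {
  cfg <- cohortConfig(c(icelandic = 2L), stridesPerTrial = 10L)
  ft <- featureTable(simulateCohort(cfg, seed = 4)$timelines)
  for (kind in c("forest", "fc")) {
    a <- predictGait(trainFeatureModel(kind, ft, "all", seed = 11), ft)
    b <- predictGait(trainFeatureModel(kind, ft, "all", seed = 11), ft)
    expect_identical(a, b, info = kind)
  }
})

test_that("hildebrand2 models consume exactly two input columns", {
  cfg <- cohortConfig(c(icelandic = 2L), stridesPerTrial = 8L)
  ft <- featureTable(simulateCohort(cfg, seed = 4)$timelines)
  m <- trainFeatureModel("lda", ft, "hildebrand2", seed = 1)
  expect_length(m@inputs, 2L)
  expect_error(predictGait(m, ft[, c("horse_id", "gait", "dap")]),
               "lacks feature column")
})

test_that("degenerate training tables are rejected", {
  cfg <- cohortConfig(c(franches_montagnes = 2L), stridesPerTrial = 6L,
                      gaits = list(franches_montagnes = "walk"))
  ft <- featureTable(simulateCohort(cfg, seed = 4)$timelines)
  expect_error(trainFeatureModel("lda", ft, "all", seed = 1),
               "single class")
  expect_error(trainFeatureModel("lda", ft[0, ], "all", seed = 1), "empty")
  expect_error(trainFeatureModel("lda", ft, c("duty_factor_mean", "nope"),
                                 seed = 1), "missing feature")
})

test_that("fc and lstm gradients match numerical differentiation", {
  withr::local_seed(99)
  ## fully connected network
  p <- 4L; H <- 5L; K <- 3L; n <- 7L
  X <- matrix(rnorm(n * p), n, p)
  Y <- matrix(FALSE, n, K)
  Y[cbind(seq_len(n), sample.int(K, n, TRUE))] <- TRUE
  par <- list(W1 = matrix(rnorm(p * H), p, H), b1 = rnorm(H),
              W2 = matrix(rnorm(H * K), H, K), b2 = rnorm(K))
  g <- equigait:::.fcGrad(par, X, Y)
  lossFC <- function(pp) equigait:::.ceLoss(equigait:::.fcForward(pp, X)$P, Y)
  for (nm in c("W1", "W2", "b1", "b2")) {
    for (idx in sample(length(par[[nm]]), min(4, length(par[[nm]])))) {
      up <- par; up[[nm]][idx] <- up[[nm]][idx] + 1e-6
      dn <- par; dn[[nm]][idx] <- dn[[nm]][idx] - 1e-6
      expect_equal(g[[nm]][idx], (lossFC(up) - lossFC(dn)) / 2e-6,
                   tolerance = 1e-4)
    }
  }
  ## stacked LSTM, both directions
  for (bid in c(FALSE, TRUE)) {
    B <- 3L; C <- 2L; T <- 4L; H <- 3L; K <- 2L
    lp <- equigait:::.lstmInitPar(C, H, 2L, bid, K)
    X <- array(rnorm(B * C * T), c(B, C, T))
    Y <- matrix(FALSE, B, K)
    Y[cbind(seq_len(B), sample.int(K, B, TRUE))] <- TRUE
    g <- equigait:::.lstmGrad(X, Y, lp)
    lossL <- function(pp)
      equigait:::.ceLoss(equigait:::.lstmForward(X, pp)$P, Y)
    for (l in 1:2) for (dir in names(lp$layers[[l]])) {
      W <- lp$layers[[l]][[dir]]$W
      for (idx in sample(length(W), 5)) {
        up <- lp; up$layers[[l]][[dir]]$W[idx] <- W[idx] + 1e-6
        dn <- lp; dn$layers[[l]][[dir]]$W[idx] <- W[idx] - 1e-6
        expect_equal(g$layers[[l]][[dir]]$W[idx],
                     (lossL(up) - lossL(dn)) / 2e-6, tolerance = 1e-4)
      }
    }
  }
})

test_that("the sequence model learns two acoustically distinct gaits", {
  p <- gaitPresets()
  mkwin <- function(gait, horse, seed) {
    h <- HorseProfile(horse, "icelandic", 1, 0.2)
    tl <- simulateTimeline(p[[gait]], h, 14, seed = seed)
    sb <- normalizeSignals(simulateSignals(tl, seed = seed + 7,
                                           noiseSd = 0.2))
    windowSignals(sb, 1, sensorSites())
  }
  wins <- c(mkwin("trot", "h1", 1), mkwin("walk", "h1", 2),
            mkwin("trot", "h2", 3), mkwin("walk", "h2", 4))
  m <- trainSequenceModel(wins, width = 12L, nLayers = 2L, epochs = 12L,
                          seed = 1)
  truth <- vapply(wins, function(w) w$gait, character(1))
  expect_equal(mean(predictGait(m, wins) == truth), 1)
  expect_true(all(predictGait(m, wins) %in% modelClasses(m)))
  expect_identical(predictGait(m, wins), predictGait(m, wins))
  ## determinism across refits
  m2 <- trainSequenceModel(wins, width = 12L, nLayers = 2L, epochs = 12L,
                           seed = 1)
  expect_identical(predictGait(m2, wins), predictGait(m, wins))
  ## empty input -> empty output
  expect_identical(predictGait(m, list()), character(0))
})

test_that("bidirectionality doubles the recurrent parameter count", {
  p <- gaitPresets()
  h <- HorseProfile("h1", "icelandic", 1, 0.2)
  tl1 <- simulateTimeline(p$trot, h, 6, seed = 1)
  tl2 <- simulateTimeline(p$walk, h, 6, seed = 2)
  wins <- c(windowSignals(normalizeSignals(simulateSignals(tl1, seed = 3)),
                          1, sensorSites()),
            windowSignals(normalizeSignals(simulateSignals(tl2, seed = 4)),
                          1, sensorSites()))
  uni <- trainSequenceModel(wins, width = 8L, epochs = 1L, seed = 1)
  bi <- trainSequenceModel(wins, width = 8L, epochs = 1L,
                           bidirectional = TRUE, seed = 1)
  ## the backward parameter set mirrors the forward one, but the second
  ## layer's input widens from H to 2H, so the ratio exceeds 2
  expect_gte(recurrentParamCount(bi), 2L * recurrentParamCount(uni))
  expect_error(trainSequenceModel(list()), "no training windows")
})
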