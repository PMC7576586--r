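test_that("grouped k-fold partitions horses exactly once", {
  counts <- c(a = 30, b = 28, c = 25, d = 31, e = 27,
              f = 29, g = 30, h = 26, i = 24, j = 32)
  plan <- groupedKFold(counts, k = 5, seed = 1)
  expect_length(plan$folds, 5L)
  expect_true(all(lengths(plan$folds) == 2L))
  all_ids <- unlist(plan$folds)
  expect_false(anyDuplicated(all_ids) > 0)
  expect_setequal(all_ids, names(counts))
  ## deterministic given seed
  expect_identical(plan$folds, groupedKFold(counts, k = 5, seed = 1)$folds)
  expect_error(groupedKFold(counts[1:3], k = 5, seed = 1), "at least 5")
})

test_that("the held-out test set never enters any fold", {
  counts <- setNames(rep(20, 10), letters[1:10])
  plan <- groupedKFold(counts, k = 5, seed = 2, testFraction = 0.2)
  expect_gt(length(plan$test), 0)
  expect_length(intersect(plan$test, unlist(plan$folds)), 0L)
  expect_setequal(c(plan$test, unlist(plan$folds)), letters[1:10])
})

test_that("fold stride counts are approximately balanced", {
  counts <- c(setNames(sample(c(150, 40, 90, 60, 120, 80, 70, 100,
                                50, 110)), letters[1:10]))
  plan <- groupedKFold(counts, k = 5, seed = 3)
  loads <- vapply(plan$folds, function(f) sum(counts[f]), numeric(1))
  expect_lt(max(loads) - min(loads), max(counts))
})

test_that("confusion matrices count and conserve correctly", {
  truth <- c("walk", "walk", "trot", "pace", "trot")
  pred <- c("walk", "trot", "trot", "pace", "trot")
  cm <- confusionTable(truth, pred, classes = c("pace", "trot", "walk"))
  expect_equal(sum(cm), length(truth))
  expect_equal(cm["walk", "trot"], 1L)
  expect_equal(accuracy(cm), 4 / 5)
  ## perfect predictions give a diagonal matrix
  cmP <- confusionTable(truth, truth)
  expect_equal(sum(cmP) - sum(diag(cmP)), 0L)
  expect_equal(accuracy(cmP), 1)
  expect_error(confusionTable(truth, pred, classes = c("walk", "trot")),
               "outside the class list")
  expect_error(confusionTable(truth, pred[-1]), "equal length")
})

test_that("no horse's strides cross a train/validation boundary", {
  cfg <- cohortConfig(c(icelandic = 5L), stridesPerTrial = 8L)
  ft <- featureTable(simulateCohort(cfg, seed = 6)$timelines)
  plan <- groupedKFold(table(ft$horse_id), k = 5, seed = 1)
  for (fold in plan$folds) {
    trainIds <- setdiff(plan$horses, fold)
    expect_length(intersect(trainIds, fold), 0L)
  }
  ## the run-time guard trips on any leaky split
  expect_error(equigait:::.assertDisjoint(c("a", "b"), c("b", "c")),
               "protocol violation")
})

test_that("cross-validating a separable cohort gives near-perfect folds", {
  cfg <- cohortConfig(c(icelandic = 5L), stridesPerTrial = 8L,
                      gaits = list(icelandic = c("walk", "trot")))
  ft <- featureTable(simulateCohort(cfg, seed = 6)$timelines)
  plan <- groupedKFold(table(ft$horse_id), k = 5, seed = 1)
  res <- crossValidate("lda", ft, plan, subset = "all", seed = 2)
  expect_length(foldAccuracies(res), 5L)
  expect_equal(meanAccuracy(res), 1)
  expect_equal(res@sdAccuracy, 0)
  ## pooled confusion conserves the stride count
  expect_equal(sum(confusionCounts(res)), nrow(ft))
})

test_that("pooled accuracy equals the stride-weighted mean of fold accuracies", {
  cfg <- cohortConfig(c(icelandic = 5L), stridesPerTrial = 8L)
  ft <- featureTable(simulateCohort(cfg, seed = 7)$timelines)
  plan <- groupedKFold(table(ft$horse_id), k = 5, seed = 2)
  res <- crossValidate("tree", ft, plan, subset = "hildebrand2", seed = 3)
  d <- res@detail
  expect_equal(accuracy(confusionCounts(res)),
               sum(d$accuracy * d$n) / sum(d$n), tolerance = 1e-12)
})

test_that("the experiment grid enumerates cells and honors exclusions", {
  cfg <- cohortConfig(c(icelandic = 5L), stridesPerTrial = 6L)
  ft <- featureTable(simulateCohort(cfg, seed = 8)$timelines)
  plan <- groupedKFold(table(ft$horse_id), k = 5, seed = 1)
  grid <- runExperimentGrid(ft, kinds = c("lda", "tree"),
                            subsets = c("all", "hildebrand2"),
                            plan = plan, seed = 4)
  expect_equal(nrow(grid$summary), 4L)
  expect_setequal(names(grid$results),
                  c("lda/all", "lda/hildebrand2", "tree/all",
                    "tree/hildebrand2"))
  ## rerun with the same master seed is identical
  grid2 <- runExperimentGrid(ft, kinds = c("lda", "tree"),
                             subsets = c("all", "hildebrand2"),
                             plan = plan, seed = 4)
  expect_identical(grid$summary, grid2$summary)
  expect_error(runExperimentGrid(ft, kinds = "lstm", plan = plan),
               "not a feature model kind")
  ## gait exclusion shrinks the confusion matrix to 7 classes
  ex <- crossValidate("lda", ft, plan, subset = "all", seed = 5,
                      excludeGaits = "pace")
  expect_equal(nrow(confusionCounts(ex)), 5L)  # icelandic has 6 gaits
  expect_false("pace" %in% rownames(confusionCounts(ex)))
})

test_that("cv summaries are internally consistent", {
  accs <- c(0.9, 0.95, 1, 0.85, 0.92)
  cm <- matrix(c(10L, 1L, 0L, 12L), 2, 2,
               dimnames = list(truth = c("a", "b"),
                               predicted = c("a", "b")))
  r <- equigait:::.mkCVResult(accs, rep(10L, 5), cm)
  expect_equal(meanAccuracy(r), mean(accs))
  expect_equal(r@sdAccuracy, sd(accs))
  expect_equal(accuracy(confusionCounts(r)), 22 / 23)
})
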