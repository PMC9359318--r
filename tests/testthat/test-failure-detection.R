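mkRecords <- function(predVar, correct, bin = "none") {
  data.frame(id = seq_along(predVar), predVar = predVar, correct = correct,
             bin = bin)
}

test_that("variance summaries report group medians and handle empty groups", {
  r <- mkRecords(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  s <- summarizeVariance(r)
  expect_equal(s$medianCorrect, 2)
  expect_true(is.na(s$medianIncorrect))   # absent, not 0
  expect_equal(s$medianCombined, 2)
  expect_equal(s$accuracy, 100)

  r2 <- mkRecords(c(0.1, 0.3, 0.9), c(TRUE, TRUE, FALSE))
  s2 <- summarizeVariance(r2)
  expect_equal(s2$medianCorrect, 0.2)
  expect_equal(s2$medianIncorrect, 0.9)
  expect_equal(s2$medianCombined, 0.3)

  ## permutation invariance
  perm <- r2[c(3, 1, 2), ]
  expect_equal(summarizeVariance(perm), s2)
  expect_error(summarizeVariance(r2, binOrder = c("none", "ghost")), "empty")
})

test_that("fixed-threshold selection reads only the minimum-noise bin", {
  s <- rbind(summarizeVariance(mkRecords(c(0.0008, 0.0008, 5), c(TRUE, TRUE, FALSE),
                                         "none")),
             summarizeVariance(mkRecords(c(9, 9, 9), c(TRUE, FALSE, TRUE),
                                         "high")))
  expect_equal(selectFixedThreshold(s, "correct-at-min-noise"), 0.0008)
  ## altering the high-noise bin leaves the selection unchanged
  s2 <- s; s2[2, 2:4] <- 1e6
  expect_equal(selectFixedThreshold(s2, "correct-at-min-noise"), 0.0008)
  expect_equal(selectFixedThreshold(s, "combined-at-min-noise"),
               s$medianCombined[1])
  expect_equal(selectFixedThreshold(s, "manual", manual = 0.5), 0.5)
  expect_error(selectFixedThreshold(s, "manual"), "value")
  expect_error(selectFixedThreshold(s, minBin = "ghost"), "bin")
})

test_that("fixed-threshold abstention reports enumerate correctly", {
  r <- mkRecords(c(0.1, 0.2, 0.9, 1.5), c(TRUE, FALSE, TRUE, FALSE))
  rep1 <- applyThreshold(r, 0.5)
  expect_equal(rep1$preAccuracy, 50)
  expect_equal(rep1$abstainedPct, 50)
  expect_equal(rep1$postAccuracy, 50)

  repInf <- applyThreshold(r, Inf)
  expect_equal(repInf$abstainedPct, 0)
  expect_equal(repInf$postAccuracy, repInf$preAccuracy)

  rep0 <- applyThreshold(r, 0)
  expect_equal(rep0$abstainedPct, 100)
  expect_true(is.na(rep0$postAccuracy))   # undefined, never 100

  ## ties are retained: a record exactly at tau keeps its decision
  expect_equal(applyThreshold(r, 0.2)$abstainedPct, 50)

  ## purity: identical inputs give identical reports
  expect_identical(applyThreshold(r, 0.5), applyThreshold(r, 0.5))
})

test_that("the abstained fraction is non-increasing in the threshold", {
  set.seed(30)
  r <- mkRecords(rexp(200), runif(200) > 0.3)
  taus <- sort(runif(10, 0, 3))
  fr <- vapply(taus, function(t) applyThreshold(r, t)$abstainedPct, numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("the learned threshold applies per-image cutoffs", {
  ## hand-built constant regressors via a zero-weight net with a bias
  constantRegressor <- function(value) {
    st <- vdpnet:::initLayerStack(vdpnet:::regressorLayers("fc", c(1, 4, 4)),
                                  c(1, 4, 4), 0, stochastic = FALSE)
    st$layers[[2]]$Wm[] <- 0; st$layers[[2]]$bm[] <- 0
    st$layers[[4]]$Wm[] <- 0; st$layers[[4]]$bm <- value
    new("ThresholdRegressor", net = st$layers,
        spec = unclass(thresholdRegressorSpec()),
        targetScale = list(center = 0, scale = 1),
        fitLog = data.frame())
  }
  set.seed(31)
  X <- matrix(runif(8 * 16), 8, 16)
  r <- mkRecords(runif(8, 0.01, 0.2), runif(8) > 0.4)
  high <- applyLearnedThreshold(r, X, constantRegressor(1e6))
  expect_equal(high$abstainedPct, 0)
  low <- applyLearnedThreshold(r, X, constantRegressor(0))
  expect_equal(low$abstainedPct, 100)
  expect_true(is.na(low$postAccuracy))
})

test_that("regressor training converges on its targets", {
  ## a quickly trained tiny VDP model supplies variance targets
  d <- generateDataset(syntheticSpec(nTrain = 150, nVal = 30, nTest = 30,
                                     seed = 12))
  net <- trainNetwork(buildNetwork(smallNetSpec(4L, seed = 12L)), d,
                      epochs = 2L, lr = 0.15, batchSize = 50L,
                      config = lossConfig(N = 150, H = 4, jitter = 0.25),
                      seed = 12L)
  spec <- thresholdRegressorSpec(epochs = 6L, lr = 0.05, seed = 3L)
  reg <- trainThresholdRegressor(net, d$train$images, noiseLevels = c(10, 4),
                                 spec = spec)
  lg <- reg@fitLog
  ## optimization makes progress over the first epochs
  expect_lt(lg$loss[6], lg$loss[1])
  tau <- predictThreshold(reg, d$test$images)
  expect_length(tau, 30)
  expect_true(all(tau >= 0))

  ## degenerate targets: all-equal variances warn and fit a constant
  zv <- net
  zv@layers <- vdpnet:::stackZeroVariance(zv@layers)
  expect_warning(trainThresholdRegressor(zv, d$train$images[1:20, , , ,
                                                            drop = FALSE],
                                         noiseLevels = 10,
                                         spec = thresholdRegressorSpec(
                                           epochs = 1L, seed = 1L)),
                 "degenerate")
})
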