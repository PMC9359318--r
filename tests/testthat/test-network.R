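test_that("network building is deterministic and the twin mirrors the means", {
  spec <- smallNetSpec(4L, seed = 5L)
  n1 <- buildNetwork(spec)
  n2 <- buildNetwork(spec)
  expect_identical(n1@layers[[1]]$Wm, n2@layers[[1]]$Wm)

  set.seed(99)
  X <- array(runif(3 * 784), c(3, 1, 28, 28))
  twin <- deterministicTwin(n1)
  pv <- predictBatch(n1, X)
  pt <- predictBatch(twin, X)
  ## twin forward equals the VDP mean forward bit-for-bit
  probCols <- grep("^prob\\.", names(pv))
  expect_identical(pv[probCols], pt[probCols])
  expect_true(all(pt$predVar == 0))
})

test_that("zero learning rate leaves parameters unchanged and lr > 0 moves them", {
  d <- generateDataset(syntheticSpec(nTrain = 40, nVal = 10, nTest = 10,
                                     seed = 2))
  spec <- smallNetSpec(4L, seed = 3L)
  net <- buildNetwork(spec)
  frozen <- trainNetwork(net, d, epochs = 1L, lr = 0, batchSize = 20L,
                         seed = 1L)
  expect_identical(frozen@layers[[1]]$Wm, net@layers[[1]]$Wm)
  expect_identical(frozen@layers[[8]]$Wlv, net@layers[[8]]$Wlv)
  moved <- trainNetwork(net, d, epochs = 1L, lr = 0.01, batchSize = 20L,
                        seed = 1L)
  expect_false(identical(moved@layers[[1]]$Wm, net@layers[[1]]$Wm))
})

test_that("training with a fixed seed reproduces the loss trajectory", {
  d <- generateDataset(syntheticSpec(nTrain = 60, nVal = 20, nTest = 10,
                                     seed = 7))
  spec <- smallNetSpec(4L, seed = 2L)
  a <- trainNetwork(buildNetwork(spec), d, epochs = 2L, lr = 0.05,
                    batchSize = 30L, seed = 9L)
  b <- trainNetwork(buildNetwork(spec), d, epochs = 2L, lr = 0.05,
                    batchSize = 30L, seed = 9L)
  expect_identical(trainLog(a), trainLog(b))
})

test_that("prediction records carry simplex means, argmax decisions and
           zero variance in the deterministic limit", {
  spec <- smallNetSpec(4L, seed = 8L)
  net <- buildNetwork(spec)
  set.seed(12)
  X <- array(runif(5 * 784), c(5, 1, 28, 28))
  rc <- predictBatch(net, X, labels = c(0, 1, 2, 3, 0))
  probCols <- grep("^prob\\.", names(rc))
  expect_equal(rowSums(rc[probCols]), rep(1, 5), tolerance = 1e-6)
  expect_equal(rc$decision, max.col(as.matrix(rc[probCols])) - 1L)
  expect_true(all(rc$predVar >= 0))
  expect_identical(rc$correct, rc$decision == rc$label)

  ## forcing all weight variances to zero makes every record's variance 0
  zv <- net
  zv@layers <- vdpnet:::stackZeroVariance(zv@layers)
  expect_true(all(predictBatch(zv, X)$predVar == 0))
})

test_that("accuracy-probability gap computes per-bin calibration error", {
  rec <- data.frame(bin = rep(c("a", "b"), each = 10),
                    maxProb = c(rep(0.8, 10), rep(1.0, 10)),
                    correct = c(rep(c(TRUE, TRUE, TRUE, TRUE, FALSE), 2),
                                rep(c(TRUE, TRUE, TRUE, FALSE, FALSE), 2)))
  g <- accuracyProbabilityGap(rec)
  expect_equal(g$gap[g$bin == "a"], 0, tolerance = 1e-9)      # calibrated
  expect_equal(g$gap[g$bin == "b"], 40, tolerance = 1e-9)     # overconfident
  expect_error(accuracyProbabilityGap(rec[0, ]), "empty")
})

test_that("checkpoints round-trip through JSON", {
  spec <- smallNetSpec(4L, seed = 4L)
  net <- buildNetwork(spec)
  path <- tempfile(fileext = ".json")
  saveCheckpoint(net, path)
  back <- loadCheckpoint(path)
  set.seed(3)
  X <- array(runif(2 * 784), c(2, 1, 28, 28))
  expect_equal(predictBatch(net, X), predictBatch(back, X), tolerance = 1e-12)
  expect_error(loadCheckpoint(tempfile()), "no checkpoint")
})

test_that("a residual block must preserve its channel count", {
  bad <- list(list(type = "conv", channels = 8L, kernel = 3L),
              list(type = "residual", channels = 16L),
              list(type = "flatten"),
              list(type = "fc", units = 4L))
  expect_error(buildNetwork(networkSpec(bad, numClasses = 4L)), "residual")
})

test_that("the synthetic benchmark trains to high validation accuracy with a
           comparable deterministic twin", {
  suite <- trainedSuite(1L)
  lg <- trainLog(suite$net)
  expect_gt(tail(lg$valAccuracy, 1), 0.85)   # 10 epochs, n = 2000
  clean <- suite$records[suite$records$bin == "none", ]
  cleanT <- suite$twinRecords[suite$twinRecords$bin == "none", ]
  expect_lte(abs(mean(clean$correct) - mean(cleanT$correct)), 0.05)
  ## noise raises the predictive variance of the Bayesian model
  high <- suite$records[suite$records$bin == "high", ]
  expect_gt(median(high$predVar), median(clean$predVar))
})

test_that("the Bayesian model is no less robust to noise than its twin
           (statistical, across seeds)", {
  drops <- vapply(benchmarkSeeds(), function(s) {
    suite <- trainedSuite(s)
    accs <- function(r) c(mean(r$correct[r$bin == "none"]),
                          mean(r$correct[r$bin == "high"]))
    v <- accs(suite$records); t <- accs(suite$twinRecords)
    c(vdp = v[1] - v[2], twin = t[1] - t[2])
  }, numeric(2))
  ## paired one-sided test: no evidence the VDP model degrades MORE than its
  ## twin from clean to high noise (the two are statistically tied here)
  p <- stats::t.test(drops["vdp", ], drops["twin", ], paired = TRUE,
                     alternative = "greater")$p.value
  expect_gt(p, 0.05)
})
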