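## Shared fixtures: toy reference networks for the moment-propagation checks
## and a cached set of trained models on the synthetic benchmark (training is
## the expensive step, so the acceptance tests and the module tests share one
## suite per seed).

.suiteCache <- new.env(parent = emptyenv())

benchmarkSeeds <- function() 1:5

smallNetSpec <- function(K = 4L, seed = 1L, inputShape = c(1L, 28L, 28L)) {
  networkSpec(architecturePreset("small", K), inputShape = inputShape,
              numClasses = K, seed = seed)
}

## Train VDP + twin on the default synthetic benchmark and evaluate the four
## Gaussian-noise bins; cached per seed for the whole test session.
trainedSuite <- function(seed) {
  key <- paste0("seed", seed)
  if (!is.null(.suiteCache[[key]])) return(.suiteCache[[key]])
  d <- generateDataset(syntheticSpec(seed = 4000L + seed))
  cfg <- lossConfig(N = d$spec$nTrain, H = d$spec$numClasses, jitter = 0.25)
  net <- trainNetwork(buildNetwork(smallNetSpec(4L, seed)), d, epochs = 10L,
                      lr = 0.15, batchSize = 50L, config = cfg, seed = seed)
  twin <- trainNetwork(deterministicTwin(buildNetwork(smallNetSpec(4L,
                                                                   seed + 500L))),
                       d, epochs = 10L, lr = 0.15, batchSize = 50L, seed = seed)
  bins <- defaultNoiseBins(seed = 900L + seed)
  recs <- NULL; recsT <- NULL
  for (b in bins) {
    Xb <- applyBin(b, d$test$images)
    recs <- rbind(recs, predictBatch(net, Xb, d$test$labels, bin = b$label))
    recsT <- rbind(recsT, predictBatch(twin, Xb, d$test$labels, bin = b$label))
  }
  out <- list(data = d, net = net, twin = twin, records = recs,
              twinRecords = recsT, binOrder = c("none", "low", "medium",
                                                "high"))
  .suiteCache[[key]] <- out
  out
}

## A small 2-conv(+pool)+fc+softmax reference network on an 8x8 input with
## parameter variances <= 1e-3 and pre-activation means far from ReLU kinks
## (positive weights on a positive image keep every pre-activation >= 3 sd
## above zero).
toyReferenceNet <- function(seed = 1L, maxVar = 1e-3) {
  set.seed(seed)
  x <- array(runif(64, 0.5, 1), c(1L, 8L, 8L))
  k1 <- randomParameter(array(runif(9 * 2, 0.1, 0.3), c(1, 3, 3, 2)),
                        array(runif(9 * 2, 0.1, 0.5) * maxVar, c(1, 3, 3, 2)),
                        "conv-kernel")
  k2 <- randomParameter(array(runif(4 * 2 * 2, 0.1, 0.3), c(2, 2, 2, 2)),
                        array(runif(4 * 2 * 2, 0.1, 0.5) * maxVar,
                              c(2, 2, 2, 2)), "conv-kernel")
  fcw <- randomParameter(matrix(runif(8 * 3, -0.15, 0.15), 8, 3),
                         matrix(runif(8 * 3, 0.05, 0.2) * maxVar, 8, 3),
                         "fc-weight")
  netSpec <- list(
    list(type = "conv", kernel = k1),                     # 8x8 -> 6x6, 2 ch
    list(type = "activation", f = "relu"),
    list(type = "pool", window = 2L),                     # -> 3x3
    list(type = "conv", kernel = k2),                     # -> 2x2, 2 ch
    list(type = "activation", f = "relu"),
    list(type = "flatten"),
    list(type = "fc", weights = fcw),
    list(type = "softmax"))
  list(netSpec = netSpec, x = x)
}

## Random positive semidefinite matrix.
randomPSD <- function(k) {
  A <- matrix(rnorm(k * k), k)
  crossprod(A) / k
}

relErr <- function(a, b) max(abs(a - b) / pmax(abs(b), 1e-12))
frobRelErr <- function(a, b) sqrt(sum((a - b)^2)) / sqrt(sum(b^2))
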