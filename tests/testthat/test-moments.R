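test_that("first-layer convolution propagates exact closed-form moments", {
  ## scalar case: z = x * w, Var = x^2 sigma^2
  k <- randomParameter(array(2, c(1, 1, 1)), array(0.5, c(1, 1, 1)),
                       "conv-kernel")
  a <- propagateConvFirst(matrix(3, 1, 1), k)
  expect_equal(actMean(a), 6, tolerance = 1e-12)
  expect_equal(actCovariance(a)[1, 1], 4.5, tolerance = 1e-12)

  ## zero kernel variance: deterministic convolution, zero covariance
  set.seed(3)
  x <- array(runif(36), c(1, 6, 6))
  km <- array(rnorm(9), c(1, 3, 3))
  k0 <- randomParameter(km, array(0, c(1, 3, 3)), "conv-kernel")
  a0 <- propagateConvFirst(x, k0)
  expect_true(all(actCovariance(a0) == 0))
  mc <- mcOracle(list(list(type = "conv", kernel = k0)), x, 2, seed = 1)
  expect_identical(actMean(a0), mc$mean)

  ## channel mismatch is a dimension error
  expect_error(propagateConvFirst(array(0.1, c(2, 4, 4)), k0), "channels")
})

test_that("first-layer convolution matches a Monte-Carlo oracle", {
  set.seed(7)
  x <- array(runif(36), c(1, 6, 6))
  k <- randomParameter(array(rnorm(9, sd = 0.3), c(1, 3, 3)),
                       array(runif(9, 0.001, 0.01), c(1, 3, 3)),
                       "conv-kernel")
  a <- propagateConvFirst(x, k, mode = "full")
  mc <- mcOracle(list(list(type = "conv", kernel = k)), x, 1e5, seed = 42)
  expect_lt(relErr(actMean(a), mc$mean), 0.01)
  expect_lt(frobRelErr(actCovariance(a), mc$cov), 0.05)
})

test_that("activation propagation implements the first-order Taylor rule", {
  a <- gaussianActivation(c(2, -3), c(0.01, 0.04))
  out <- propagateActivation(a, "relu")
  expect_equal(actMean(out), c(2, 0))
  expect_equal(actCovariance(out), c(0.01, 0))

  ## identity leaves the moments unchanged
  full <- gaussianActivation(c(1, -1), randomPSD(2))
  id <- propagateActivation(full, "identity")
  expect_identical(actMean(id), actMean(full))
  expect_identical(actCovariance(id), actCovariance(full))

  ## far from the kink the Taylor covariance is near-exact (vs Monte Carlo)
  set.seed(5)
  mu <- runif(4, 3, 5)
  S <- diag(runif(4, 0.1, 0.3))    # sd <= 0.55, means >= 3 sd from 0
  act <- gaussianActivation(mu, S,
                            layout = list(channels = 1, height = 2, width = 2))
  taylor <- propagateActivation(act, "relu")
  mc <- mcOracle(list(list(type = "activation", f = "relu")), act, 2e5,
                 seed = 9)
  expect_lt(frobRelErr(actCovariance(taylor), mc$cov), 0.02)
})

test_that("max-pooling selects mean argmax and co-pools the covariance", {
  a <- gaussianActivation(c(1, 5, 2, 4), c(0.1, 0.2, 0.3, 0.4),
                          layout = list(channels = 1, height = 1, width = 4))
  out <- propagateMaxPool(a, window = c(1, 2))
  expect_equal(actMean(out), c(5, 4))
  expect_equal(actCovariance(out), c(0.2, 0.4))

  ## ties resolve to the first (row-major) index
  tied <- gaussianActivation(rep(1, 4), c(0.1, 0.2, 0.3, 0.4),
                             layout = list(channels = 1, height = 2, width = 2))
  expect_equal(actCovariance(propagateMaxPool(tied, 2)), 0.1)

  ## zero covariance in, zero covariance out (full mode)
  z <- gaussianActivation(runif(16), matrix(0, 16, 16),
                          layout = list(channels = 1, height = 4, width = 4))
  expect_true(all(actCovariance(propagateMaxPool(z, 2)) == 0))

  ## window larger than the spatial extent
  expect_error(propagateMaxPool(tied, 3), "larger")
})

test_that("flattening concatenates means with block-diagonal covariance", {
  S1 <- randomPSD(2); S2 <- randomPSD(2)
  p1 <- gaussianActivation(c(1, 2), S1)
  p2 <- gaussianActivation(c(3, 4), S2)
  out <- propagateFlatten(list(p1, p2))
  expect_equal(actMean(out), 1:4)
  expect_identical(actCovariance(out)[1:2, 3:4], matrix(0, 2, 2))
  expect_equal(actCovariance(out)[1:2, 1:2], S1)
  expect_equal(actCovariance(out)[3:4, 3:4], S2)

  ## single part is an identity; diagonal mode concatenates variances
  expect_equal(actMean(propagateFlatten(p1)), c(1, 2))
  d1 <- gaussianActivation(c(1, 2), c(0.1, 0.2))
  d2 <- gaussianActivation(3, 0.3)
  expect_equal(actCovariance(propagateFlatten(list(d1, d2))), c(0.1, 0.2, 0.3))
  expect_error(propagateFlatten(list(p1, d1)), "mode")
})

test_that("fully-connected layer implements the product-of-Gaussians moments", {
  ## scalar: Var = sw2*sb2 + mw^2*sb2 + mb^2*sw2 = 0.5 + 4 + 4.5 = 9
  b <- gaussianActivation(3, matrix(1, 1, 1))
  w <- randomParameter(2, 0.5)
  out <- propagateFC(b, list(w))
  expect_equal(actMean(out), 6, tolerance = 1e-12)
  expect_equal(actCovariance(out)[1, 1], 9, tolerance = 1e-12)

  ## all variances zero: deterministic product
  b0 <- gaussianActivation(c(1, 2, 3), matrix(0, 3, 3))
  W <- randomParameter(matrix(c(1, 0, 1, 0, 1, 1), 3, 2),
                       matrix(0, 3, 2), "fc-weight")
  out0 <- propagateFC(b0, W)
  expect_equal(actMean(out0), c(4, 5))
  expect_true(all(actCovariance(out0) == 0))

  ## 3-unit input, 2 outputs vs Monte Carlo
  set.seed(21)
  bS <- randomPSD(3) * 0.1
  bin <- gaussianActivation(runif(3, 1, 2), bS,
                            layout = list(channels = 1, height = 1, width = 3))
  Wr <- randomParameter(matrix(rnorm(6, sd = 0.5), 3, 2),
                        matrix(runif(6, 0.01, 0.05), 3, 2), "fc-weight")
  out2 <- propagateFC(bin, Wr)
  mc <- mcOracle(list(list(type = "fc", weights = Wr)), bin, 1e5, seed = 3)
  expect_lt(relErr(actMean(out2), mc$mean), 0.01)
  expect_lt(frobRelErr(actCovariance(out2), mc$cov), 0.05)

  expect_error(propagateFC(b0, list(w)), "length")
})

test_that("intermediate convolution generalizes the fc moments", {
  ## deterministic reduction
  set.seed(2)
  aIn <- gaussianActivation(runif(9), matrix(0, 9, 9),
                            layout = list(channels = 1, height = 3, width = 3))
  k0 <- randomParameter(array(rnorm(4), c(1, 2, 2)), array(0, c(1, 2, 2)),
                        "conv-kernel")
  out <- propagateConvInner(aIn, k0)
  expect_true(all(actCovariance(out) == 0))

  ## 1x1 conv on a 1-pixel input reduces to the fc scalar case
  px <- gaussianActivation(3, matrix(1, 1, 1),
                           layout = list(channels = 1, height = 1, width = 1))
  k11 <- randomParameter(array(2, c(1, 1, 1)), array(0.5, c(1, 1, 1)),
                         "conv-kernel")
  o11 <- propagateConvInner(px, k11)
  expect_equal(actMean(o11), 6, tolerance = 1e-12)
  expect_equal(actCovariance(o11)[1, 1], 9, tolerance = 1e-12)

  ## random input and kernel vs Monte Carlo (both sampled)
  set.seed(31)
  S <- randomPSD(9) * 0.05
  aR <- gaussianActivation(runif(9, 0.5, 1.5), S,
                           layout = list(channels = 1, height = 3, width = 3))
  kR <- randomParameter(array(rnorm(4, sd = 0.4), c(1, 2, 2, 1)),
                        array(runif(4, 0.005, 0.02), c(1, 2, 2, 1)),
                        "conv-kernel")
  oR <- propagateConvInner(aR, kR)
  mc <- mcOracle(list(list(type = "conv", kernel = kR)), aR, 1e5, seed = 8)
  expect_lt(relErr(actMean(oR), mc$mean), 0.01)
  expect_lt(frobRelErr(actCovariance(oR), mc$cov), 0.05)
})

test_that("softmax propagation uses the Jacobian sandwich", {
  ## zero input covariance
  d0 <- gaussianActivation(c(1, 2, 0.5), matrix(0, 3, 3))
  o0 <- propagateSoftmax(d0)
  expect_equal(sum(actMean(o0)), 1, tolerance = 1e-12)
  expect_true(all(actCovariance(o0) == 0))

  ## symmetric two-class case: J = [[.25,-.25],[-.25,.25]], Sigma = J J'
  d <- gaussianActivation(c(0, 0), diag(2))
  o <- propagateSoftmax(d)
  expect_equal(actMean(o), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(actCovariance(o),
               matrix(c(0.125, -0.125, -0.125, 0.125), 2), tolerance = 1e-12)

  ## degeneracy: rows of J sum to zero, so 1' Sigma 1 = 0
  set.seed(13)
  for (r in 1:100) {
    k <- sample(2:6, 1)
    dd <- gaussianActivation(rnorm(k, sd = 2), randomPSD(k))
    S <- actCovariance(propagateSoftmax(dd))
    expect_lte(abs(sum(S)), 1e-8 * sum(diag(S)))
  }
})

test_that("batch normalization rescales moments through the diagonal map", {
  a <- gaussianActivation(4, matrix(2, 1, 1))
  o <- propagateBatchNorm(a, batchMean = 1, batchVar = 3, gamma = 2,
                          beta = 0.5, eps = 1)
  expect_equal(actMean(o), 3.5, tolerance = 1e-12)
  expect_equal(actCovariance(o)[1, 1], 2, tolerance = 1e-12)

  ## gamma = sqrt(var+eps), beta = mean: identity on the moments
  set.seed(4)
  x <- gaussianActivation(rnorm(5), randomPSD(5))
  bm <- rnorm(5); bv <- runif(5, 0.5, 2); eps <- 1e-3
  id <- propagateBatchNorm(x, bm, bv, gamma = sqrt(bv + eps), beta = bm,
                           eps = eps)
  expect_equal(actMean(id), actMean(x), tolerance = 1e-12)
  expect_equal(actCovariance(id), actCovariance(x), tolerance = 1e-12)

  ## zero input covariance stays zero; invalid batch variance errors
  z <- gaussianActivation(rnorm(3), rep(0, 3))
  expect_true(all(actCovariance(propagateBatchNorm(z, 0, 1, 1, 0)) == 0))
  expect_error(propagateBatchNorm(z, 0, -2, 1, 0, eps = 1), "positive")
})

test_that("residual connections propagate through the summed-map Jacobian", {
  ## F = 0: moments unchanged
  x <- gaussianActivation(c(1, -2), randomPSD(2))
  zeroBlock <- function(a) gaussianActivation(rep(0, 2), matrix(0, 2, 2))
  o <- propagateResidual(x, zeroBlock)
  expect_equal(actMean(o), actMean(x))
  expect_equal(actCovariance(o), actCovariance(x), tolerance = 1e-8)

  ## linear F(x) = A x: J = I + A; scalar A = 1, Var = 4 * 0.2
  s <- gaussianActivation(1.5, matrix(0.2, 1, 1))
  lin <- function(a) gaussianActivation(actMean(a), matrix(0, 1, 1))
  os <- propagateResidual(s, lin)
  expect_equal(actMean(os), 3, tolerance = 1e-6)
  expect_equal(actCovariance(os)[1, 1], 0.8, tolerance = 1e-6)

  ## small nonlinear residual branch vs Monte Carlo at small input variance:
  ## a tanh map is smooth, so the linearized covariance is near-exact
  set.seed(17)
  A <- matrix(rnorm(9, sd = 0.4), 3, 3)
  branch <- function(a) gaussianActivation(tanh(A %*% actMean(a)),
                                           matrix(0, 3, 3))
  xin <- gaussianActivation(runif(3), randomPSD(3) * 1e-3)
  o3 <- propagateResidual(xin, branch)
  set.seed(23)
  draws <- t(replicate(2e4, {
    ev <- eigen(actCovariance(xin), symmetric = TRUE)
    z <- actMean(xin) + ev$vectors %*% (sqrt(pmax(ev$values, 0)) * rnorm(3))
    as.vector(z + tanh(A %*% z))
  }))
  expect_lt(relErr(actMean(o3), colMeans(draws)), 0.01)
  expect_lt(frobRelErr(actCovariance(o3), stats::cov(draws)), 0.05)
})

test_that("the Monte-Carlo oracle is deterministic and consistent", {
  toy <- toyReferenceNet(seed = 2)
  a <- mcOracle(toy$netSpec, toy$x, 50, seed = 7)
  b <- mcOracle(toy$netSpec, toy$x, 50, seed = 7)
  expect_identical(a, b)
  expect_error(mcOracle(toy$netSpec, toy$x, 1), "nSamples")

  ## scalar fc closed form: empirical variance near 9
  bin <- gaussianActivation(3, matrix(1, 1, 1),
                            layout = list(channels = 1, height = 1, width = 1))
  net <- list(list(type = "fc", weights = list(randomParameter(2, 0.5))))
  mc <- mcOracle(net, bin, 2e5, seed = 2)
  expect_lt(abs(mc$cov[1, 1] - 9) / 9, 0.01)
})

test_that("full covariances stay positive semidefinite and diagonal mode is
           consistent on non-mixing transforms", {
  set.seed(19)
  for (r in 1:20) {
    k <- sample(3:6, 1)
    S <- randomPSD(k)
    a <- gaussianActivation(rnorm(k), S,
                            layout = list(channels = 1, height = 1, width = k))
    for (op in list(function(z) propagateActivation(z, "relu"),
                    function(z) propagateSoftmax(z),
                    function(z) propagateBatchNorm(z, 0, 1, 1.5, 0))) {
      out <- op(a)
      if (covarianceMode(out) == "full") {
        ev <- eigen(actCovariance(out), symmetric = TRUE, only.values = TRUE)
        expect_gte(min(ev$values), -1e-8 * max(ev$values, 1e-12))
      }
    }
    ## diagonal output equals the diagonal of the full output exactly
    adiag <- gaussianActivation(actMean(a), diag(S), layout = actLayout(a))
    expect_identical(actCovariance(propagateActivation(adiag, "relu")),
                     diag(actCovariance(propagateActivation(a, "relu"))))
    expect_identical(actCovariance(propagateBatchNorm(adiag, 0.2, 2, 1.3, 1)),
                     diag(actCovariance(propagateBatchNorm(a, 0.2, 2, 1.3, 1))))
  }
})
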