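#' Configuration of the evidence-lower-bound objective
#'
#' @param N dataset size (the number of training samples the likelihood sum
#'   runs over).
#' @param H number of output classes.
#' @param M number of Monte-Carlo draws for the expectation. The propagated
#'   output moments are deterministic per input, so the default analytic path
#'   uses \code{M = 1} with no sampling.
#' @param priorMean,priorVariance parameters of the isotropic Gaussian prior
#'   over every weight.
#' @param klWeight weight of the KL regularizer per mini-batch; defaults to
#'   \code{1/N} so that the full-dataset objective counts the KL once.
#' @param jitter variance floor added to the propagated output covariance
#'   before inversion/log-determinant.
#' @return list of class \code{lossConfig}.
#' @export
lossConfig <- function(N = 1L, H = 2L, M = 1L, priorMean = 0,
                       priorVariance = 1, klWeight = 1 / N, jitter = 1e-3) {
  stopifnot(N >= 1, H >= 1, M >= 1, priorVariance > 0, jitter > 0,
            klWeight > 0)
  structure(list(N = as.integer(N), H = as.integer(H), M = as.integer(M),
                 priorMean = priorMean, priorVariance = priorVariance,
                 klWeight = klWeight, jitter = jitter),
            class = "lossConfig")
}

#' Expected log-likelihood of one-hot targets under the predictive Gaussian
#'
#' Evaluates the Gaussian expected-log-likelihood term of the ELBO on a batch:
#' \deqn{-\frac{NH}{2}\log 2\pi - \frac{N}{B}\sum_{i=1}^{B}\left[
#'   \tfrac12\log|\Sigma_i| +
#'   \tfrac12 (y_i-\mu_i)^\top \Sigma_i^{-1} (y_i-\mu_i)\right],}
#' where B is the batch size, so a mini-batch estimates the full data sum by
#' \code{N/B} scaling. Covariances are floored by \code{config$jitter} on the
#' diagonal; if a Cholesky factorization still fails the sample falls back to
#' the covariance diagonal with a warning.
#'
#' @param targets one-hot target matrix (batch x H), or a vector for a single
#'   sample.
#' @param predMean predictive mean matrix (batch x H) or vector.
#' @param predCov predictive covariances: a list of H x H matrices (one per
#'   sample), a single H x H matrix (batch of one), or a batch x H matrix of
#'   diagonal variances.
#' @param config a \code{\link{lossConfig}}.
#' @return scalar expected log-likelihood.
#' @examples
#' cfg <- lossConfig(N = 1, H = 2, jitter = 1e-12)
#' expectedLogLik(c(1, 0), c(1, 0), diag(2), cfg)  # -log(2*pi)
#' @export
expectedLogLik <- function(targets, predMean, predCov, config) {
  stopifnot(inherits(config, "lossConfig"))
  if (is.vector(targets)) targets <- matrix(targets, nrow = 1L)
  if (is.vector(predMean)) predMean <- matrix(predMean, nrow = 1L)
  B <- nrow(targets)
  H <- ncol(targets)
  if (is.matrix(predCov) && nrow(predCov) == H && ncol(predCov) == H &&
      B == 1L) predCov <- list(predCov)
  if (!all(rowSums(targets) == 1) || any(targets < 0) || any(targets > 1))
    stop("targets must be valid one-hot vectors")
  perSample <- numeric(B)
  for (i in seq_len(B)) {
    e <- targets[i, ] - predMean[i, ]
    if (is.list(predCov)) {
      S <- predCov[[i]] + diag(config$jitter, H)
      ch <- tryCatch(chol(S), error = function(err) NULL)
      if (is.null(ch)) {
        warning("covariance not positive definite after jitter; ",
                "falling back to its diagonal (sample ", i, ")")
        d <- pmax(diag(S), config$jitter)
        perSample[i] <- sum(log(d)) / 2 + sum(e * e / d) / 2
      } else {
        logdet <- 2 * sum(log(diag(ch)))
        quad <- sum(backsolve(ch, e, transpose = TRUE)^2)
        perSample[i] <- logdet / 2 + quad / 2
      }
    } else {
      d <- predCov[i, ] + config$jitter
      if (any(d <= 0)) stop("non-positive variance after jitter")
      perSample[i] <- sum(log(d)) / 2 + sum(e * e / d) / 2
    }
  }
  -config$N * H / 2 * log(2 * pi) - config$N / B * sum(perSample)
}

#' KL divergence of the factorized Gaussian posterior from the prior
#'
#' Closed form, summed over all parameters:
#' \deqn{\sum \tfrac12\left( v/\sigma_p^2 + (m-\mu_p)^2/\sigma_p^2 - 1 +
#'   \log(\sigma_p^2/v) \right).}
#'
#' @param qMean numeric tensor of posterior means (any shape), or a
#'   \linkS4class{RandomParameter} (in which case \code{qVar} is ignored).
#' @param qVar strictly positive tensor of posterior variances.
#' @param config a \code{\link{lossConfig}} supplying the prior.
#' @return non-negative scalar; exactly 0 iff the posterior equals the prior.
#' @examples
#' klGaussianDiag(1, 1, lossConfig())  # 0.5
#' @export
klGaussianDiag <- function(qMean, qVar = NULL, config = lossConfig()) {
  if (is(qMean, "RandomParameter")) {
    qVar <- paramVariance(qMean)
    qMean <- paramMean(qMean)
  }
  stopifnot(inherits(config, "lossConfig"))
  if (any(qVar <= 0)) stop("posterior variances must be strictly positive")
  klClosedForm(qMean, qVar, config$priorMean, config$priorVariance)
}

#' The ELBO training objective (as a minimized loss)
#'
#' \code{-expectedLogLik + klWeight * KL}: the quantity gradient descent
#' minimizes when training a VDP model.
#'
#' @inheritParams expectedLogLik
#' @param params list of \linkS4class{RandomParameter}s (all variational
#'   parameters of the model), or a \linkS4class{VDPNetwork} whose parameters
#'   are used.
#' @return scalar loss.
#' @export
elboObjective <- function(targets, predMean, predCov, params, config) {
  kl <- if (is(params, "VDPNetwork")) {
    stackKL(params@layers, config$priorMean, config$priorVariance)
  } else {
    sum(vapply(params, function(p) klGaussianDiag(p, config = config),
               numeric(1)))
  }
  -expectedLogLik(targets, predMean, predCov, config) + config$klWeight * kl
}
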