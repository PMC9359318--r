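## Reference moment propagation: single-sample operations on
## GaussianActivation objects, with the full covariance as the reference
## representation and the diagonal as the scalable approximation. The training
## backend (layers-internal.R) reuses the diagonal formulas in batched form.

## Normalize a convolution kernel RandomParameter into flat weight matrices.
## Kernel mean arrays are (channels, k, k) for one output channel or
## (channels, k, k, outChannels); rows follow the patch order (channel-major,
## then kernel row, then kernel column).
kernelWeights <- function(kernel) {
  stopifnot(is(kernel, "RandomParameter"))
  m <- paramMean(kernel); v <- paramVariance(kernel)
  d <- dim(m)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stop("kernel mean must be a (channels, k, k[, outChannels]) array")
  if (d[2] != d[3]) stop("only square kernels are supported")
  kout <- if (length(d) == 4L) d[4] else 1L
  P <- prod(d[1:3])
  Mw <- matrix(0, P, kout); Vw <- matrix(0, P, kout)
  for (co in seq_len(kout)) {
    mk <- if (length(d) == 4L) m[, , , co, drop = FALSE] else m
    vk <- if (length(d) == 4L) v[, , , co, drop = FALSE] else v
    dim(mk) <- d[1:3]; dim(vk) <- d[1:3]
    Mw[, co] <- flattenImage(mk)
    Vw[, co] <- flattenImage(vk)
  }
  list(Mw = Mw, Vw = Vw, k = d[2], cin = d[1], cout = kout)
}

## Normalize fully-connected weights: a list of RandomParameter vectors (one
## per output) or a single RandomParameter with a D x S mean matrix.
fcWeights <- function(weights, D) {
  if (is(weights, "RandomParameter")) {
    Mw <- paramMean(weights); Vw <- paramVariance(weights)
    if (is.vector(Mw)) { Mw <- matrix(Mw, ncol = 1L); Vw <- matrix(Vw, ncol = 1L) }
  } else {
    Mw <- vapply(weights, paramMean, numeric(D))
    Vw <- vapply(weights, paramVariance, numeric(D))
    if (is.vector(Mw)) { Mw <- matrix(Mw, nrow = D); Vw <- matrix(Vw, nrow = D) }
  }
  if (nrow(Mw) != D)
    stop("weight vector length ", nrow(Mw), " does not match input length ", D)
  list(Mw = Mw, Vw = Vw)
}

activationLayout <- function(a) {
  if (!length(a@layout))
    stop("this operation needs a spatial layout on its input activation")
  a@layout
}

## ---------------------------------------------------------------------------

#' First-layer convolution of a deterministic input with a random kernel
#'
#' The input image is a constant; the kernel is Gaussian. Writing \eqn{\tilde X}
#' for the im2col matrix of the input (one row per output location), the
#' output moments are \eqn{\mu = \tilde X m} and
#' \eqn{\Sigma = \tilde X\,\mathrm{diag}(\sigma^2)\,\tilde X^\top} per output
#' channel; distinct output channels use independent kernels, so their
#' cross-covariance is exactly zero (block-diagonal).
#'
#' @param x deterministic input image: array \code{c(channels, height, width)}
#'   or a matrix (single channel).
#' @param kernel \linkS4class{RandomParameter} with a
#'   \code{(channels, k, k[, outChannels])} mean array.
#' @param stride,padding convolution geometry (zero padding, unit dilation,
#'   cross-correlation convention).
#' @param mode \code{"full"} or \code{"diagonal"}.
#' @return a \linkS4class{GaussianActivation} with layout
#'   \code{(outChannels, outHeight, outWidth)}.
#' @examples
#' k <- randomParameter(array(2, c(1, 1, 1)), array(0.5, c(1, 1, 1)),
#'                      "conv-kernel")
#' propagateConvFirst(matrix(3, 1, 1), k)  # mean 6, variance 4.5
#' @export
propagateConvFirst <- function(x, kernel, stride = 1L, padding = 0L,
                               mode = c("full", "diagonal")) {
  mode <- match.arg(mode)
  if (is.matrix(x)) x <- array(x, c(1L, nrow(x), ncol(x)))
  kw <- kernelWeights(kernel)
  if (dim(x)[1] != kw$cin)
    stop("input has ", dim(x)[1], " channels but kernel expects ", kw$cin)
  C <- dim(x)[1]; H <- dim(x)[2]; W <- dim(x)[3]
  ci <- buildConvIndex(C, H, W, kw$k, stride, padding)
  Xtil <- gatherPatches(matrix(flattenImage(x), nrow = 1L), ci$idx)
  mu <- as.vector(Xtil %*% kw$Mw)                      # (co-1)*nLoc + loc
  if (mode == "diagonal") {
    v <- as.vector((Xtil * Xtil) %*% kw$Vw)
    return(gaussianActivation(mu, v, "diagonal",
                              list(channels = kw$cout, height = ci$outHeight,
                                   width = ci$outWidth)))
  }
  blocks <- lapply(seq_len(kw$cout), function(co)
    Xtil %*% (kw$Vw[, co] * t(Xtil)))
  gaussianActivation(mu, blockDiag(blocks), "full",
                     list(channels = kw$cout, height = ci$outHeight,
                          width = ci$outWidth))
}

#' Elementwise nonlinearity by first-order Taylor expansion
#'
#' Mean: \eqn{f(\mu)}. Covariance:
#' \eqn{\Sigma \odot (\nabla f(\mu)\,\nabla f(\mu)^\top)} in full mode,
#' \eqn{\sigma^2 \odot \nabla f(\mu)^2} in diagonal mode.
#'
#' @param a a \linkS4class{GaussianActivation}.
#' @param f \code{"relu"}, \code{"identity"}, \code{"tanh"},
#'   \code{"sigmoid"}, or a list with elements \code{fun} and \code{grad}.
#' @return a \linkS4class{GaussianActivation} with the same layout and mode.
#' @export
propagateActivation <- function(a, f = "relu") {
  stopifnot(is(a, "GaussianActivation"))
  if (is.character(f)) {
    f <- switch(f,
      relu = list(fun = function(z) pmax(z, 0),
                  grad = function(z) as.numeric(z > 0)),
      identity = list(fun = identity, grad = function(z) rep(1, length(z))),
      tanh = list(fun = tanh, grad = function(z) 1 - tanh(z)^2),
      sigmoid = list(fun = function(z) 1 / (1 + exp(-z)),
                     grad = function(z) { s <- 1 / (1 + exp(-z)); s * (1 - s) }),
      stop("unknown activation: ", f))
  }
  mu <- f$fun(a@mean)
  g <- f$grad(a@mean)
  cov <- if (a@mode == "full") a@cov * outer(g, g) else a@cov * (g * g)
  gaussianActivation(mu, cov, a@mode, a@layout)
}

#' Max-pooling of the mean with covariance co-pooling
#'
#' The mean is max-pooled per channel; the covariance keeps the rows and
#' columns (diagonal entries, in diagonal mode) at the argmax indices of the
#' mean. Ties are broken by the first index in row-major window order.
#'
#' @param a a \linkS4class{GaussianActivation} with a spatial layout.
#' @param window pooling window size.
#' @param stride pooling stride (defaults to \code{window}).
#' @return a \linkS4class{GaussianActivation} with the pooled layout.
#' @export
propagateMaxPool <- function(a, window, stride = window) {
  stopifnot(is(a, "GaussianActivation"))
  lay <- activationLayout(a)
  pi <- buildPoolIndex(lay$channels, lay$height, lay$width, window, stride)
  G <- matrix(a@mean[as.vector(pi$idx)], nrow(pi$idx), ncol(pi$idx))
  sel <- pi$idx[cbind(seq_len(nrow(pi$idx)),
                      max.col(G, ties.method = "first"))]
  mu <- a@mean[sel]
  cov <- if (a@mode == "full") a@cov[sel, sel, drop = FALSE] else a@cov[sel]
  gaussianActivation(mu, cov, a@mode,
                     list(channels = lay$channels, height = pi$outHeight,
                          width = pi$outWidth))
}

#' Flattening: concatenate activations with block-diagonal covariance
#'
#' Cross-part covariances are exactly zero (independent kernels), so the full
#' covariance of the concatenation is block-diagonal; diagonal mode simply
#' concatenates the variance vectors.
#'
#' @param parts a list of \linkS4class{GaussianActivation}s in a consistent
#'   mode (a single activation is passed through, dropping its layout).
#' @return a flat \linkS4class{GaussianActivation}.
#' @export
propagateFlatten <- function(parts) {
  if (is(parts, "GaussianActivation")) parts <- list(parts)
  modes <- vapply(parts, covarianceMode, character(1))
  if (length(unique(modes)) != 1L)
    stop("all parts must share one covariance mode")
  mu <- unlist(lapply(parts, actMean))
  cov <- if (modes[1] == "full") blockDiag(lapply(parts, actCovariance))
         else unlist(lapply(parts, actCovariance))
  gaussianActivation(mu, cov, modes[1], list())
}

#' Fully-connected layer: product of two independent Gaussian vectors
#'
#' For output \eqn{d_i = w_i^\top b} with independent weight vectors
#' \eqn{w_i \sim N(m_i, \Sigma_i)} (diagonal \eqn{\Sigma_i}) and input
#' \eqn{b \sim N(\mu_b, \Sigma_b)}:
#' \deqn{\mu_{d_i} = m_i^\top \mu_b,\qquad
#'  \Sigma_{d_{ii}} = \mathrm{tr}(\Sigma_i\Sigma_b) + m_i^\top\Sigma_b m_i +
#'  \mu_b^\top \Sigma_i \mu_b,\qquad
#'  \Sigma_{d_{ij}} = m_i^\top \Sigma_b m_j \;(i\ne j).}
#'
#' @param b input \linkS4class{GaussianActivation}.
#' @param weights list of \linkS4class{RandomParameter} weight vectors (one
#'   per output), or one RandomParameter with a \code{D x S} mean matrix.
#' @param mode \code{"full"} or \code{"diagonal"} output representation.
#' @return a flat \linkS4class{GaussianActivation} of length S.
#' @examples
#' b <- gaussianActivation(3, matrix(1, 1, 1))
#' w <- randomParameter(2, 0.5)
#' actVariance(propagateFC(b, list(w)))  # 0.5*1 + 4*1 + 9*0.5 = 9
#' @export
propagateFC <- function(b, weights, mode = covarianceMode(b)) {
  stopifnot(is(b, "GaussianActivation"))
  D <- length(b@mean)
  fw <- fcWeights(weights, D)
  mu <- as.vector(crossprod(fw$Mw, b@mean))
  if (b@mode == "diagonal" || mode == "diagonal") {
    vb <- actVariance(b)
    v <- as.vector(crossprod(fw$Vw, vb + b@mean^2) +
                   crossprod(fw$Mw^2, vb))
    if (mode == "diagonal")
      return(gaussianActivation(mu, v, "diagonal", list()))
    ## full-mode output from a diagonal input
    S <- crossprod(fw$Mw, vb * fw$Mw)
    diag(S) <- v
    return(gaussianActivation(mu, S, "full", list()))
  }
  Sb <- b@cov
  S <- crossprod(fw$Mw, Sb %*% fw$Mw)
  diag(S) <- diag(S) + as.vector(crossprod(fw$Vw, diag(Sb) + b@mean^2))
  gaussianActivation(mu, S, "full", list())
}

#' Intermediate convolution: random kernel on a random input
#'
#' Per output location the im2col patch of the (Gaussian) input is multiplied
#' by the (Gaussian) kernel, the product-of-independent-Gaussian-vectors
#' moments of the fully-connected case applied patchwise. Outputs at
#' different spatial locations of one channel share the same kernel, so in
#' full mode their cross-covariance carries the shared-weight terms
#' \eqn{\mu_{b_l}^\top \Sigma_w \mu_{b_{l'}} +
#' \mathrm{tr}(\Sigma_w \Sigma_{b_{l'l}})} in addition to
#' \eqn{m^\top \Sigma_{b_{ll'}} m}; distinct channels are independent given
#' the input, leaving only the \eqn{m_c^\top \Sigma_{b_{ll'}} m_{c'}} term.
#' The diagonal entries coincide with the fully-connected formula.
#'
#' @param a input \linkS4class{GaussianActivation} with a spatial layout.
#' @inheritParams propagateConvFirst
#' @return a \linkS4class{GaussianActivation} with the convolved layout.
#' @export
propagateConvInner <- function(a, kernel, stride = 1L, padding = 0L,
                               mode = covarianceMode(a)) {
  stopifnot(is(a, "GaussianActivation"))
  lay <- activationLayout(a)
  kw <- kernelWeights(kernel)
  if (lay$channels != kw$cin)
    stop("input has ", lay$channels, " channels but kernel expects ", kw$cin)
  ci <- buildConvIndex(lay$channels, lay$height, lay$width, kw$k, stride,
                       padding)
  nLoc <- ci$nLoc
  muPad <- c(0, a@mean)
  Mu <- matrix(muPad[ci$idx], nLoc, ci$patchLen)    # patch means
  mu <- as.vector(Mu %*% kw$Mw)
  outLayout <- list(channels = kw$cout, height = ci$outHeight,
                    width = ci$outWidth)
  if (a@mode == "diagonal" || mode == "diagonal") {
    vPad <- c(0, actVariance(a))
    Vp <- matrix(vPad[ci$idx], nLoc, ci$patchLen)
    v <- as.vector(Vp %*% (kw$Vw + kw$Mw^2) + (Mu * Mu) %*% kw$Vw)
    if (mode == "diagonal")
      return(gaussianActivation(mu, v, "diagonal", outLayout))
    stop("full-mode output from a diagonal-mode input is not defined for ",
         "the intermediate convolution")
  }
  D <- length(a@mean)
  Spad <- matrix(0, D + 1L, D + 1L)
  Spad[-1L, -1L] <- a@cov
  ## Tr[l, l'] = sum_p vw[p] * Sigma_b(l, l')[p, p], per output channel
  cout <- kw$cout
  total <- cout * nLoc
  S <- matrix(0, total, total)
  ## U[[c]][l, j] = sum_p m_c[p] [idx(l,p) = j]: scatter of kernel means
  Ulist <- lapply(seq_len(cout), function(co) {
    U <- matrix(0, nLoc, D + 1L)
    for (p in seq_len(ci$patchLen)) {
      cells <- cbind(seq_len(nLoc), ci$idx[, p])
      U[cells] <- U[cells] + kw$Mw[p, co]
    }
    U
  })
  for (co in seq_len(cout)) {
    Uco <- Ulist[[co]]
    for (cp in co:cout) {
      Ucp <- Ulist[[cp]]
      blk <- Uco %*% Spad %*% t(Ucp)                 # m_c' Sigma_b m_c''
      if (cp == co) {
        vw <- kw$Vw[, co]
        blk <- blk + Mu %*% (vw * t(Mu))             # mu_b' Sigma_w mu_b
        Tr <- matrix(0, nLoc, nLoc)
        for (p in seq_len(ci$patchLen))
          Tr <- Tr + vw[p] * Spad[ci$idx[, p], ci$idx[, p]]
        blk <- blk + Tr                              # tr(Sigma_w Sigma_b)
      }
      ri <- (co - 1L) * nLoc + seq_len(nLoc)
      cj <- (cp - 1L) * nLoc + seq_len(nLoc)
      S[ri, cj] <- blk
      if (cp != co) S[cj, ri] <- t(blk)
    }
  }
  gaussianActivation(mu, S, "full", outLayout)
}

#' Softmax by first-order Taylor expansion
#'
#' Mean: \eqn{g(\mu_d)}. Covariance: \eqn{J \Sigma_d J^\top} with the softmax
#' Jacobian \eqn{J = \mathrm{diag}(g) - g g^\top} evaluated at the mean;
#' diagonal mode keeps the diagonal of \eqn{J \Sigma_d J^\top}. Because the
#' rows of J sum to zero, the full-mode output covariance is singular:
#' \eqn{1^\top \Sigma_{\tilde y} 1 = 0}.
#'
#' @param d pre-activation \linkS4class{GaussianActivation} (length K).
#' @return a \linkS4class{GaussianActivation} on the probability simplex.
#' @export
propagateSoftmax <- function(d) {
  stopifnot(is(d, "GaussianActivation"))
  z <- d@mean - max(d@mean)
  g <- exp(z) / sum(exp(z))
  J <- diag(g) - outer(g, g)
  if (d@mode == "full") {
    S <- J %*% d@cov %*% t(J)
    return(gaussianActivation(g, S, "full", list()))
  }
  v <- as.vector((J * J) %*% d@cov)   # sum_l J_kl^2 v_l
  gaussianActivation(g, v, "diagonal", list())
}

#' Batch normalization of Gaussian activations
#'
#' With scale \eqn{D = \mathrm{diag}(\gamma/\sqrt{\sigma_B^2+\epsilon})}:
#' mean \eqn{D(\mu_x - \mu_B) + \beta}, covariance \eqn{D \Sigma_x D}.
#' Batch statistics are supplied externally (mini-batch or running averages).
#'
#' @param x a \linkS4class{GaussianActivation}.
#' @param batchMean,batchVar per-feature batch statistics (recycled to the
#'   activation length).
#' @param gamma,beta scale and shift parameters.
#' @param eps numerical-stability constant.
#' @return a \linkS4class{GaussianActivation} with unchanged layout.
#' @examples
#' a <- gaussianActivation(4, matrix(2, 1, 1))
#' propagateBatchNorm(a, 1, 3, 2, 0.5, eps = 1)  # mean 3.5, variance 2
#' @export
propagateBatchNorm <- function(x, batchMean, batchVar, gamma, beta,
                               eps = 1e-5) {
  stopifnot(is(x, "GaussianActivation"))
  n <- length(x@mean)
  batchMean <- rep_len(batchMean, n); batchVar <- rep_len(batchVar, n)
  gamma <- rep_len(gamma, n); beta <- rep_len(beta, n)
  if (any(batchVar + eps <= 0))
    stop("batchVar + eps must be strictly positive")
  scale <- gamma / sqrt(batchVar + eps)
  mu <- scale * (x@mean - batchMean) + beta
  cov <- if (x@mode == "full") outer(scale, scale) * x@cov
         else scale * scale * x@cov
  gaussianActivation(mu, cov, x@mode, x@layout)
}

#' Residual (skip) connection
#'
#' Mean: \eqn{\mu + F(\mu)}. Covariance: \eqn{J \Sigma_x J^\top} where J is
#' the Jacobian of the summed map \eqn{x + F(x)} at the input mean, computed
#' by central finite differences of the block's mean map (step
#' \code{1e-5 * max(1, |mean|)} per coordinate).
#'
#' @param x input \linkS4class{GaussianActivation}.
#' @param block a function mapping a \code{GaussianActivation} to a
#'   \code{GaussianActivation} (the residual branch F); only its mean map is
#'   differentiated.
#' @param fdStep optional finite-difference step override.
#' @return a \linkS4class{GaussianActivation} with the input's layout.
#' @export
propagateResidual <- function(x, block, fdStep = NULL) {
  stopifnot(is(x, "GaussianActivation"))
  n <- length(x@mean)
  meanMap <- function(mu) {
    zero <- if (x@mode == "full") matrix(0, n, n) else numeric(n)
    out <- block(gaussianActivation(mu, zero, x@mode, x@layout))
    actMean(out)
  }
  Fmu <- meanMap(x@mean)
  if (length(Fmu) != n)
    stop("residual branch must preserve the activation length")
  mu <- x@mean + Fmu
  J <- diag(n)
  for (j in seq_len(n)) {
    h <- fdStep %||% (1e-5 * max(1, abs(x@mean[j])))
    ep <- x@mean; ep[j] <- ep[j] + h
    em <- x@mean; em[j] <- em[j] - h
    J[, j] <- J[, j] + (meanMap(ep) - meanMap(em)) / (2 * h)
  }
  cov <- if (x@mode == "full") J %*% x@cov %*% t(J)
         else as.vector((J * J) %*% x@cov)
  gaussianActivation(mu, cov, x@mode, x@layout)
}

## ---------------------------------------------------------------------------
## Whole-network reference propagation and the Monte-Carlo oracle.
## ---------------------------------------------------------------------------

#' Propagate moments through a toy network specification
#'
#' Runs the reference per-layer operations over a layer list. Each layer is a
#' list with a \code{type}: \code{"conv"} (\code{kernel} RandomParameter,
#' \code{stride}, \code{pad}), \code{"activation"} (\code{f}), \code{"pool"}
#' (\code{window}, \code{stride}), \code{"flatten"}, \code{"fc"}
#' (\code{weights}), \code{"batchnorm"} (\code{batchMean}, \code{batchVar},
#' \code{gamma}, \code{beta}, \code{eps}), \code{"softmax"}.
#'
#' @param netSpec list of layer descriptors.
#' @param x deterministic input image (array/matrix) or a
#'   \linkS4class{GaussianActivation}.
#' @param mode \code{"full"} or \code{"diagonal"}.
#' @return the output \linkS4class{GaussianActivation}.
#' @export
propagateNetwork <- function(netSpec, x, mode = c("full", "diagonal")) {
  mode <- match.arg(mode)
  a <- NULL
  for (ly in netSpec) {
    a <- switch(ly$type,
      conv = {
        if (is.null(a)) {
          if (is(x, "GaussianActivation"))
            propagateConvInner(x, ly$kernel, ly$stride %||% 1L,
                               ly$pad %||% 0L, mode)
          else
            propagateConvFirst(x, ly$kernel, ly$stride %||% 1L,
                               ly$pad %||% 0L, mode)
        } else {
          propagateConvInner(a, ly$kernel, ly$stride %||% 1L,
                             ly$pad %||% 0L, mode)
        }
      },
      activation = propagateActivation(a %||% stop("activation first?"),
                                       ly$f %||% "relu"),
      pool = propagateMaxPool(a, ly$window, ly$stride %||% ly$window),
      flatten = propagateFlatten(a),
      fc = propagateFC(a, ly$weights, mode),
      batchnorm = propagateBatchNorm(a, ly$batchMean, ly$batchVar, ly$gamma,
                                     ly$beta, ly$eps %||% 1e-5),
      softmax = propagateSoftmax(a),
      stop("unknown layer type: ", ly$type))
  }
  a
}

#' Monte-Carlo oracle for moment propagation
#'
#' Draws weight realizations from the variational distribution (and input
#' realizations when the input is a \code{GaussianActivation}), runs the
#' deterministic forward pass per draw, and returns the empirical mean and
#' covariance of the outputs. Used as an independent check of the analytic
#' propagation; it never replaces it.
#'
#' @inheritParams propagateNetwork
#' @param nSamples number of draws (>= 2).
#' @param seed integer seed; identical seeds give identical outputs.
#' @return list with \code{mean} (vector) and \code{cov} (matrix).
#' @export
mcOracle <- function(netSpec, x, nSamples, seed = 1L) {
  if (nSamples < 2) stop("nSamples must be >= 2")
  set.seed(seed)
  randomInput <- is(x, "GaussianActivation")
  if (randomInput) {
    lay <- activationLayout(x)
    inC <- lay$channels; inH <- lay$height; inW <- lay$width
    muIn <- x@mean
    if (x@mode == "full") {
      ev <- eigen(symmetrizeCov(x@cov), symmetric = TRUE)
      rootIn <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
    } else rootIn <- NULL
  } else {
    if (is.matrix(x)) x <- array(x, c(1L, nrow(x), ncol(x)))
    inC <- dim(x)[1]; inH <- dim(x)[2]; inW <- dim(x)[3]
    xFlat <- flattenImage(x)
  }
  ## Precompute geometry by tracking shapes once.
  geom <- list(); C <- inC; H <- inH; W <- inW
  for (i in seq_along(netSpec)) {
    ly <- netSpec[[i]]
    if (ly$type == "conv") {
      kw <- kernelWeights(ly$kernel)
      ci <- buildConvIndex(C, H, W, kw$k, ly$stride %||% 1L, ly$pad %||% 0L)
      geom[[i]] <- list(kw = kw, ci = ci)
      C <- kw$cout; H <- ci$outHeight; W <- ci$outWidth
    } else if (ly$type == "pool") {
      pi <- buildPoolIndex(C, H, W, ly$window, ly$stride %||% ly$window)
      geom[[i]] <- list(pi = pi)
      H <- pi$outHeight; W <- pi$outWidth
    } else if (ly$type == "fc") {
      fw <- fcWeights(ly$weights, C * H * W)
      geom[[i]] <- list(fw = fw, din = C * H * W)
      C <- 1L; H <- 1L; W <- ncol(fw$Mw)
    } else geom[[i]] <- list()
  }
  outLen <- C * H * W
  acc <- matrix(0, nSamples, outLen)
  for (s in seq_len(nSamples)) {
    a <- if (randomInput) {
      if (is.null(rootIn)) muIn + rnorm(length(muIn)) * sqrt(pmax(x@cov, 0))
      else muIn + as.vector(rootIn %*% rnorm(length(muIn)))
    } else xFlat
    for (i in seq_along(netSpec)) {
      ly <- netSpec[[i]]; ge <- geom[[i]]
      if (ly$type == "conv") {
        Wd <- ge$kw$Mw + matrix(rnorm(length(ge$kw$Mw)), nrow(ge$kw$Mw)) *
          sqrt(ge$kw$Vw)
        Pm <- matrix(c(0, a)[ge$ci$idx], ge$ci$nLoc, ge$ci$patchLen)
        a <- as.vector(Pm %*% Wd)
      } else if (ly$type == "activation") {
        a <- switch(if (is.character(ly$f %||% "relu")) ly$f %||% "relu"
                    else "custom",
          relu = pmax(a, 0), identity = a, tanh = tanh(a),
          sigmoid = 1 / (1 + exp(-a)), custom = ly$f$fun(a))
      } else if (ly$type == "pool") {
        G <- matrix(a[as.vector(ge$pi$idx)], nrow(ge$pi$idx), ncol(ge$pi$idx))
        sel <- ge$pi$idx[cbind(seq_len(nrow(ge$pi$idx)),
                               max.col(G, ties.method = "first"))]
        a <- a[sel]
      } else if (ly$type == "fc") {
        Wd <- ge$fw$Mw + matrix(rnorm(length(ge$fw$Mw)), nrow(ge$fw$Mw)) *
          sqrt(ge$fw$Vw)
        a <- as.vector(crossprod(Wd, a))
      } else if (ly$type == "batchnorm") {
        scale <- rep_len(ly$gamma, length(a)) /
          sqrt(rep_len(ly$batchVar, length(a)) + (ly$eps %||% 1e-5))
        a <- scale * (a - rep_len(ly$batchMean, length(a))) +
          rep_len(ly$beta, length(a))
      } else if (ly$type == "softmax") {
        z <- a - max(a); a <- exp(z) / sum(exp(z))
      } else if (ly$type == "flatten") {
        ## no-op on the flat vector
      }
    }
    acc[s, ] <- a
  }
  list(mean = colMeans(acc), cov = stats::cov(acc))
}
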