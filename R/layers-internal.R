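## Internal trainable layer stack: batched diagonal-mode moment propagation
## with hand-derived reverse-mode gradients. The user-facing reference
## implementation of the per-layer moment algebra (full covariance, single
## sample) lives in the propagate*() functions; this file is the scalable
## training backend that shares the same diagonal formulas.
##
## State convention: a batch flows as (M, V) where M is the n x D matrix of
## activation means and V the matching matrix of diagonal variances. V = NULL
## encodes an exactly-zero variance (deterministic signal), so the first
## convolution layer treats its input as a constant, and the deterministic
## twin runs the whole stack with V = NULL.

addBias <- function(M, b) M + rep(b, each = nrow(M))

## ---- initialization ---------------------------------------------------------

initLayerStack <- function(layerSpecs, inShape, initLogVar, stochastic = TRUE) {
  C <- inShape[1L]; H <- inShape[2L]; W <- inShape[3L]
  layers <- list()
  for (ls in layerSpecs) {
    ly <- switch(ls$type,
      conv = {
        k <- ls$kernel %||% 3L
        stride <- ls$stride %||% 1L
        pad <- ls$pad %||% ((k - 1L) %/% 2L)
        ci <- buildConvIndex(C, H, W, k, stride, pad)
        P <- ci$patchLen
        cout <- ls$channels
        l <- list(type = "conv", k = k, stride = stride, pad = pad,
                  cin = C, cout = cout, inH = H, inW = W,
                  outH = ci$outHeight, outW = ci$outWidth,
                  din = C * H * W, ci = ci,
                  Wm = matrix(rnorm(P * cout, sd = sqrt(2 / P)), P, cout),
                  bm = numeric(cout))
        if (stochastic) {
          l$Wlv <- matrix(initLogVar, P, cout)
          l$blv <- rep(initLogVar, cout)
        }
        C <- cout; H <- ci$outHeight; W <- ci$outWidth
        l
      },
      relu = list(type = "relu"),
      pool = {
        win <- ls$window %||% 2L
        stride <- ls$stride %||% win
        pi <- buildPoolIndex(C, H, W, win, stride)
        pi$idxFlat <- as.vector(pi$idx)
        l <- list(type = "pool", window = win, stride = stride, channels = C,
                  nonOverlap = stride >= win,
                  inH = H, inW = W, outH = pi$outHeight, outW = pi$outWidth,
                  din = C * H * W, pi = pi)
        H <- pi$outHeight; W <- pi$outWidth
        l
      },
      flatten = list(type = "flatten"),
      fc = {
        din <- C * H * W
        dout <- ls$units
        l <- list(type = "fc", din = din, dout = dout,
                  Wm = matrix(rnorm(din * dout, sd = sqrt(2 / din)), din, dout),
                  bm = numeric(dout))
        if (stochastic) {
          l$Wlv <- matrix(initLogVar, din, dout)
          l$blv <- rep(initLogVar, dout)
        }
        C <- 1L; H <- 1L; W <- dout
        l
      },
      residual = {
        ch <- ls$channels %||% C
        if (ch != C)
          stop("residual block must preserve the channel count (in ", C,
               ", requested ", ch, ")")
        k <- ls$kernel %||% 3L
        inner <- list(list(type = "conv", channels = ch, kernel = k),
                      list(type = "relu"),
                      list(type = "conv", channels = ch, kernel = k))
        blk <- initLayerStack(inner, c(C, H, W), initLogVar, stochastic)
        list(type = "residual", block = blk$layers, din = C * H * W)
      },
      stop("unknown layer type: ", ls$type))
    layers[[length(layers) + 1L]] <- ly
  }
  list(layers = layers, outShape = c(C, H, W))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- forward ---------------------------------------------------------------

## Returns list(M, V, caches). stochastic = FALSE ignores the variance
## parameters entirely (deterministic twin / mean path).
stackForward <- function(layers, M, V = NULL, stochastic = TRUE,
                         keepCache = FALSE) {
  caches <- if (keepCache) vector("list", length(layers)) else NULL
  n <- nrow(M)
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      Pm <- gatherPatches(M, ly$ci$idx, ly$ci$idxFlat)
      Om <- addBias(Pm %*% ly$Wm, ly$bm)
      Pv <- NULL; Ov <- NULL
      if (stochastic) {
        Wv <- exp(ly$Wlv)
        if (is.null(V)) {
          Ov <- (Pm * Pm) %*% Wv
        } else {
          Pv <- gatherPatches(V, ly$ci$idx, ly$ci$idxFlat)
          Ov <- Pv %*% (Wv + ly$Wm^2) + (Pm * Pm) %*% Wv
        }
        Ov <- addBias(Ov, exp(ly$blv))
      }
      if (keepCache) caches[[i]] <- list(Pm = Pm, Pv = Pv, hadV = !is.null(V))
      M <- convOutToBatch(Om, n)
      V <- if (stochastic) convOutToBatch(Ov, n) else NULL
    } else if (ly$type == "relu") {
      mask <- M > 0
      if (keepCache) caches[[i]] <- list(mask = mask)
      M <- M * mask
      if (!is.null(V)) V <- V * mask
    } else if (ly$type == "pool") {
      idx <- ly$pi$idx
      Q <- nrow(idx)
      G <- M[, ly$pi$idxFlat, drop = FALSE]
      dim(G) <- c(n * Q, ncol(idx))
      amax <- max.col(G, ties.method = "first")
      qv <- rep(seq_len(Q), each = n)
      iv <- rep(seq_len(n), times = Q)
      chosen <- idx[(amax - 1L) * Q + qv]
      lin <- (chosen - 1L) * n + iv
      if (keepCache) caches[[i]] <- list(lin = lin, din = ly$din,
                                         nonOverlap = ly$nonOverlap)
      Mn <- M[lin]; dim(Mn) <- c(n, Q)
      if (!is.null(V)) { Vn <- V[lin]; dim(Vn) <- c(n, Q); V <- Vn }
      M <- Mn
    } else if (ly$type == "flatten") {
      ## batch state is already flat in canonical order; layout bookkeeping only
    } else if (ly$type == "fc") {
      Min <- M; Vin <- V
      Om <- addBias(M %*% ly$Wm, ly$bm)
      if (stochastic) {
        Wv <- exp(ly$Wlv)
        Ov <- if (is.null(V)) (M * M) %*% Wv
              else V %*% (Wv + ly$Wm^2) + (M * M) %*% Wv
        Ov <- addBias(Ov, exp(ly$blv))
        V <- Ov
      } else V <- NULL
      if (keepCache) caches[[i]] <- list(Min = Min, Vin = Vin)
      M <- Om
    } else if (ly$type == "residual") {
      sub <- stackForward(ly$block, M, V, stochastic, keepCache)
      if (keepCache) caches[[i]] <- list(sub = sub$caches)
      ## skip connection: means add; branch variances add (branches treated as
      ## uncorrelated -- the diagonal-mode approximation, see vignette)
      Mout <- M + sub$M
      V <- if (is.null(V)) sub$V else if (is.null(sub$V)) V else V + sub$V
      M <- Mout
    }
  }
  list(M = M, V = V, caches = caches)
}

## ---- backward --------------------------------------------------------------

## dM, dV: gradients of the scalar loss w.r.t. the stack output moments.
## Returns list(dM, dV, grads) where grads mirrors the layer list.
stackBackward <- function(layers, caches, dM, dV = NULL, stochastic = TRUE,
                          needInputGrad = FALSE) {
  n <- nrow(dM)
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]; ca <- caches[[i]]
    if (ly$type == "conv") {
      nLoc <- ly$ci$nLoc
      dOm <- batchToConvOut(dM, n, nLoc, ly$cout)
      g <- list(Wm = crossprod(ca$Pm, dOm), bm = colSums(dOm))
      dPm <- dOm %*% t(ly$Wm)
      dPv <- NULL
      if (stochastic && !is.null(dV)) {
        Wv <- exp(ly$Wlv)
        dOv <- batchToConvOut(dV, n, nLoc, ly$cout)
        gWvRaw <- crossprod(ca$Pm * ca$Pm, dOv)
        if (ca$hadV) {
          gWvRaw <- gWvRaw + crossprod(ca$Pv, dOv)
          g$Wm <- g$Wm + 2 * ly$Wm * crossprod(ca$Pv, dOv)
          dPv <- dOv %*% t(Wv + ly$Wm^2)
        }
        g$Wlv <- gWvRaw * Wv
        g$blv <- colSums(dOv) * exp(ly$blv)
        dPm <- dPm + 2 * ca$Pm * (dOv %*% t(Wv))
      }
      grads[[i]] <- g
      lowest <- i == 1L && !needInputGrad
      if (!lowest) {
        dM <- scatterPatches(dPm, ly$ci$idx, n, ly$din)
        dV <- if (!is.null(dPv)) scatterPatches(dPv, ly$ci$idx, n, ly$din) else NULL
      } else { dM <- NULL; dV <- NULL }
    } else if (ly$type == "relu") {
      dM <- dM * ca$mask
      if (!is.null(dV)) dV <- dV * ca$mask
    } else if (ly$type == "pool") {
      dM <- poolScatter(dM, ca$lin, n, ca$din, ca$nonOverlap)
      if (!is.null(dV)) dV <- poolScatter(dV, ca$lin, n, ca$din, ca$nonOverlap)
    } else if (ly$type == "flatten") {
      ## no-op
    } else if (ly$type == "fc") {
      g <- list(Wm = crossprod(ca$Min, dM), bm = colSums(dM))
      dMin <- dM %*% t(ly$Wm)
      dVin <- NULL
      if (stochastic && !is.null(dV)) {
        Wv <- exp(ly$Wlv)
        gWvRaw <- crossprod(ca$Min * ca$Min, dV)
        if (!is.null(ca$Vin)) {
          gWvRaw <- gWvRaw + crossprod(ca$Vin, dV)
          g$Wm <- g$Wm + 2 * ly$Wm * crossprod(ca$Vin, dV)
          dVin <- dV %*% t(Wv + ly$Wm^2)
        }
        g$Wlv <- gWvRaw * Wv
        g$blv <- colSums(dV) * exp(ly$blv)
        dMin <- dMin + 2 * ca$Min * (dV %*% t(Wv))
      }
      grads[[i]] <- g
      dM <- dMin; dV <- dVin
    } else if (ly$type == "residual") {
      sub <- stackBackward(ly$block, ca$sub, dM, dV, stochastic,
                           needInputGrad = TRUE)
      grads[[i]] <- list(block = sub$grads)
      dM <- dM + sub$dM
      if (!is.null(dV)) dV <- if (is.null(sub$dV)) dV else dV + sub$dV
      else dV <- sub$dV
    }
  }
  list(dM = dM, dV = dV, grads = grads)
}

poolScatter <- function(dOut, lin, n, din, nonOverlap = TRUE) {
  dIn <- numeric(n * din)
  if (nonOverlap) {
    ## non-overlapping windows: each input cell feeds at most one window,
    ## so the argmax positions are unique per sample and plain assignment works
    dIn[lin] <- dOut
  } else {
    agg <- rowsum(as.vector(dOut), lin, reorder = FALSE)
    dIn[as.integer(rownames(agg))] <- agg
  }
  dim(dIn) <- c(n, din)
  dIn
}

## ---- parameter traversal ----------------------------------------------------

## Apply an SGD step: layers <- layers - lr * (lossGrads + klWeight * klGrads).
## KL gradients are computed in closed form against the N(priorMean, priorVar)
## prior: d/dm = (m - m0)/v0, d/dlogv = (v/v0 - 1)/2.
sgdUpdate <- function(layers, grads, lr, klWeight = 0, priorMean = 0,
                      priorVar = 1, stochastic = TRUE) {
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type %in% c("conv", "fc")) {
      g <- grads[[i]]
      gm <- g$Wm; gb <- g$bm
      if (stochastic && klWeight > 0) {
        gm <- gm + klWeight * (ly$Wm - priorMean) / priorVar
        gb <- gb + klWeight * (ly$bm - priorMean) / priorVar
      }
      ly$Wm <- ly$Wm - lr * gm
      ly$bm <- ly$bm - lr * gb
      if (stochastic && !is.null(g$Wlv)) {
        glv <- g$Wlv; gblv <- g$blv
        if (klWeight > 0) {
          glv <- glv + klWeight * (exp(ly$Wlv) / priorVar - 1) / 2
          gblv <- gblv + klWeight * (exp(ly$blv) / priorVar - 1) / 2
        }
        ly$Wlv <- ly$Wlv - lr * glv
        ly$blv <- ly$blv - lr * gblv
      }
    } else if (ly$type == "residual") {
      ly$block <- sgdUpdate(ly$block, grads[[i]]$block, lr, klWeight,
                            priorMean, priorVar, stochastic)
    }
    layers[[i]] <- ly
  }
  layers
}

## Closed-form KL of the whole stack's variational posterior vs the prior.
stackKL <- function(layers, priorMean = 0, priorVar = 1) {
  total <- 0
  for (ly in layers) {
    if (ly$type %in% c("conv", "fc")) {
      if (is.null(ly$Wlv)) next
      total <- total +
        klClosedForm(ly$Wm, exp(ly$Wlv), priorMean, priorVar) +
        klClosedForm(ly$bm, exp(ly$blv), priorMean, priorVar)
    } else if (ly$type == "residual") {
      total <- total + stackKL(ly$block, priorMean, priorVar)
    }
  }
  total
}

klClosedForm <- function(m, v, m0, v0) {
  sum((v / v0 + (m - m0)^2 / v0 - 1 + log(v0 / v)) / 2)
}

## Extract/overwrite all parameter means (used by the deterministic twin and
## the zero-variance limit).
stackMeans <- function(layers) {
  lapply(layers, function(ly) {
    if (ly$type %in% c("conv", "fc")) list(Wm = ly$Wm, bm = ly$bm)
    else if (ly$type == "residual") list(block = stackMeans(ly$block))
    else NULL
  })
}

stackSetMeans <- function(layers, means) {
  for (i in seq_along(layers)) {
    if (layers[[i]]$type %in% c("conv", "fc")) {
      layers[[i]]$Wm <- means[[i]]$Wm
      layers[[i]]$bm <- means[[i]]$bm
    } else if (layers[[i]]$type == "residual") {
      layers[[i]]$block <- stackSetMeans(layers[[i]]$block, means[[i]]$block)
    }
  }
  layers
}

## Force all variational variances to (numerically exact) zero by dropping the
## variance parameters; stochastic forward then yields zero covariance.
stackZeroVariance <- function(layers) {
  for (i in seq_along(layers)) {
    if (layers[[i]]$type %in% c("conv", "fc")) {
      layers[[i]]$Wlv <- matrix(-Inf, nrow(layers[[i]]$Wm), ncol(layers[[i]]$Wm))
      layers[[i]]$blv <- rep(-Inf, length(layers[[i]]$bm))
    } else if (layers[[i]]$type == "residual") {
      layers[[i]]$block <- stackZeroVariance(layers[[i]]$block)
    }
  }
  layers
}

## Global L2 norm of a gradient structure, and rescaling for norm clipping.
gradsSumSq <- function(grads) {
  total <- 0
  for (g in grads) {
    if (is.null(g)) next
    if (!is.null(g$block)) total <- total + gradsSumSq(g$block)
    else for (part in g) total <- total + sum(part * part)
  }
  total
}

gradsScale <- function(grads, s) {
  for (i in seq_along(grads)) {
    g <- grads[[i]]
    if (is.null(g)) next
    if (!is.null(g$block)) grads[[i]]$block <- gradsScale(g$block, s)
    else grads[[i]] <- lapply(g, function(part) part * s)
  }
  grads
}

clipGrads <- function(grads, maxNorm) {
  if (!is.finite(maxNorm) || maxNorm <= 0) return(grads)
  nrm <- sqrt(gradsSumSq(grads))
  if (nrm > maxNorm) grads <- gradsScale(grads, maxNorm / nrm)
  grads
}

## ---- loss heads -------------------------------------------------------------

## Diagonal-covariance Gaussian negative log-likelihood of one-hot targets
## against the softmax-propagated output moments (the per-sample core of the
## expected log-likelihood), with exact gradients w.r.t. the pre-softmax
## moments (Md, Vd). Returns the batch MEAN loss and matching gradients.
vdpNllGrad <- function(Md, Vd, Y, jitter = 1e-3) {
  n <- nrow(Md)
  G <- rowSoftmax(Md)
  sg2v <- rowSums(G * G * Vd)                 # sum_l g_l^2 v_l, per sample
  Q <- sg2v + Vd * (1 - 2 * G)                # q_k >= 0
  S <- G * G * Q + jitter                     # propagated softmax variances + floor
  E <- Y - G
  nll <- rowSums(log(S) + E * E / S) / 2
  loss <- mean(nll)
  Tm <- (1 / S - E * E / (S * S)) / (2 * n)   # dLoss/dS
  sTg2 <- rowSums(Tm * G * G)                 # sum_k t_k g_k^2
  dVd <- G * G * (Tm * (1 - 2 * G) + sTg2)
  ## dL/dg: error term contributes -e/s (since de/dg = -1), plus the
  ## s-dependence terms through q_k and g_k^2
  U <- -E / S / n + Tm * (2 * G * Q - 2 * G * G * Vd) + 2 * G * Vd * sTg2
  dMd <- G * (U - rowSums(U * G))
  list(loss = loss, dMd = dMd, dVd = dVd, probs = G, probVar = G * G * Q)
}

## Cross-entropy on softmax for the deterministic twin.
ceGrad <- function(Md, Y) {
  G <- rowSoftmax(Md)
  loss <- -mean(rowSums(Y * log(pmax(G, 1e-12))))
  list(loss = loss, dMd = (G - Y) / nrow(Md), probs = G)
}

regressionGrad <- function(pred, target, kind = c("mse", "mae")) {
  kind <- match.arg(kind)
  r <- pred - target
  if (kind == "mse") list(loss = mean(r * r), dPred = 2 * r / length(r))
  else list(loss = mean(abs(r)), dPred = sign(r) / length(r))
}

oneHot <- function(labels, K) {
  Y <- matrix(0, length(labels), K)
  Y[cbind(seq_along(labels), labels + 1L)] <- 1
  Y
}
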