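#' Describe a VDP classifier architecture
#'
#' A network spec lists the layer stack of a variational density propagation
#' classifier. The default is a scaled-down residual CNN: two residual blocks
#' at 16 and 32 channels on a 28x28 input, ending in a softmax over
#' \code{numClasses} classes. The final softmax is implicit: the stack ends in
#' a fully-connected layer whose output moments are pushed through the softmax
#' moment propagation at prediction/loss time.
#'
#' @param layers list of layer descriptors, each a list with a \code{type} of
#'   \code{"conv"} (fields \code{channels}, \code{kernel}, \code{stride},
#'   \code{pad}), \code{"relu"}, \code{"pool"} (\code{window}, \code{stride}),
#'   \code{"residual"} (\code{channels}, \code{kernel}; a conv-relu-conv block
#'   with an identity skip), \code{"flatten"}, or \code{"fc"} (\code{units}).
#'   \code{NULL} selects the default residual architecture.
#' @param inputShape integer c(channels, height, width).
#' @param numClasses number of output classes K.
#' @param mode covariance mode of the trained model; the training backend is
#'   \code{"diagonal"} (elementwise variances).
#' @param seed integer seed controlling parameter initialization.
#' @param initLogVar initial log-variance of every variational weight.
#' @param varianceReduction how the K x K predictive covariance is reduced to
#'   the scalar predictive variance of a record: \code{"decision"} (diagonal
#'   entry at the predicted class; default), \code{"trace"}, or
#'   \code{"maxdiag"}.
#' @return a list of class \code{networkSpec}.
#' @export
networkSpec <- function(layers = NULL, inputShape = c(1L, 28L, 28L),
                        numClasses = 4L, mode = "diagonal", seed = 1L,
                        initLogVar = -6, varianceReduction = "decision") {
  if (is.null(layers)) {
    layers <- list(
      list(type = "conv", channels = 16L, kernel = 3L),
      list(type = "relu"),
      list(type = "pool", window = 2L),
      list(type = "residual", channels = 16L, kernel = 3L),
      list(type = "relu"),
      list(type = "conv", channels = 32L, kernel = 3L),
      list(type = "relu"),
      list(type = "pool", window = 2L),
      list(type = "residual", channels = 32L, kernel = 3L),
      list(type = "relu"),
      list(type = "flatten"),
      list(type = "fc", units = numClasses))
  }
  lastFc <- layers[[length(layers)]]
  if (!identical(lastFc$type, "fc") || lastFc$units != numClasses)
    stop("the final layer must be fc with units = numClasses (softmax head)")
  if (!varianceReduction %in% c("decision", "trace", "maxdiag"))
    stop("varianceReduction must be decision, trace or maxdiag")
  structure(list(layers = layers, inputShape = as.integer(inputShape),
                 numClasses = as.integer(numClasses), mode = mode,
                 seed = as.integer(seed), initLogVar = initLogVar,
                 varianceReduction = varianceReduction),
            class = "networkSpec")
}

#' Build a VDP network (and, on demand, its deterministic twin)
#'
#' Initializes the variational parameters (Gaussian means by He-style
#' initialization, a constant initial log-variance) of the architecture in
#' \code{spec}. The deterministic twin -- a standard CNN with the same
#' architecture whose weights are the VDP means -- is obtained from any VDP
#' model with \code{deterministicTwin()}.
#'
#' @param spec a \code{\link{networkSpec}}.
#' @return a \linkS4class{VDPNetwork} of kind \code{"vdp"}.
#' @examples
#' spec <- networkSpec(numClasses = 4, seed = 7)
#' net <- buildNetwork(spec)
#' @export
buildNetwork <- function(spec) {
  stopifnot(inherits(spec, "networkSpec"))
  set.seed(spec$seed)
  st <- initLayerStack(spec$layers, spec$inputShape, spec$initLogVar,
                       stochastic = TRUE)
  if (prod(st$outShape) != spec$numClasses)
    stop("configuration error: stack output length ", prod(st$outShape),
         " != numClasses ", spec$numClasses)
  new("VDPNetwork", layers = st$layers, spec = unclass(spec), kind = "vdp",
      trainLog = data.frame(), trained = FALSE)
}

#' @describeIn buildNetwork the deterministic twin: same architecture, weights
#'   equal to the current VDP means, zero variances. Its forward pass is the
#'   VDP mean path, so an untrained twin's outputs equal the VDP predictive
#'   means bit-for-bit.
#' @param model a \code{VDPNetwork} of kind \code{"vdp"}.
#' @export
deterministicTwin <- function(model) {
  stopifnot(is(model, "VDPNetwork"))
  new("VDPNetwork", layers = stackZeroVariance(model@layers),
      spec = model@spec, kind = "twin", trainLog = data.frame(),
      trained = model@trained)
}

## Flatten user-supplied images (n x C x H x W array, or already-flat matrix).
asBatchMatrix <- function(images, inputShape) {
  if (is.matrix(images)) {
    if (ncol(images) != prod(inputShape))
      stop("image matrix has ", ncol(images), " columns; expected ",
           prod(inputShape))
    return(images)
  }
  if (length(dim(images)) == 3L) {           # single image
    return(matrix(flattenImage(images), nrow = 1L))
  }
  if (!all(dim(images)[-1L] == inputShape))
    stop("image array dims ", paste(dim(images)[-1L], collapse = "x"),
         " do not match the network input ", paste(inputShape, collapse = "x"))
  flattenBatch(images)
}

#' Train a VDP network or its deterministic twin
#'
#' Plain stochastic gradient descent. A VDP model (kind \code{"vdp"})
#' minimizes the negative evidence lower bound: the expected-log-likelihood
#' term evaluated on the propagated output moments plus \code{klWeight} times
#' the closed-form KL divergence of the variational posterior from the prior.
#' A twin (kind \code{"twin"}) minimizes softmax cross-entropy.
#'
#' @param model a \linkS4class{VDPNetwork}.
#' @param dataset a dataset as returned by \code{\link{generateDataset}} (or a
#'   list with \code{train}/\code{val} elements, each carrying
#'   \code{images} and integer 0-based \code{labels}).
#' @param epochs number of passes over the training split.
#' @param lr learning rate (fixed).
#' @param batchSize mini-batch size.
#' @param config a \code{\link{lossConfig}}; its \code{jitter} floors the
#'   propagated softmax variances inside the likelihood and its prior/KL
#'   settings weight the regularizer. \code{NULL} uses defaults with
#'   \code{N = } training-set size.
#' @param seed integer; controls mini-batch shuffling.
#' @param clipNorm clip the global L2 norm of each mini-batch gradient to this
#'   value before the update (stabilizes the stiff early phase of the
#'   likelihood); \code{Inf} disables clipping.
#' @return the trained model, with a per-epoch \code{trainLog()} data.frame
#'   (columns epoch, loss, kl, valAccuracy).
#' @export
trainNetwork <- function(model, dataset, epochs = 10L, lr = NULL,
                         batchSize = 100L, config = NULL, seed = 1L,
                         clipNorm = 2) {
  stopifnot(is(model, "VDPNetwork"))
  spec <- model@spec
  K <- spec$numClasses
  Xtr <- asBatchMatrix(dataset$train$images, spec$inputShape)
  ytr <- as.integer(dataset$train$labels)
  Xva <- asBatchMatrix(dataset$val$images, spec$inputShape)
  yva <- as.integer(dataset$val$labels)
  n <- nrow(Xtr)
  stochastic <- model@kind == "vdp"
  if (is.null(config)) config <- lossConfig(N = n, H = K)
  if (is.null(lr)) lr <- if (stochastic) 0.05 else 0.1
  klW <- if (stochastic) config$klWeight else 0
  layers <- model@layers
  set.seed(seed)
  log <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1L, n, by = batchSize)) {
      idx <- ord[start:min(start + batchSize - 1L, n)]
      Xb <- Xtr[idx, , drop = FALSE]
      Yb <- oneHot(ytr[idx], K)
      fw <- stackForward(layers, Xb, stochastic = stochastic, keepCache = TRUE)
      if (stochastic) {
        hd <- vdpNllGrad(fw$M, fw$V, Yb, jitter = config$jitter)
        bw <- stackBackward(layers, fw$caches, hd$dMd, hd$dVd,
                            stochastic = TRUE)
        batchLoss <- hd$loss + klW * stackKL(layers, config$priorMean,
                                             config$priorVariance)
      } else {
        hd <- ceGrad(fw$M, Yb)
        bw <- stackBackward(layers, fw$caches, hd$dMd, stochastic = FALSE)
        batchLoss <- hd$loss
      }
      if (!is.finite(batchLoss))
        stop("training diverged (non-finite loss) at epoch ", ep,
             "; reduce the learning rate")
      layers <- sgdUpdate(layers, clipGrads(bw$grads, clipNorm), lr, klWeight = klW,
                          priorMean = config$priorMean,
                          priorVar = config$priorVariance,
                          stochastic = stochastic)
      losses <- c(losses, batchLoss)
    }
    va <- stackForward(layers, Xva, stochastic = FALSE)
    valAcc <- mean(max.col(va$M, ties.method = "first") - 1L == yva)
    log[[ep]] <- data.frame(epoch = ep, loss = mean(losses),
                            kl = if (stochastic)
                              stackKL(layers, config$priorMean,
                                      config$priorVariance) else NA_real_,
                            valAccuracy = valAcc)
  }
  model@layers <- layers
  model@trainLog <- do.call(rbind, log)
  model@trained <- TRUE
  model
}

#' Per-sample prediction records
#'
#' Runs the model on a batch and returns one record per image: the decision
#' (argmax of the predictive mean), the predictive mean vector over classes,
#' the scalar predictive variance (reduced from the propagated softmax
#' covariance diagonal according to the spec's \code{varianceReduction}),
#' and, when labels are supplied, a correctness flag. For a deterministic
#' twin the predictive variance is exactly 0 and \code{maxProb} carries the
#' (uncalibrated) maximum softmax probability.
#'
#' @param model a \linkS4class{VDPNetwork}.
#' @param images n x C x H x W array (or pre-flattened n x D matrix).
#' @param labels optional integer 0-based class labels.
#' @param bin optional noise-bin label stored in the records.
#' @return data.frame with columns \code{id}, \code{decision}, \code{predVar},
#'   \code{maxProb}, \code{label}, \code{correct}, \code{bin}, and the
#'   predictive-mean columns \code{prob.0 ... prob.(K-1)}.
#' @export
predictBatch <- function(model, images, labels = NULL, bin = NA_character_) {
  stopifnot(is(model, "VDPNetwork"))
  spec <- model@spec
  X <- asBatchMatrix(images, spec$inputShape)
  stochastic <- model@kind == "vdp"
  fw <- stackForward(model@layers, X, stochastic = stochastic)
  G <- rowSoftmax(fw$M)
  decision <- max.col(G, ties.method = "first") - 1L
  if (stochastic) {
    Vd <- fw$V
    sg2v <- rowSums(G * G * Vd)
    SoftVar <- G * G * (sg2v + Vd * (1 - 2 * G))   # diag of J Sigma J'
    predVar <- switch(spec$varianceReduction,
      decision = SoftVar[cbind(seq_len(nrow(G)), decision + 1L)],
      trace = rowSums(SoftVar),
      maxdiag = apply(SoftVar, 1L, max))
    predVar <- clampVar(predVar)
  } else {
    predVar <- numeric(nrow(G))
  }
  out <- data.frame(id = seq_len(nrow(G)), decision = decision,
                    predVar = predVar,
                    maxProb = G[cbind(seq_len(nrow(G)), decision + 1L)],
                    label = if (is.null(labels)) NA_integer_ else
                      as.integer(labels),
                    bin = bin, stringsAsFactors = FALSE)
  out$correct <- if (is.null(labels)) NA else out$decision == out$label
  probs <- as.data.frame(G)
  names(probs) <- paste0("prob.", seq_len(ncol(G)) - 1L)
  cbind(out, probs)
}

#' Accuracy-probability gap of a (deterministic) model per noise bin
#'
#' The gap is the mean maximum softmax probability minus the accuracy, both in
#' percent, computed per noise bin. A positive gap quantifies the
#' overconfidence of uncalibrated softmax outputs; it widens as inputs get
#' noisier.
#'
#' @param records prediction records (rows of \code{\link{predictBatch}})
#'   carrying \code{correct} flags and \code{bin} labels.
#' @return data.frame with columns \code{bin}, \code{meanMaxProb},
#'   \code{accuracy}, \code{gap} (all in percent except bin).
#' @export
accuracyProbabilityGap <- function(records) {
  stopifnot(all(c("bin", "maxProb", "correct") %in% names(records)))
  if (!nrow(records)) stop("empty record set")
  if (any(is.na(records$correct)))
    stop("records must carry correctness flags (supply labels to predictBatch)")
  bins <- unique(records$bin)
  out <- do.call(rbind, lapply(bins, function(b) {
    r <- records[records$bin == b, ]
    data.frame(bin = b, meanMaxProb = 100 * mean(r$maxProb),
               accuracy = 100 * mean(r$correct),
               gap = 100 * (mean(r$maxProb) - mean(r$correct)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Save / load a model checkpoint (plain-text JSON)
#'
#' Checkpoints hold the architecture spec, all parameter means and
#' log-variances, and the training log, as a single JSON file.
#'
#' @param model a \linkS4class{VDPNetwork}.
#' @param path file path.
#' @return \code{loadCheckpoint} returns the restored \code{VDPNetwork}.
#' @export
saveCheckpoint <- function(model, path) {
  stopifnot(is(model, "VDPNetwork"))
  payload <- list(spec = model@spec, kind = model@kind,
                  trained = model@trained,
                  params = serializeLayers(model@layers),
                  trainLog = model@trainLog)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  if (!file.exists(path)) stop("no checkpoint at '", path, "'")
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  spec <- payload$spec
  spec$inputShape <- as.integer(unlist(spec$inputShape))
  spec$numClasses <- as.integer(spec$numClasses)
  st <- initLayerStack(spec$layers, spec$inputShape, spec$initLogVar,
                       stochastic = TRUE)
  layers <- deserializeLayers(st$layers, payload$params)
  trainLog <- if (length(payload$trainLog))
    do.call(rbind, lapply(payload$trainLog, as.data.frame)) else data.frame()
  new("VDPNetwork", layers = layers, spec = spec,
      kind = payload$kind, trainLog = trainLog, trained = payload$trained)
}

serializeLayers <- function(layers) {
  lapply(layers, function(ly) {
    if (ly$type %in% c("conv", "fc"))
      list(type = ly$type, Wm = ly$Wm, bm = ly$bm, Wlv = ly$Wlv, blv = ly$blv)
    else if (ly$type == "residual")
      list(type = "residual", block = serializeLayers(ly$block))
    else list(type = ly$type)
  })
}

## JSON matrices arrive as lists of rows (row-major).
jsonMatrix <- function(x, nr, nc) matrix(unlist(x), nr, nc, byrow = TRUE)

deserializeLayers <- function(layers, params) {
  for (i in seq_along(layers)) {
    ly <- layers[[i]]; pa <- params[[i]]
    if (ly$type %in% c("conv", "fc")) {
      layers[[i]]$Wm <- jsonMatrix(pa$Wm, nrow(ly$Wm), ncol(ly$Wm))
      layers[[i]]$bm <- as.numeric(unlist(pa$bm))
      if (length(pa$Wlv)) {    # absent or JSON-null for deterministic nets
        layers[[i]]$Wlv <- jsonMatrix(pa$Wlv, nrow(ly$Wm), ncol(ly$Wm))
        layers[[i]]$blv <- as.numeric(unlist(pa$blv))
      }
    } else if (ly$type == "residual") {
      layers[[i]]$block <- deserializeLayers(ly$block, pa$block)
    }
  }
  layers
}

## Gradient of a cross-entropy loss on the predictive mean w.r.t. the input
## image -- the attack surface. The predictive mean of a VDP model is exactly
## the deterministic forward pass through the weight means, so the gradient is
## taken through the mean path.
inputGradient <- function(model, X, labels) {
  K <- model@spec$numClasses
  Y <- oneHot(as.integer(labels), K)
  fw <- stackForward(model@layers, X, stochastic = FALSE, keepCache = TRUE)
  hd <- ceGrad(fw$M, Y)
  bw <- stackBackward(model@layers, fw$caches, hd$dMd, stochastic = FALSE,
                      needInputGrad = TRUE)
  bw$dM * nrow(X)    # per-sample gradient (undo the batch-mean scaling)
}
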