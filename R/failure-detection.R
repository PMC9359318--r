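#' Summarize predictive variance per noise bin
#'
#' For each bin, the median predictive variance is computed over the correct
#' decisions, the incorrect decisions, and all decisions combined, together
#' with the bin accuracy. A bin with no incorrect (or no correct) decisions
#' reports \code{NA} for that group's median, never 0.
#'
#' @param records prediction records (\code{\link{predictBatch}} rows) with
#'   \code{correct} flags and \code{bin} labels.
#' @param binOrder optional character vector fixing the bin order of the
#'   output (defaults to order of first appearance).
#' @return data.frame with columns \code{bin}, \code{medianCorrect},
#'   \code{medianIncorrect}, \code{medianCombined}, \code{accuracy} (percent),
#'   \code{n}.
#' @export
summarizeVariance <- function(records, binOrder = NULL) {
  stopifnot(all(c("bin", "correct", "predVar") %in% names(records)))
  if (!nrow(records)) stop("empty record set")
  if (any(is.na(records$correct)))
    stop("records must carry correctness flags")
  bins <- binOrder %||% unique(records$bin)
  out <- do.call(rbind, lapply(bins, function(b) {
    r <- records[records$bin == b, ]
    if (!nrow(r)) stop("empty bin '", b, "'")
    data.frame(bin = b,
               medianCorrect = if (any(r$correct))
                 median(r$predVar[r$correct]) else NA_real_,
               medianIncorrect = if (any(!r$correct))
                 median(r$predVar[!r$correct]) else NA_real_,
               medianCombined = median(r$predVar),
               accuracy = 100 * mean(r$correct),
               n = nrow(r), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Select a fixed variance threshold from variance summaries
#'
#' The primary strategy follows the calibration rule: the median predictive
#' variance of the \emph{correct} decisions at the minimum tested noise level
#' (the first bin of the summaries, or \code{minBin}). The alternative
#' strategies are the combined median at minimum noise, and a manual value
#' (the remaining thresholds in practice are chosen by inspecting the
#' correct/combined variance trends, which no closed rule captures).
#'
#' @param summaries output of \code{\link{summarizeVariance}} whose first row
#'   (or \code{minBin} row) is the minimum-noise bin.
#' @param strategy \code{"correct-at-min-noise"}, \code{"combined-at-min-noise"}
#'   or \code{"manual"}.
#' @param manual threshold value for the manual strategy.
#' @param minBin label of the minimum-noise bin (defaults to the first row).
#' @return scalar threshold.
#' @export
selectFixedThreshold <- function(summaries,
                                 strategy = c("correct-at-min-noise",
                                              "combined-at-min-noise",
                                              "manual"),
                                 manual = NULL, minBin = NULL) {
  strategy <- match.arg(strategy)
  if (strategy == "manual") {
    if (is.null(manual)) stop("manual strategy needs a threshold value")
    return(manual)
  }
  minBin <- minBin %||% summaries$bin[1L]
  row <- summaries[summaries$bin == minBin, ]
  if (!nrow(row)) stop("summaries do not contain the minimum-noise bin '",
                       minBin, "'")
  tau <- if (strategy == "correct-at-min-noise") row$medianCorrect
         else row$medianCombined
  if (is.na(tau)) stop("the selected median is undefined in bin '", minBin, "'")
  tau
}

#' Apply a fixed variance threshold: abstention report
#'
#' Records whose predictive variance strictly exceeds \code{tau} abstain
#' ("no decision"); a sample exactly at the threshold is retained. The report
#' carries the accuracy before thresholding, the percentage of abstained
#' samples, and the accuracy over the retained samples (undefined -- \code{NA}
#' -- when everything abstains, never 100).
#'
#' @param records prediction records with \code{predVar} and \code{correct}.
#' @param tau non-negative threshold (may be \code{Inf}).
#' @param threshold descriptor stored in the report (defaults to \code{tau}).
#' @return one-row data.frame: \code{threshold}, \code{preAccuracy},
#'   \code{abstainedPct}, \code{postAccuracy} (all accuracies in percent).
#' @export
applyThreshold <- function(records, tau, threshold = NULL) {
  stopifnot(tau >= 0 || is.infinite(tau))
  if (any(is.na(records$correct)))
    stop("records must carry correctness flags")
  abstain <- records$predVar > tau
  kept <- records[!abstain, ]
  data.frame(threshold = if (is.null(threshold)) tau else threshold,
             preAccuracy = 100 * mean(records$correct),
             abstainedPct = 100 * mean(abstain),
             postAccuracy = if (nrow(kept)) 100 * mean(kept$correct)
                            else NA_real_,
             stringsAsFactors = FALSE)
}

#' Specification of the learned-threshold regressor
#'
#' @param architecture \code{"fc"} (flatten - 32-unit ReLU layer - linear
#'   output) or \code{"conv"} (one 8-channel conv + pool before the
#'   fully-connected head).
#' @param loss \code{"mse"} or \code{"mae"}.
#' @param epochs,lr,batchSize SGD settings.
#' @param seed integer seed.
#' @return list of class \code{thresholdRegressorSpec}.
#' @export
thresholdRegressorSpec <- function(architecture = c("fc", "conv"),
                                   loss = c("mse", "mae"), epochs = 30L,
                                   lr = 0.05, batchSize = 100L, seed = 1L) {
  structure(list(architecture = match.arg(architecture),
                 loss = match.arg(loss), epochs = as.integer(epochs),
                 lr = lr, batchSize = as.integer(batchSize),
                 seed = as.integer(seed)),
            class = "thresholdRegressorSpec")
}

regressorLayers <- function(architecture, inputShape) {
  if (architecture == "conv") {
    list(list(type = "conv", channels = 8L, kernel = 3L),
         list(type = "relu"),
         list(type = "pool", window = 2L),
         list(type = "flatten"),
         list(type = "fc", units = 32L),
         list(type = "relu"),
         list(type = "fc", units = 1L))
  } else {
    list(list(type = "flatten"),
         list(type = "fc", units = 32L),
         list(type = "relu"),
         list(type = "fc", units = 1L))
  }
}

#' Learn a per-image variance threshold
#'
#' Trains a regression network whose inputs are clean training images plus
#' noise-corrupted copies (one per Gaussian noise level) and whose target, for
#' both the clean image and each of its corrupted variants, is the BDNN's
#' predictive variance of the \emph{clean} image. At deployment the regressor
#' output is a per-image abstention threshold that approximates "how uncertain
#' this model is on a clean image of this kind".
#'
#' @param model a trained VDP \linkS4class{VDPNetwork}.
#' @param images clean training images.
#' @param noiseLevels target SNRs (dB) of the corrupted copies.
#' @param spec a \code{\link{thresholdRegressorSpec}}.
#' @return a \linkS4class{ThresholdRegressor}.
#' @export
trainThresholdRegressor <- function(model, images,
                                    noiseLevels = c(25, 15, 5),
                                    spec = thresholdRegressorSpec()) {
  stopifnot(is(model, "VDPNetwork"), model@kind == "vdp")
  inputShape <- model@spec$inputShape
  Xc <- asBatchMatrix(images, inputShape)
  targets <- predictBatch(model, Xc)$predVar
  if (length(unique(targets)) == 1L)
    warning("degenerate regression targets (all equal); fitting a constant ",
            "predictor")
  Xall <- Xc
  yall <- targets
  for (i in seq_along(noiseLevels)) {
    Xn <- addGaussianNoiseSNR(Xc, noiseLevels[i],
                              seed = spec$seed + i)$images
    Xall <- rbind(Xall, Xn)
    yall <- c(yall, targets)       # noisy copy shares the clean target
  }
  ## standardize targets internally for conditioning; undone at prediction
  ctr <- mean(yall); scl <- stats::sd(yall)
  if (!is.finite(scl) || scl == 0) scl <- 1
  yz <- (yall - ctr) / scl
  set.seed(spec$seed)
  st <- initLayerStack(regressorLayers(spec$architecture, inputShape),
                       inputShape, initLogVar = 0, stochastic = FALSE)
  layers <- st$layers
  n <- nrow(Xall)
  log <- vector("list", spec$epochs)
  for (ep in seq_len(spec$epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1L, n, by = spec$batchSize)) {
      idx <- ord[start:min(start + spec$batchSize - 1L, n)]
      fw <- stackForward(layers, Xall[idx, , drop = FALSE],
                         stochastic = FALSE, keepCache = TRUE)
      hd <- regressionGrad(as.vector(fw$M), yz[idx], spec$loss)
      bw <- stackBackward(layers, fw$caches, matrix(hd$dPred, ncol = 1L),
                          stochastic = FALSE)
      layers <- sgdUpdate(layers, bw$grads, spec$lr, stochastic = FALSE)
      losses <- c(losses, hd$loss)
    }
    log[[ep]] <- data.frame(epoch = ep, loss = mean(losses))
  }
  new("ThresholdRegressor", net = layers, spec = unclass(spec),
      targetScale = list(center = ctr, scale = scl),
      fitLog = do.call(rbind, log))
}

#' @describeIn trainThresholdRegressor predict per-image thresholds (clamped
#'   at 0, since a variance threshold cannot be negative).
#' @param regressor a \linkS4class{ThresholdRegressor}.
#' @export
predictThreshold <- function(regressor, images) {
  stopifnot(is(regressor, "ThresholdRegressor"))
  X <- if (is.matrix(images)) images else batchify(images)$X
  fw <- stackForward(regressor@net, X, stochastic = FALSE)
  pmax(as.vector(fw$M) * regressor@targetScale$scale +
         regressor@targetScale$center, 0)
}

#' Apply a learned per-image threshold: abstention report
#'
#' Each record abstains iff its predictive variance strictly exceeds the
#' regressor's threshold for its own image.
#'
#' @param records prediction records for \code{images} (same order).
#' @param images the images the records were produced from.
#' @param regressor a trained \linkS4class{ThresholdRegressor}.
#' @param threshold descriptor stored in the report.
#' @return one-row data.frame as \code{\link{applyThreshold}}.
#' @export
applyLearnedThreshold <- function(records, images, regressor,
                                  threshold = "learned") {
  tau <- predictThreshold(regressor, images)
  if (length(tau) != nrow(records))
    stop("records and images disagree in length")
  if (any(is.na(records$correct)))
    stop("records must carry correctness flags")
  abstain <- records$predVar > tau
  kept <- records[!abstain, ]
  data.frame(threshold = threshold,
             preAccuracy = 100 * mean(records$correct),
             abstainedPct = 100 * mean(abstain),
             postAccuracy = if (nrow(kept)) 100 * mean(kept$correct)
                            else NA_real_,
             stringsAsFactors = FALSE)
}
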