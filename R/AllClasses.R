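#' @import methods
#' @importFrom stats rnorm runif median setNames quantile
#' @importFrom utils head tail
NULL

## ---------------------------------------------------------------------------
## RandomParameter: a Gaussian variational posterior over one layer parameter.
## ---------------------------------------------------------------------------

#' Gaussian variational posterior over a layer parameter
#'
#' A \code{RandomParameter} holds the mean and elementwise variance of the
#' factorized Gaussian variational distribution over one network parameter
#' (a convolution kernel stack, a fully-connected weight matrix, or a bias
#' vector). The variance is diagonal: every scalar parameter is an
#' independent Gaussian.
#'
#' @slot mean numeric array/matrix/vector of parameter means.
#' @slot variance non-negative numeric object of the same shape.
#' @slot role character, one of \code{"conv-kernel"}, \code{"fc-weight"},
#'   \code{"bias"}.
#' @export
setClass("RandomParameter",
  representation(mean = "ANY", variance = "ANY", role = "character"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@mean), dim(object@variance)) ||
        length(object@mean) != length(object@variance))
      msg <- c(msg, "mean and variance must have identical shapes")
    if (any(object@variance < 0))
      msg <- c(msg, "variance must be non-negative elementwise")
    if (!object@role %in% c("conv-kernel", "fc-weight", "bias"))
      msg <- c(msg, "role must be one of conv-kernel, fc-weight, bias")
    if (length(msg)) msg else TRUE
  })

#' Construct a RandomParameter
#'
#' @param mean numeric array of parameter means.
#' @param variance non-negative numeric array of the same shape.
#' @param role one of \code{"conv-kernel"}, \code{"fc-weight"}, \code{"bias"}.
#' @return a \linkS4class{RandomParameter}.
#' @examples
#' randomParameter(matrix(0, 2, 3), matrix(0.1, 2, 3), "fc-weight")
#' @export
randomParameter <- function(mean, variance, role = "fc-weight") {
  new("RandomParameter", mean = mean, variance = variance, role = role)
}

#' @describeIn randomParameter accessor for the mean tensor.
#' @param x a \code{RandomParameter}.
#' @export
paramMean <- function(x) x@mean

#' @describeIn randomParameter accessor for the elementwise variance tensor.
#' @export
paramVariance <- function(x) x@variance

setMethod("show", "RandomParameter", function(object) {
  dims <- dim(object@mean)
  cat("RandomParameter [", object@role, "] shape ",
      if (is.null(dims)) length(object@mean) else paste(dims, collapse = "x"),
      "  mean range [", signif(min(object@mean), 3), ", ",
      signif(max(object@mean), 3), "]  var range [",
      signif(min(object@variance), 3), ", ",
      signif(max(object@variance), 3), "]\n", sep = "")
})

## ---------------------------------------------------------------------------
## GaussianActivation: the (mean, covariance) pair flowing between layers.
## ---------------------------------------------------------------------------

#' Gaussian activation: the moments flowing between layers
#'
#' A \code{GaussianActivation} carries the first two moments of the signal at
#' one point in the network: a mean vector over the flattened activation and
#' either a full symmetric covariance matrix (\code{mode = "full"}, the
#' reference representation) or its diagonal (\code{mode = "diagonal"}, the
#' scalable approximation). The \code{layout} descriptor records the spatial
#' interpretation of the flat vector (channel-major, then row-major).
#'
#' @slot mean numeric vector (flattened activation mean).
#' @slot cov either a symmetric matrix (full mode) or a numeric vector of
#'   diagonal variances (diagonal mode).
#' @slot mode \code{"full"} or \code{"diagonal"}.
#' @slot layout list with \code{channels}, \code{height}, \code{width}
#'   (all 1-length integers), or an empty list for flat (post-flatten) vectors.
#' @export
setClass("GaussianActivation",
  representation(mean = "numeric", cov = "ANY", mode = "character",
                 layout = "list"),
  validity = function(object) {
    msg <- character()
    n <- length(object@mean)
    if (!object@mode %in% c("full", "diagonal"))
      msg <- c(msg, "mode must be 'full' or 'diagonal'")
    if (object@mode == "full") {
      if (!is.matrix(object@cov) || any(dim(object@cov) != n))
        msg <- c(msg, "full covariance dimension must equal flattened mean length")
      else {
        asym <- max(abs(object@cov - t(object@cov)))
        scale <- max(abs(object@cov), 1e-300)
        if (asym > 1e-8 * scale)
          msg <- c(msg, "full covariance must be symmetric (1e-8 relative)")
        if (any(diag(object@cov) < -1e-10))
          msg <- c(msg, "covariance diagonal must be >= -1e-10")
      }
    } else {
      if (is.matrix(object@cov) || length(object@cov) != n)
        msg <- c(msg, "diagonal covariance must be a vector matching the mean")
      else if (any(object@cov < -1e-10))
        msg <- c(msg, "diagonal variances must be >= -1e-10")
    }
    if (length(object@layout) &&
        !all(c("channels", "height", "width") %in% names(object@layout)))
      msg <- c(msg, "layout must name channels, height, width")
    if (length(msg)) msg else TRUE
  })

#' Construct a GaussianActivation
#'
#' @param mean numeric vector of activation means (canonical flat order).
#' @param cov full covariance matrix or diagonal-variance vector; defaults to
#'   all-zero diagonal.
#' @param mode \code{"full"} or \code{"diagonal"}; inferred from \code{cov}
#'   when missing.
#' @param layout optional list \code{list(channels=, height=, width=)}
#'   describing the spatial interpretation of \code{mean}.
#' @return a \linkS4class{GaussianActivation}. Tiny negative diagonal entries
#'   (down to \code{-1e-10}) are clamped to zero; full covariances are
#'   symmetrized.
#' @examples
#' gaussianActivation(c(1, 2), diag(0.1, 2))
#' @export
gaussianActivation <- function(mean, cov = NULL, mode = NULL, layout = list()) {
  if (is.null(cov)) cov <- numeric(length(mean))
  if (is.null(mode)) mode <- if (is.matrix(cov)) "full" else "diagonal"
  if (mode == "full") cov <- symmetrizeCov(cov) else cov <- clampVar(cov)
  if (length(layout)) {
    layout <- lapply(layout[c("channels", "height", "width")], as.integer)
    names(layout) <- c("channels", "height", "width")
  }
  new("GaussianActivation", mean = as.numeric(mean), cov = cov, mode = mode,
      layout = layout)
}

#' @describeIn gaussianActivation accessor for the mean vector.
#' @param x a \code{GaussianActivation}.
#' @export
actMean <- function(x) x@mean

#' @describeIn gaussianActivation accessor for the covariance (matrix in full
#'   mode, diagonal vector in diagonal mode).
#' @export
actCovariance <- function(x) x@cov

#' @describeIn gaussianActivation accessor for the covariance mode.
#' @export
covarianceMode <- function(x) x@mode

#' @describeIn gaussianActivation accessor for the layout descriptor.
#' @export
actLayout <- function(x) x@layout

#' @describeIn gaussianActivation diagonal of the covariance in either mode.
#' @export
actVariance <- function(x) if (x@mode == "full") diag(x@cov) else x@cov

setMethod("show", "GaussianActivation", function(object) {
  cat("GaussianActivation (", object@mode, ") length ", length(object@mean),
      sep = "")
  if (length(object@layout))
    cat("  [", object@layout$channels, "x", object@layout$height, "x",
        object@layout$width, "]", sep = "")
  cat("\n  mean range [", signif(min(object@mean), 4), ", ",
      signif(max(object@mean), 4), "]  var range [",
      signif(min(actVariance(object)), 4), ", ",
      signif(max(actVariance(object)), 4), "]\n", sep = "")
})

## ---------------------------------------------------------------------------
## VDPNetwork: a trainable variational-density-propagation classifier.
## ---------------------------------------------------------------------------

#' A variational density propagation network
#'
#' Container for a trainable VDP classifier (or its deterministic twin): the
#' layer stack with its variational parameters (means and log-variances), the
#' architecture spec, and the training log. Build with
#' \code{\link{buildNetwork}}; train with \code{\link{trainNetwork}}.
#'
#' @slot layers list of internal layer states.
#' @slot spec the \code{\link{networkSpec}} the model was built from.
#' @slot kind \code{"vdp"} or \code{"twin"}.
#' @slot trainLog data.frame of per-epoch loss/accuracy (empty before training).
#' @slot trained logical.
#' @export
setClass("VDPNetwork",
  representation(layers = "list", spec = "list", kind = "character",
                 trainLog = "data.frame", trained = "logical"),
  validity = function(object) {
    if (!object@kind %in% c("vdp", "twin")) return("kind must be vdp or twin")
    TRUE
  })

setMethod("show", "VDPNetwork", function(object) {
  cat(sprintf("VDPNetwork (%s) input %s, %d classes, mode %s, %s\n",
              object@kind,
              paste(object@spec$inputShape, collapse = "x"),
              object@spec$numClasses, object@spec$mode,
              if (object@trained) "trained" else "untrained"))
  for (ly in object@layers) {
    cat("  -", ly$type)
    if (ly$type == "conv")
      cat(sprintf(" %dx%d, %d -> %d ch", ly$k, ly$k, ly$cin, ly$cout))
    if (ly$type == "fc") cat(sprintf(" %d -> %d", ly$din, ly$dout))
    if (ly$type == "pool") cat(sprintf(" %dx%d", ly$window, ly$window))
    if (ly$type == "residual") cat(sprintf(" (%d inner layers)", length(ly$block)))
    cat("\n")
  }
  if (nrow(object@trainLog)) {
    last <- object@trainLog[nrow(object@trainLog), ]
    cat(sprintf("  last epoch: loss %.4f, val accuracy %.1f%%\n",
                last$loss, 100 * last$valAccuracy))
  }
})

#' @describeIn buildNetwork training log accessor (per-epoch data.frame).
#' @export
trainLog <- function(model) model@trainLog

## ---------------------------------------------------------------------------
## ThresholdRegressor: learned per-image variance threshold model.
## ---------------------------------------------------------------------------

#' Learned variance-threshold regressor
#'
#' A small neural network that maps an input image to a predicted clean-image
#' predictive variance; used as a per-image abstention threshold. Build with
#' \code{\link{trainThresholdRegressor}}.
#'
#' @slot net the internal regression network (deterministic layer stack).
#' @slot spec the \code{\link{thresholdRegressorSpec}} used.
#' @slot targetScale internal target standardization (list with center/scale).
#' @slot fitLog data.frame of per-epoch training loss.
#' @export
setClass("ThresholdRegressor",
  representation(net = "list", spec = "list", targetScale = "list",
                 fitLog = "data.frame"))

setMethod("show", "ThresholdRegressor", function(object) {
  cat(sprintf("ThresholdRegressor (%s, %s loss), %d epochs trained\n",
              object@spec$architecture, object@spec$loss,
              nrow(object@fitLog)))
})
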