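#' Signal-to-noise ratio of a corruption, in dB
#'
#' \code{10 log10(sum(clean^2) / sum(noise^2))}: the energy-ratio reading of
#' the SNR, so halving the noise amplitude raises the SNR by ~6 dB and scaling
#' it by 10 lowers the SNR by exactly 20 dB.
#'
#' @param clean clean image (any numeric array/matrix/vector).
#' @param noise the additive noise component, same shape.
#' @return SNR in dB; \code{Inf} (with a warning) for zero noise energy.
#' @export
computeSNR <- function(clean, noise) {
  if (length(clean) != length(noise))
    stop("clean and noise must have the same shape")
  eN <- sum(noise^2)
  if (eN == 0) {
    warning("zero noise energy; SNR is infinite")
    return(Inf)
  }
  10 * log10(sum(clean^2) / eN)
}

## Normalize a batch argument to n x D plus a restore function.
batchify <- function(images) {
  if (is.matrix(images)) {
    list(X = images, restore = identity)
  } else if (length(dim(images)) == 4L) {
    d <- dim(images)
    list(X = flattenBatch(images),
         restore = function(m) unflattenBatch(m, d[2], d[3], d[4]))
  } else if (length(dim(images)) == 3L) {
    d <- dim(images)
    list(X = matrix(flattenImage(images), nrow = 1L),
         restore = function(m) unflattenImage(as.vector(m), d[1], d[2], d[3]))
  } else stop("images must be an array (C,H,W), (n,C,H,W), or an n x D matrix")
}

#' Corrupt images with Gaussian noise at a target SNR
#'
#' Zero-mean i.i.d. Gaussian noise is scaled per image so that the clean-to-
#' noise energy ratio hits the target exactly (to solver precision) before
#' clipping to [0,1]; the achieved (pre-clip) SNR is returned alongside.
#'
#' @param images images in [0,1]: (C,H,W) array, (n,C,H,W) array, or n x D
#'   matrix.
#' @param targetSnrDb finite target SNR in dB.
#' @param seed integer seed; identical seeds give identical noise.
#' @return list with \code{images} (same shape as the input, clipped to
#'   [0,1]) and \code{achievedSnr} (per-image, pre-clip).
#' @export
addGaussianNoiseSNR <- function(images, targetSnrDb, seed = 1L) {
  if (!is.finite(targetSnrDb)) stop("targetSnrDb must be finite")
  b <- batchify(images)
  X <- b$X
  set.seed(seed)
  Nz <- matrix(rnorm(length(X)), nrow(X), ncol(X))
  eSig <- rowSums(X * X)
  if (any(eSig == 0)) stop("cannot target an SNR on an all-zero image")
  eNz <- rowSums(Nz * Nz)
  scale <- sqrt(eSig * 10^(-targetSnrDb / 10) / eNz)
  Nz <- Nz * scale
  achieved <- 10 * log10(eSig / rowSums(Nz * Nz))
  list(images = b$restore(pmin(pmax(X + Nz, 0), 1)), achievedSnr = achieved)
}

#' Corrupt images with multiplicative speckle noise
#'
#' \code{x * (1 + intensity * n)} with standard-normal n, clipped to [0,1].
#'
#' @inheritParams addGaussianNoiseSNR
#' @param intensity non-negative speckle intensity; 0 is the identity.
#' @return corrupted images, same shape as the input.
#' @export
addSpeckleNoise <- function(images, intensity, seed = 1L) {
  if (intensity < 0) stop("intensity must be non-negative")
  b <- batchify(images)
  X <- b$X
  set.seed(seed)
  Nz <- matrix(rnorm(length(X)), nrow(X), ncol(X))
  b$restore(pmin(pmax(X * (1 + intensity * Nz), 0), 1))
}

#' Fast gradient sign method (FGSM) attack
#'
#' \code{x' = clip(x + epsilon * sign(grad_x L), 0, 1)} with L the
#' cross-entropy on the model's predictive mean -- the decision surface the
#' failure detector has to protect. The perturbation satisfies
#' \code{max |x' - x| <= epsilon} by construction.
#'
#' @param model a trained \linkS4class{VDPNetwork} (VDP or twin).
#' @param images images in [0,1] (any batch shape accepted by the package).
#' @param labels integer 0-based true labels.
#' @param epsilon attack budget in the infinity norm.
#' @return adversarial images, same shape as the input.
#' @export
fgsmAttack <- function(model, images, labels, epsilon) {
  stopifnot(epsilon >= 0)
  b <- batchify(images)
  X <- b$X
  g <- inputGradient(model, X, labels)
  if (all(g == 0))
    warning("input gradient is identically zero; returning the input unchanged")
  b$restore(pmin(pmax(X + epsilon * sign(g), 0), 1))
}

#' Projected gradient descent (PGD) attack
#'
#' Iterative FGSM with projection onto the epsilon-ball around the original
#' image and clipping to [0,1], optionally starting from a uniformly random
#' point inside the ball. With \code{steps = 1}, \code{alpha = epsilon} and
#' \code{randomStart = FALSE}, PGD reduces exactly to FGSM.
#'
#' @inheritParams fgsmAttack
#' @param alpha per-step size.
#' @param steps iteration count.
#' @param seed integer seed for the random start.
#' @param randomStart start from a random point in the epsilon-ball.
#' @return adversarial images, same shape as the input.
#' @export
pgdAttack <- function(model, images, labels, epsilon, alpha = 2 / 255,
                      steps = 50L, seed = 1L, randomStart = TRUE) {
  stopifnot(epsilon >= 0, alpha >= 0, steps >= 1)
  b <- batchify(images)
  X0 <- b$X
  X <- X0
  if (randomStart) {
    set.seed(seed)
    X <- pmin(pmax(X0 + matrix(runif(length(X0), -epsilon, epsilon),
                               nrow(X0), ncol(X0)), 0), 1)
  }
  for (t in seq_len(steps)) {
    g <- inputGradient(model, X, labels)
    X <- pmin(pmax(X + alpha * sign(g), 0), 1)
    X <- pmin(pmax(X, X0 - epsilon), X0 + epsilon)   # project onto the ball
  }
  b$restore(X)
}

#' Standard noise-bin definitions
#'
#' Convenience constructor for the four-bin Gaussian-noise evaluation protocol
#' (clean, then low/medium/high noise at decreasing SNR) and for attack bins.
#'
#' @param label bin label.
#' @param kind \code{"none"}, \code{"gaussian"}, \code{"speckle"},
#'   \code{"fgsm"}, or \code{"pgd"}.
#' @param snrDb target SNR (gaussian bins).
#' @param intensity speckle intensity.
#' @param epsilon,alpha,steps attack parameters.
#' @param seed per-bin seed.
#' @return list of class \code{noiseBin}.
#' @export
noiseBin <- function(label, kind = c("none", "gaussian", "speckle", "fgsm",
                                     "pgd"),
                     snrDb = NULL, intensity = NULL, epsilon = NULL,
                     alpha = NULL, steps = NULL, seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "gaussian" && is.null(snrDb))
    stop("gaussian bins need a target SNR")
  if (kind %in% c("fgsm", "pgd") && is.null(epsilon))
    stop("attack bins need an epsilon")
  structure(list(label = label, kind = kind, snrDb = snrDb,
                 intensity = intensity, epsilon = epsilon, alpha = alpha,
                 steps = steps, seed = as.integer(seed)),
            class = "noiseBin")
}

#' @rdname noiseBin
#' @param snrLevels SNRs (dB) of the low/medium/high Gaussian bins.
#' @export
defaultNoiseBins <- function(snrLevels = c(low = 15, medium = 7, high = 2),
                             seed = 1L) {
  bins <- list(noiseBin("none", "none", seed = seed))
  for (i in seq_along(snrLevels)) {
    bins[[length(bins) + 1L]] <- noiseBin(names(snrLevels)[i], "gaussian",
                                          snrDb = snrLevels[i],
                                          seed = seed + i)
  }
  bins
}

#' Apply a noise/attack bin to a batch of images
#'
#' @param bin a \code{\link{noiseBin}}.
#' @param images clean images.
#' @param model model handle (required for attack bins).
#' @param labels true labels (required for attack bins).
#' @return corrupted images, same shape as the input.
#' @export
applyBin <- function(bin, images, model = NULL, labels = NULL) {
  stopifnot(inherits(bin, "noiseBin"))
  switch(bin$kind,
    none = images,
    gaussian = addGaussianNoiseSNR(images, bin$snrDb, bin$seed)$images,
    speckle = addSpeckleNoise(images, bin$intensity, bin$seed),
    fgsm = fgsmAttack(model, images, labels, bin$epsilon),
    pgd = pgdAttack(model, images, labels, bin$epsilon,
                    bin$alpha %||% 2 / 255, bin$steps %||% 50L, bin$seed))
}
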