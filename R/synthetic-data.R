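#' Specification of a synthetic multi-class image dataset
#'
#' The generator emulates the structure the analysis pipeline assumes:
#' K-class (4-11) small images (default 28x28, 1 or 3 channels) with pixel
#' values in [0,1], balanced classes, and a tunable separability so that
#' additive noise degrades accuracy gradually rather than abruptly. Each class
#' is a parametric prototype -- a positioned geometric shape combined with a
#' class-specific intensity gradient -- jittered per sample (position, size,
#' amplitude) and overlaid with i.i.d. Gaussian texture noise of standard
#' deviation \code{1/separability}.
#'
#' @param nTrain,nVal,nTest split sizes.
#' @param numClasses K, between 2 and 11 (4-11 mirrors the intended regime).
#' @param channels 1 or 3.
#' @param side image side length.
#' @param separability positive real; texture-noise scale is
#'   \code{1/separability}. Larger values give cleaner, easier classes.
#' @param seed integer; each split consumes a disjoint seed stream.
#' @return list of class \code{syntheticSpec}.
#' @export
syntheticSpec <- function(nTrain = 2000L, nVal = 500L, nTest = 1000L,
                          numClasses = 4L, channels = 1L, side = 28L,
                          separability = 3, seed = 1L) {
  if (numClasses < 2L) stop("numClasses must be at least 2")
  if (numClasses > 11L) stop("at most 11 prototype classes are defined")
  if (!channels %in% c(1L, 3L)) stop("channels must be 1 or 3")
  stopifnot(separability > 0, side >= 8L)
  structure(list(nTrain = as.integer(nTrain), nVal = as.integer(nVal),
                 nTest = as.integer(nTest), numClasses = as.integer(numClasses),
                 channels = as.integer(channels), side = as.integer(side),
                 separability = separability, seed = as.integer(seed)),
            class = "syntheticSpec")
}

## Prototype masks on an L x L grid, centered at (cy, cx), size parameter r.
## Row-major coordinates; values in [0, 1].
prototypeMask <- function(class0, L, cy, cx, r) {
  yy <- matrix(seq_len(L), L, L)          # row index
  xx <- matrix(seq_len(L), L, L, byrow = TRUE)
  dy <- yy - cy; dx <- xx - cx
  rad <- sqrt(dy^2 + dx^2)
  switch(class0 + 1L,
    (rad <= r) * 1,                                          # 0 disk
    (abs(dy) <= r & abs(dx) <= r) *
      (pmax(abs(dy), abs(dx)) >= 0.55 * r),                  # 1 square frame
    (abs(dy) <= 0.35 * r & abs(dx) <= 1.4 * r) * 1,          # 2 horizontal bar
    (abs(dx) <= 0.35 * r & abs(dy) <= 1.4 * r) * 1,          # 3 vertical bar
    ((abs(dy) <= 0.3 * r | abs(dx) <= 0.3 * r) &
       rad <= 1.4 * r) * 1,                                  # 4 cross
    (abs(dy - dx) <= 0.45 * r & rad <= 1.5 * r) * 1,         # 5 diagonal stripe
    (rad <= r & rad >= 0.55 * r) * 1,                        # 6 ring
    ((((yy %/% max(2, round(r / 1.5))) +
       (xx %/% max(2, round(r / 1.5)))) %% 2) *
       (rad <= 1.4 * r)),                                    # 7 checker patch
    (dy >= -r & dx >= -r & (dy + dx) <= 0.2 * r &
       dy <= r & dx <= r) * 1,                               # 8 triangle
    ((abs(dy - dx) <= 0.3 * r | abs(dy + dx) <= 0.3 * r) &
       rad <= 1.4 * r) * 1,                                  # 9 X shape
    ((round(rad) %% max(2, round(r / 2))) <= 0.6 &
       rad <= 1.3 * r) * 1                                   # 10 concentric dots
  )
}

## One sample image (C x H x W) for a class, using the current RNG stream.
synthSample <- function(class0, spec) {
  L <- spec$side
  K <- spec$numClasses
  cy <- L / 2 + runif(1, -4, 4)
  cx <- L / 2 + runif(1, -4, 4)
  r <- L / 6.5 * runif(1, 0.7, 1.3)
  amp <- runif(1, 0.55, 1)
  mask <- prototypeMask(class0, L, cy, cx, r)
  theta <- 2 * pi * class0 / K
  yy <- matrix(seq_len(L), L, L); xx <- matrix(seq_len(L), L, L, byrow = TRUE)
  grad <- 0.1 * ((cos(theta) * (xx - L / 2) + sin(theta) * (yy - L / 2)) /
                   L + 0.5)
  base <- 0.1 + grad + 0.55 * amp * mask
  img <- array(0, c(spec$channels, L, L))
  if (spec$channels == 1L) {
    img[1, , ] <- base
  } else {
    ## class-specific channel mixture so color carries signal too
    mix <- 0.5 + 0.5 * cos(theta + 2 * pi * (0:2) / 3)
    for (ch in 1:3) img[ch, , ] <- grad + mix[ch] * (0.1 + 0.55 * amp * mask)
  }
  img <- img + array(rnorm(length(img), sd = 1 / spec$separability), dim(img))
  pmin(pmax(img, 0), 1)
}

synthSplit <- function(spec, n, splitSeed) {
  set.seed(splitSeed)
  K <- spec$numClasses
  labels <- rep_len(0:(K - 1L), n)[sample.int(n)]   # balanced within +-1
  images <- array(0, c(n, spec$channels, spec$side, spec$side))
  for (i in seq_len(n)) images[i, , , ] <- synthSample(labels[i], spec)
  list(images = images, labels = labels)
}

#' Generate a synthetic image dataset
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @return list with elements \code{train}, \code{val}, \code{test} (each a
#'   list with \code{images}, an \code{n x channels x side x side} array in
#'   [0,1], and integer 0-based \code{labels}), plus the \code{spec}.
#'   Bit-identical for identical specs; the three splits use disjoint seed
#'   streams derived from \code{spec$seed}.
#' @examples
#' d <- generateDataset(syntheticSpec(nTrain = 8, nVal = 4, nTest = 4))
#' range(d$train$images)   # within [0, 1]
#' @export
generateDataset <- function(spec) {
  stopifnot(inherits(spec, "syntheticSpec"))
  base <- (spec$seed %% 1000000L) * 1000L
  list(train = synthSplit(spec, spec$nTrain, base + 1L),
       val = synthSplit(spec, spec$nVal, base + 2L),
       test = synthSplit(spec, spec$nTest, base + 3L),
       spec = spec)
}
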