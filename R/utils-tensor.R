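## Tensor layout and gather/scatter machinery shared by the moment-propagation
## code, the trainable network, and the Monte-Carlo oracle.
##
## Flattening convention (fixed, recorded in every GaussianActivation layout):
## channel-major, then row-major spatial. A pixel (ch, r, c) of a C x H x W
## image maps to flat index (ch-1)*H*W + (r-1)*W + c. Batches are stored as
## n x D matrices of flattened images.

#' Flatten an image array to the package's canonical vector layout
#'
#' @param img numeric array with dim \code{c(channels, height, width)}, or a
#'   matrix (interpreted as a single-channel \code{height x width} image).
#' @return numeric vector of length \code{prod(dim(img))} in channel-major,
#'   row-major order.
#' @export
flattenImage <- function(img) {
  if (is.matrix(img)) img <- array(img, c(1L, nrow(img), ncol(img)))
  stopifnot(length(dim(img)) == 3L)
  ## aperm to (W, H, C) so as.vector enumerates column, then row, then channel
  as.vector(aperm(img, c(3L, 2L, 1L)))
}

#' Restore an image array from its canonical flat vector
#'
#' @param v numeric vector of length \code{channels * height * width}.
#' @param channels,height,width image dimensions.
#' @return numeric array with dim \code{c(channels, height, width)}.
#' @export
unflattenImage <- function(v, channels, height, width) {
  stopifnot(length(v) == channels * height * width)
  aperm(array(v, c(width, height, channels)), c(3L, 2L, 1L))
}

## Flatten a batch given as an n x C x H x W array into an n x D matrix.
flattenBatch <- function(x) {
  if (is.matrix(x)) return(x)
  stopifnot(length(dim(x)) == 4L)
  n <- dim(x)[1L]
  ## aperm to (n, W, H, C): vector order runs n, then w, then r, then ch,
  ## giving columns in canonical flat order.
  m <- aperm(x, c(1L, 4L, 3L, 2L))
  dim(m) <- c(n, prod(dim(x)[-1L]))
  m
}

unflattenBatch <- function(m, channels, height, width) {
  n <- nrow(m)
  a <- array(m, c(n, width, height, channels))
  aperm(a, c(1L, 4L, 3L, 2L))
}

## Output spatial size of a convolution/pool: floor((n + 2p - k)/s) + 1.
convOutSize <- function(n, k, stride, pad = 0L) {
  out <- (n + 2L * pad - k) %/% stride + 1L
  if (out < 1L) stop("window/kernel larger than (padded) spatial extent")
  out
}

## im2col index matrix for a C x H x W input: one row per output location
## (row-major over the output grid), one column per patch entry (channel-major,
## then kernel-row, then kernel-column -- matching the kernel vectorization).
## Values index the columns of cbind(0, X); 1 denotes a zero-padding entry.
buildConvIndex <- function(channels, height, width, k, stride = 1L, pad = 0L) {
  Ho <- convOutSize(height, k, stride, pad)
  Wo <- convOutSize(width, k, stride, pad)
  nLoc <- Ho * Wo
  or <- rep(seq_len(Ho), each = Wo)
  oc <- rep(seq_len(Wo), times = Ho)
  chp <- rep(seq_len(channels), each = k * k)
  krp <- rep(rep(seq_len(k), each = k), times = channels)
  kcp <- rep(seq_len(k), times = k * channels)
  R <- outer((or - 1L) * stride, krp, "+") - pad   # nLoc x P row coords
  Cc <- outer((oc - 1L) * stride, kcp, "+") - pad
  Chm <- matrix(chp, nLoc, length(chp), byrow = TRUE)
  inb <- R >= 1L & R <= height & Cc >= 1L & Cc <= width
  idx <- ifelse(inb, (Chm - 1L) * height * width + (R - 1L) * width + Cc + 1L, 1L)
  storage.mode(idx) <- "integer"
  list(idx = idx, idxFlat = as.vector(idx), outHeight = Ho, outWidth = Wo,
       nLoc = nLoc, patchLen = ncol(idx))
}

## Gather im2col patches for a batch. X: n x D, idx from buildConvIndex.
## Returns an (n*nLoc) x patchLen matrix; rows ordered sample-fastest, then
## output location.
gatherPatches <- function(X, idx, idxFlat = NULL) {
  n <- nrow(X)
  Xp <- cbind(0, X)
  G <- Xp[, idxFlat %||% as.vector(idx), drop = FALSE]
  dim(G) <- c(n * nrow(idx), ncol(idx))
  G
}

## Adjoint of gatherPatches: scatter-add patch gradients back to the input.
scatterPatches <- function(dG, idx, n, D) {
  nLoc <- nrow(idx)
  dXp <- matrix(0, n, D + 1L)
  for (p in seq_len(ncol(idx))) {
    cols <- idx[, p]
    keep <- cols > 1L
    if (!any(keep)) next
    blk <- dG[, p]
    dim(blk) <- c(n, nLoc)
    dXp[, cols[keep]] <- dXp[, cols[keep]] + blk[, keep, drop = FALSE]
  }
  dXp[, -1L, drop = FALSE]
}

## Reshape conv output (n*nLoc) x Cout -> n x (Cout*nLoc) in canonical flat
## order ((co-1)*nLoc + loc), and back. Both are pure dim tricks because rows
## are sample-fastest.
convOutToBatch <- function(O, n) { dim(O) <- c(n, length(O) / n); O }
batchToConvOut <- function(M, n, nLoc, cout) { dim(M) <- c(n * nLoc, cout); M }

## Max-pool index matrix: rows ordered (ch-1)*nLoc + loc (canonical output
## flat order), columns over the window. Values are 1-based flat input indices.
## `window` and `stride` may be scalars (square) or length-2 c(h, w) vectors.
buildPoolIndex <- function(channels, height, width, window, stride = window) {
  window <- rep_len(as.integer(window), 2L)
  stride <- rep_len(as.integer(stride), 2L)
  Ho <- convOutSize(height, window[1], stride[1], 0L)
  Wo <- convOutSize(width, window[2], stride[2], 0L)
  nLoc <- Ho * Wo
  or <- rep(seq_len(Ho), each = Wo)
  oc <- rep(seq_len(Wo), times = Ho)
  wr <- rep(seq_len(window[1]), each = window[2])
  wc <- rep(seq_len(window[2]), times = window[1])
  R <- outer((or - 1L) * stride[1], wr, "+")   # nLoc x wh*ww
  Cc <- outer((oc - 1L) * stride[2], wc, "+")
  base <- (R - 1L) * width + Cc                # single-channel flat index
  idx <- matrix(0L, channels * nLoc, window[1] * window[2])
  for (ch in seq_len(channels)) {
    idx[(ch - 1L) * nLoc + seq_len(nLoc), ] <- base + (ch - 1L) * height * width
  }
  list(idx = idx, outHeight = Ho, outWidth = Wo, nLoc = nLoc)
}

## Block-diagonal assembly of a list of square matrices.
blockDiag <- function(mats) {
  sizes <- vapply(mats, nrow, integer(1))
  total <- sum(sizes)
  out <- matrix(0, total, total)
  at <- 0L
  for (m in mats) {
    i <- at + seq_len(nrow(m))
    out[i, i] <- m
    at <- at + nrow(m)
  }
  out
}

## Symmetrize and clamp tiny negative diagonal entries (numerical hygiene).
symmetrizeCov <- function(S) {
  S <- (S + t(S)) / 2
  d <- diag(S)
  d[d < 0 & d > -1e-10] <- 0
  diag(S) <- d
  S
}

clampVar <- function(v) {
  v[v < 0 & v > -1e-10] <- 0
  pmax(v, 0)
}

## Row-wise softmax of a matrix of logits.
rowSoftmax <- function(M) {
  M <- M - apply(M, 1L, max)
  E <- exp(M)
  E / rowSums(E)
}
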