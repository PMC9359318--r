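## Dataset fixtures in the MedMNIST npz dialect: a zip archive of NumPy .npy
## arrays named train_images/train_labels/val_images/val_labels/test_images/
## test_labels. Images are stored (n, H, W) for single-channel data and
## (n, H, W, C) otherwise; labels are (n, 1). No R package in the dependency
## set speaks this format, so a minimal npy v1.0 codec and a stored
## (uncompressed) zip writer live here; reading goes through utils::unzip.

## ---- npy codec --------------------------------------------------------------

npyDescr <- function(x) if (is.integer(x)) "<i4" else "<f8"

writeNpy <- function(x, path) {
  dims <- dim(x) %||% length(x)
  ## numpy arrays are C-ordered; R arrays are Fortran-ordered
  xc <- if (length(dims) > 1L) aperm(x, rev(seq_along(dims))) else x
  shape <- paste0("(", paste(dims, collapse = ", "),
                  if (length(dims) == 1L) "," else "", ")")
  header <- sprintf("{'descr': '%s', 'fortran_order': False, 'shape': %s, }",
                    npyDescr(x), shape)
  ## pad so that magic(6)+version(2)+hlen(2)+header is a multiple of 64
  total <- 10L + nchar(header) + 1L
  pad <- (64L - total %% 64L) %% 64L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, charToRaw("NUMPY"), 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header)), con, size = 2L, endian = "little")
  writeChar(header, con, eos = NULL)
  if (is.integer(x)) writeBin(as.vector(xc), con, size = 4L, endian = "little")
  else writeBin(as.numeric(as.vector(xc)), con, size = 8L, endian = "little")
  invisible(path)
}

readNpy <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 10L || any(raw[1:6] != as.raw(c(0x93, charToRaw("NUMPY")))))
    stop("not an npy file: ", path)
  major <- as.integer(raw[7])
  if (major == 1L) {
    hlen <- as.integer(raw[9]) + 256L * as.integer(raw[10])
    hstart <- 11L
  } else {
    hlen <- sum(as.integer(raw[9:12]) * 256^(0:3))
    hstart <- 13L
  }
  header <- rawToChar(raw[hstart:(hstart + hlen - 1L)])
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shapeStr <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  dims <- as.integer(strsplit(gsub("\\s", "", shapeStr), ",")[[1]])
  dims <- dims[!is.na(dims)]
  if (!length(dims)) dims <- integer(0)
  nElem <- if (length(dims)) prod(dims) else 1L
  dataStart <- hstart + hlen
  body <- raw[dataStart:length(raw)]
  vals <- switch(descr,
    "<f8" = readBin(body, "numeric", nElem, size = 8L, endian = "little"),
    "<f4" = readBin(body, "numeric", nElem, size = 4L, endian = "little"),
    "<i8" = readBin(body, "numeric", nElem, size = 8L, endian = "little"),
    "<i4" = readBin(body, "integer", nElem, size = 4L, endian = "little"),
    "<i2" = readBin(body, "integer", nElem, size = 2L, endian = "little"),
    "|u1" = as.integer(readBin(body, "integer", nElem, size = 1L,
                               signed = FALSE)),
    "<u1" = as.integer(readBin(body, "integer", nElem, size = 1L,
                               signed = FALSE)),
    "|i1" = readBin(body, "integer", nElem, size = 1L),
    stop("unsupported npy dtype '", descr, "' in ", path))
  if (length(dims) > 1L) {
    if (fortran) { dim(vals) <- dims }
    else { dim(vals) <- rev(dims); vals <- aperm(vals, rev(seq_along(dims))) }
  }
  attr(vals, "descr") <- descr
  vals
}

## ---- stored zip writer ------------------------------------------------------

## CRC-32 via the trailer of a true gzip stream (zlib computes it in C);
## memCompress is unsuitable here because it emits zlib framing (Adler-32).
crc32raw <- function(data) {
  tmp <- tempfile(fileext = ".gz")
  on.exit(unlink(tmp))
  con <- gzfile(tmp, "wb", compression = 1)
  writeBin(data, con)
  close(con)
  gz <- readBin(tmp, "raw", file.info(tmp)$size)
  gz[(length(gz) - 7L):(length(gz) - 4L)]
}

int2le <- function(x, nbytes) {
  out <- raw(nbytes)
  for (i in seq_len(nbytes)) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

## Write entries (a named list of raw vectors) as an uncompressed zip archive.
writeStoredZip <- function(entries, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- integer(length(entries))
  crcs <- vector("list", length(entries))
  pos <- 0L
  for (i in seq_along(entries)) {
    name <- charToRaw(names(entries)[i])
    data <- entries[[i]]
    crcs[[i]] <- crc32raw(data)
    offsets[i] <- pos
    local <- c(as.raw(c(0x50, 0x4b, 0x03, 0x04)),  # PK\3\4
               int2le(20, 2), int2le(0, 2), int2le(0, 2),  # ver, flags, method
               int2le(0, 2), int2le(0x21, 2),      # time, date (dummy valid)
               crcs[[i]], int2le(length(data), 4), int2le(length(data), 4),
               int2le(length(name), 2), int2le(0, 2))
    writeBin(local, con)
    writeBin(name, con)
    writeBin(data, con)
    pos <- pos + length(local) + length(name) + length(data)
  }
  cdStart <- pos
  for (i in seq_along(entries)) {
    name <- charToRaw(names(entries)[i])
    data <- entries[[i]]
    central <- c(as.raw(c(0x50, 0x4b, 0x01, 0x02)),  # PK\1\2
                 int2le(20, 2), int2le(20, 2), int2le(0, 2), int2le(0, 2),
                 int2le(0, 2), int2le(0x21, 2),
                 crcs[[i]], int2le(length(data), 4), int2le(length(data), 4),
                 int2le(length(name), 2), int2le(0, 2), int2le(0, 2),
                 int2le(0, 2), int2le(0, 2), int2le(0, 4),
                 int2le(offsets[i], 4))
    writeBin(central, con)
    writeBin(name, con)
    pos <- pos + length(central) + length(name)
  }
  end <- c(as.raw(c(0x50, 0x4b, 0x05, 0x06)), int2le(0, 2), int2le(0, 2),
           int2le(length(entries), 2), int2le(length(entries), 2),
           int2le(pos - cdStart, 4), int2le(cdStart, 4), int2le(0, 2))
  writeBin(end, con)
  invisible(path)
}

## ---- fixture interface ------------------------------------------------------

#' Write / read a dataset fixture (MedMNIST npz dialect)
#'
#' \code{writeFixture} serializes a dataset (as produced by
#' \code{\link{generateDataset}}) into an npz archive with arrays
#' \code{train_images}, \code{train_labels}, \code{val_images},
#' \code{val_labels}, \code{test_images}, \code{test_labels}. Images are
#' written \code{(n, H, W)} for single-channel data or \code{(n, H, W, C)}
#' otherwise, labels as \code{(n, 1)} integers -- the layout of the real
#' PathMNIST/DermaMNIST/OrganAMNIST archives, so \code{readFixture} also loads
#' those unchanged (uint8 images are rescaled to [0,1]).
#'
#' @param dataset list with \code{train}/\code{val}/\code{test} splits, each
#'   carrying \code{images} (n x C x H x W array in [0,1]) and \code{labels}.
#' @param path file path of the archive.
#' @return \code{readFixture} returns the dataset in the internal
#'   representation (images \code{n x C x H x W}, labels 0-based integers).
#' @export
writeFixture <- function(dataset, path) {
  entries <- list()
  for (split in c("train", "val", "test")) {
    sp <- dataset[[split]]
    if (is.null(sp)) stop("dataset is missing the '", split, "' split")
    imgs <- sp$images
    stopifnot(length(dim(imgs)) == 4L)
    n <- dim(imgs)[1]; C <- dim(imgs)[2]; H <- dim(imgs)[3]; W <- dim(imgs)[4]
    arr <- if (C == 1L) array(imgs[, 1L, , ], c(n, H, W))
           else aperm(imgs, c(1L, 3L, 4L, 2L))          # (n, H, W, C)
    lab <- matrix(as.integer(sp$labels), ncol = 1L)
    ti <- tempfile(fileext = ".npy"); writeNpy(arr, ti)
    tl <- tempfile(fileext = ".npy"); writeNpy(lab, tl)
    entries[[paste0(split, "_images.npy")]] <-
      readBin(ti, "raw", file.info(ti)$size)
    entries[[paste0(split, "_labels.npy")]] <-
      readBin(tl, "raw", file.info(tl)$size)
    unlink(c(ti, tl))
  }
  writeStoredZip(entries, path)
  invisible(path)
}

#' @rdname writeFixture
#' @export
readFixture <- function(path) {
  if (!file.exists(path)) stop("no archive at '", path, "'")
  exdir <- tempfile("npz")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE))
  files <- utils::unzip(path, exdir = exdir)
  present <- sub("\\.npy$", "", basename(files))
  out <- list()
  for (split in c("train", "val", "test")) {
    for (kind in c("images", "labels")) {
      nm <- paste0(split, "_", kind)
      if (!nm %in% present)
        stop("malformed archive: missing array '", nm, "'")
    }
    imgs <- readNpy(file.path(exdir, paste0(split, "_images.npy")))
    labs <- readNpy(file.path(exdir, paste0(split, "_labels.npy")))
    if (!is.null(attr(imgs, "descr")) &&
        attr(imgs, "descr") %in% c("|u1", "<u1")) imgs <- imgs / 255
    d <- dim(imgs)
    arr <- if (length(d) == 3L) {
      a <- array(0, c(d[1], 1L, d[2], d[3])); a[, 1L, , ] <- imgs; a
    } else if (length(d) == 4L) {
      aperm(imgs, c(1L, 4L, 2L, 3L))                     # -> (n, C, H, W)
    } else stop("images array '", split, "_images' must be 3- or 4-dimensional")
    out[[split]] <- list(images = arr, labels = as.integer(as.vector(labs)))
  }
  out
}
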