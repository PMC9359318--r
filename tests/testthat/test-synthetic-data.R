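test_that("the generator is reproducible, bounded, and balanced", {
  spec <- syntheticSpec(nTrain = 40, nVal = 12, nTest = 12, seed = 5)
  d1 <- generateDataset(spec)
  d2 <- generateDataset(spec)
  expect_identical(d1, d2)
  expect_true(all(d1$train$images >= 0 & d1$train$images <= 1))
  tab <- table(d1$train$labels)
  expect_lte(max(tab) - min(tab), 1)
  expect_setequal(names(tab), as.character(0:3))
  ## splits differ (disjoint seed streams)
  expect_false(identical(d1$train$images[1, , , ], d1$val$images[1, , , ]))
  expect_error(syntheticSpec(numClasses = 1), "at least 2")
  expect_error(syntheticSpec(channels = 2), "channels")
})

test_that("all eleven prototype classes render for 1- and 3-channel images", {
  d <- generateDataset(syntheticSpec(nTrain = 22, nVal = 11, nTest = 11,
                                     numClasses = 11, seed = 3))
  expect_equal(dim(d$train$images), c(22, 1, 28, 28))
  perClassSd <- vapply(0:10, function(k)
    stats::sd(d$train$images[d$train$labels == k, , , ]), numeric(1))
  expect_true(all(perClassSd > 0))
  d3 <- generateDataset(syntheticSpec(nTrain = 8, nVal = 4, nTest = 4,
                                      channels = 3, seed = 4))
  expect_equal(dim(d3$train$images)[2], 3)
})

test_that("in the noiseless limit a nearest-prototype classifier is perfect
           and accuracy is monotone in separability", {
  nn1Accuracy <- function(sep, seed) {
    d <- generateDataset(syntheticSpec(nTrain = 320, nVal = 10, nTest = 80,
                                       separability = sep, seed = seed))
    Xtr <- vdpnet:::flattenBatch(d$train$images)
    Xte <- vdpnet:::flattenBatch(d$test$images)
    d2 <- outer(rowSums(Xte^2), rowSums(Xtr^2), "+") - 2 * Xte %*% t(Xtr)
    mean(d$train$labels[max.col(-d2)] == d$test$labels)
  }
  expect_equal(nn1Accuracy(1e9, 1), 1)
  accs <- vapply(c(1.2, 3, 8), function(s)
    mean(vapply(1:3, function(sd) nn1Accuracy(s, sd), numeric(1))),
    numeric(1))
  expect_true(all(diff(accs) > 0))
})

test_that("fixtures round-trip through the npz dialect", {
  d <- generateDataset(syntheticSpec(nTrain = 5, nVal = 3, nTest = 3,
                                     seed = 9))
  path <- tempfile(fileext = ".npz")
  writeFixture(d, path)
  back <- readFixture(path)
  expect_equal(back$train$images, d$train$images, tolerance = 0)
  expect_identical(back$test$labels, as.integer(d$test$labels))

  ## 3-channel images use the (n, H, W, C) layout
  d3 <- generateDataset(syntheticSpec(nTrain = 4, nVal = 2, nTest = 2,
                                      channels = 3, seed = 10))
  path3 <- tempfile(fileext = ".npz")
  writeFixture(d3, path3)
  expect_equal(readFixture(path3)$val$images, d3$val$images, tolerance = 0)
  expect_error(readFixture(tempfile()), "no archive")
})

test_that("archives follow the MedMNIST npz dialect at byte level", {
  d <- generateDataset(syntheticSpec(nTrain = 4, nVal = 2, nTest = 2,
                                     seed = 11))
  path <- tempfile(fileext = ".npz")
  writeFixture(d, path)
  listing <- utils::unzip(path, list = TRUE)
  expect_setequal(listing$Name,
                  paste0(rep(c("train", "val", "test"), each = 2),
                         c("_images.npy", "_labels.npy")))
  ## each entry is an npy v1.0 array with a C-ordered float64/int32 header
  exdir <- tempfile(); dir.create(exdir)
  utils::unzip(path, exdir = exdir)
  raw <- readBin(file.path(exdir, "train_images.npy"), "raw", 200)
  expect_identical(raw[1:6], as.raw(c(0x93, charToRaw("NUMPY"))))
  header <- rawToChar(raw[11:(10 + as.integer(raw[9]) +
                                256L * as.integer(raw[10]))])
  expect_match(header, "'descr': '<f8'")
  expect_match(header, "'fortran_order': False")
  expect_match(header, "'shape': \\(4, 28, 28\\)")
  rawLab <- readBin(file.path(exdir, "train_labels.npy"), "raw", 200)
  headerLab <- rawToChar(rawLab[11:(10 + as.integer(rawLab[9]) +
                                      256L * as.integer(rawLab[10]))])
  expect_match(headerLab, "'shape': \\(4, 1\\)")
})

test_that("a malformed archive names its missing array", {
  d <- generateDataset(syntheticSpec(nTrain = 3, nVal = 2, nTest = 2,
                                     seed = 12))
  full <- tempfile(fileext = ".npz")
  writeFixture(d, full)
  exdir <- tempfile(); dir.create(exdir)
  utils::unzip(full, exdir = exdir)
  entries <- list()
  for (f in list.files(exdir)) {
    if (f == "val_labels.npy") next
    entries[[f]] <- readBin(file.path(exdir, f), "raw",
                            file.info(file.path(exdir, f))$size)
  }
  crippled <- tempfile(fileext = ".npz")
  vdpnet:::writeStoredZip(entries, crippled)
  expect_error(readFixture(crippled), "val_labels")

  ## uint8 payloads (the real MedMNIST encoding) parse with their dtype
  header <- "{'descr': '|u1', 'fortran_order': False, 'shape': (2, 2), }"
  pad <- (64 - (10 + nchar(header) + 1) %% 64) %% 64
  header <- paste0(header, strrep(" ", pad), "\n")
  u1 <- tempfile(fileext = ".npy")
  con <- file(u1, "wb")
  writeBin(as.raw(c(0x93, charToRaw("NUMPY"), 0x01, 0x00)), con)
  writeBin(nchar(header), con, size = 2, endian = "little")
  writeChar(header, con, eos = NULL)
  writeBin(as.raw(c(0, 128, 255, 64)), con)
  close(con)
  arr <- vdpnet:::readNpy(u1)
  expect_identical(attr(arr, "descr"), "|u1")
  expect_equal(arr[1, ], c(0L, 128L))
  expect_equal(arr[2, ], c(255L, 64L))
})
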