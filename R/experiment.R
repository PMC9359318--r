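#' Experiment configuration
#'
#' A declarative description of a full failure-detection experiment: data
#' source, architecture, training settings, noise and attack bins, and
#' threshold strategies. Round-trips through YAML (\code{readExperimentConfig}
#' / \code{writeExperimentConfig}).
#'
#' @param dataset either \code{list(synthetic = list(...))} with
#'   \code{\link{syntheticSpec}} arguments, or \code{list(npz = "path")} for a
#'   MedMNIST-dialect archive.
#' @param architecture \code{"small"} (one 8-channel residual block; the test
#'   bench) or \code{"default"} (two residual blocks at 16/32 channels).
#' @param train list with \code{epochs}, \code{lr}, \code{twinLr},
#'   \code{batchSize}, \code{jitter}.
#' @param snrLevels named vector of Gaussian-bin SNRs (dB), ordered from the
#'   least to the most noisy.
#' @param attacks list of attack descriptors, each with \code{kind}
#'   (\code{"fgsm"}/\code{"pgd"}), \code{epsilon} and, for pgd, \code{alpha}
#'   and \code{steps}.
#' @param attackSamples number of test samples used in attack bins.
#' @param regressor \code{\link{thresholdRegressorSpec}} arguments.
#' @param manualThreshold optional third fixed threshold value.
#' @param outDir output directory for all artifacts.
#' @param seed global seed; fans out to named per-stage streams.
#' @return list of class \code{experimentConfig}.
#' @export
experimentConfig <- function(dataset = list(synthetic = list()),
                             architecture = c("small", "default"),
                             train = list(),
                             snrLevels = c(low = 15, medium = 7, high = 2),
                             attacks = list(
                               list(kind = "fgsm", epsilon = 0.1),
                               list(kind = "pgd", epsilon = 0.1,
                                    alpha = 0.01, steps = 20L)),
                             attackSamples = 400L,
                             regressor = list(),
                             manualThreshold = NULL,
                             outDir = "vdp-experiment", seed = 1L) {
  architecture <- match.arg(architecture)
  trainDefaults <- list(epochs = 10L, lr = 0.15, twinLr = 0.15,
                        batchSize = 50L, jitter = 0.25)
  train <- utils::modifyList(trainDefaults, train)
  structure(list(dataset = dataset, architecture = architecture,
                 train = train, snrLevels = snrLevels, attacks = attacks,
                 attackSamples = as.integer(attackSamples),
                 regressor = regressor, manualThreshold = manualThreshold,
                 outDir = outDir, seed = as.integer(seed)),
            class = "experimentConfig")
}

#' @rdname experimentConfig
#' @param path YAML file path.
#' @export
readExperimentConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$snrLevels <- unlist(raw$snrLevels)
  do.call(experimentConfig, raw)
}

#' @rdname experimentConfig
#' @param config an \code{experimentConfig}.
#' @export
writeExperimentConfig <- function(config, path) {
  out <- unclass(config)
  out$snrLevels <- as.list(out$snrLevels)   # keep names through YAML
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Architecture presets
#'
#' @param architecture \code{"small"} or \code{"default"}.
#' @param numClasses class count of the final softmax.
#' @return a layer list for \code{\link{networkSpec}}.
#' @export
architecturePreset <- function(architecture = c("small", "default"),
                               numClasses = 4L) {
  architecture <- match.arg(architecture)
  if (architecture == "small") {
    list(list(type = "conv", channels = 8L, kernel = 3L),
         list(type = "relu"),
         list(type = "pool", window = 2L),
         list(type = "residual", channels = 8L, kernel = 3L),
         list(type = "relu"),
         list(type = "pool", window = 2L),
         list(type = "flatten"),
         list(type = "fc", units = numClasses))
  } else NULL   # networkSpec's own default: 2 residual blocks, 16/32 channels
}

stageSeed <- function(globalSeed, stage) {
  offsets <- c(data = 11L, init = 23L, train = 37L, bins = 53L, attack = 71L,
               regressor = 89L, twin = 97L)
  as.integer((as.numeric(globalSeed) * 1009 + offsets[[stage]]) %% 2147483647)
}

expDataset <- function(config) {
  if (!is.null(config$dataset$npz)) return(readFixture(config$dataset$npz))
  args <- config$dataset$synthetic %||% list()
  if (is.null(args$seed)) args$seed <- stageSeed(config$seed, "data")
  generateDataset(do.call(syntheticSpec, args))
}

configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA, null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

expLog <- function(outDir, ...) {
  line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), sprintf(...))
  cat(line, "\n", sep = "")
  cat(line, "\n", sep = "", file = file.path(outDir, "log.txt"), append = TRUE)
}

expBins <- function(config) {
  defaultNoiseBins(config$snrLevels, seed = stageSeed(config$seed, "bins"))
}

#' Run a failure-detection experiment
#'
#' Orchestrates the pipeline and writes CSV artifacts plus a manifest to
#' \code{config$outDir}. Stages: \code{train} (fit the VDP model and its
#' deterministic twin, write checkpoints), \code{evaluate} (per-bin prediction
#' records for both models), \code{curves} (per-bin accuracy, mean max softmax
#' probability, accuracy-probability gap and variance medians),
#' \code{attack} (attack bins with accuracies and variance medians),
#' \code{threshold-fit} (train the learned-threshold regressor),
#' \code{threshold-apply} (fixed and learned abstention reports),
#' \code{report} (run everything and summarize). A completed stage with an
#' unchanged config hash is skipped unless \code{force}.
#'
#' @param config an \code{\link{experimentConfig}} or a YAML path.
#' @param stage one of \code{"all"}, \code{"train"}, \code{"evaluate"},
#'   \code{"curves"}, \code{"attack"}, \code{"threshold-fit"},
#'   \code{"threshold-apply"}, \code{"report"}.
#' @param force re-run even when outputs exist for this config hash.
#' @return invisibly, the manifest list.
#' @export
runExperiment <- function(config, stage = "all", force = FALSE) {
  if (is.character(config)) config <- readExperimentConfig(config)
  stopifnot(inherits(config, "experimentConfig"))
  stages <- c("train", "evaluate", "curves", "attack", "threshold-fit",
              "threshold-apply")
  stage <- match.arg(stage, c("all", "report", stages))
  todo <- if (stage %in% c("all", "report")) stages else stage
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  hash <- configHash(config)
  manifestPath <- file.path(config$outDir, "manifest.json")
  manifest <- if (file.exists(manifestPath))
    jsonlite::read_json(manifestPath, simplifyVector = TRUE) else
    list(hash = hash, done = character())
  if (!identical(manifest$hash, hash)) {
    manifest <- list(hash = hash, done = character())
  }
  manifest$config <- unclass(config)
  manifest$rVersion <- as.character(getRversion())
  manifest$package <- as.character(utils::packageVersion("vdpnet"))
  for (st in todo) {
    outs <- stageOutputs(st, config$outDir)
    if (!force && st %in% manifest$done && all(file.exists(outs))) {
      expLog(config$outDir, "stage %s: up to date, skipping (use force to re-run)", st)
      next
    }
    res <- tryCatch({ runStage(st, config); NULL }, error = function(e) e)
    if (!is.null(res)) {
      unlink(outs)
      stop("stage '", st, "' failed (", conditionMessage(res),
           "); partial outputs removed", call. = FALSE)
    }
    manifest$done <- union(manifest$done, st)
    jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE, digits = NA)
  }
  if (stage == "report") writeSummaryReport(config)
  invisible(manifest)
}

stageOutputs <- function(st, outDir) {
  file.path(outDir, switch(st,
    train = c("vdp.json", "twin.json", "trainlog.csv"),
    evaluate = c("records_vdp.csv", "records_twin.csv"),
    curves = "curves.csv",
    attack = "attack.csv",
    `threshold-fit` = "regressor.json",
    `threshold-apply` = "thresholds.csv"))
}

loadModelOrStop <- function(outDir, which) {
  path <- file.path(outDir, paste0(which, ".json"))
  if (!file.exists(path))
    stop("no trained ", which, " checkpoint at '", path,
         "'; run the train stage first")
  loadCheckpoint(path)
}

runStage <- function(st, config) {
  outDir <- config$outDir
  d <- expDataset(config)
  K <- length(unique(d$train$labels))
  inputShape <- dim(d$train$images)[2:4]
  if (st == "train") {
    spec <- networkSpec(architecturePreset(config$architecture, K),
                        inputShape = inputShape, numClasses = K,
                        seed = stageSeed(config$seed, "init"))
    cfg <- lossConfig(N = nrow2(d$train$images), H = K,
                      jitter = config$train$jitter)
    expLog(outDir, "training VDP model (%d epochs)", config$train$epochs)
    net <- trainNetwork(buildNetwork(spec), d, epochs = config$train$epochs,
                        lr = config$train$lr,
                        batchSize = config$train$batchSize, config = cfg,
                        seed = stageSeed(config$seed, "train"))
    expLog(outDir, "training deterministic twin")
    twinSpec <- networkSpec(architecturePreset(config$architecture, K),
                            inputShape = inputShape, numClasses = K,
                            seed = stageSeed(config$seed, "init") + 1L)
    twin <- trainNetwork(deterministicTwin(buildNetwork(twinSpec)), d,
                         epochs = config$train$epochs,
                         lr = config$train$twinLr,
                         batchSize = config$train$batchSize,
                         seed = stageSeed(config$seed, "twin"))
    saveCheckpoint(net, file.path(outDir, "vdp.json"))
    saveCheckpoint(twin, file.path(outDir, "twin.json"))
    lg <- rbind(cbind(model = "vdp", trainLog(net)),
                cbind(model = "twin", trainLog(twin)))
    utils::write.csv(lg, file.path(outDir, "trainlog.csv"), row.names = FALSE)
  } else if (st == "evaluate") {
    net <- loadModelOrStop(outDir, "vdp")
    twin <- loadModelOrStop(outDir, "twin")
    recs <- NULL; recsT <- NULL
    for (b in expBins(config)) {
      Xb <- applyBin(b, d$test$images)
      recs <- rbind(recs, predictBatch(net, Xb, d$test$labels, bin = b$label))
      recsT <- rbind(recsT, predictBatch(twin, Xb, d$test$labels,
                                         bin = b$label))
      expLog(outDir, "evaluated bin %s", b$label)
    }
    utils::write.csv(recs, file.path(outDir, "records_vdp.csv"),
                     row.names = FALSE)
    utils::write.csv(recsT, file.path(outDir, "records_twin.csv"),
                     row.names = FALSE)
  } else if (st == "curves") {
    recs <- utils::read.csv(file.path(outDir, "records_vdp.csv"))
    recsT <- utils::read.csv(file.path(outDir, "records_twin.csv"))
    binOrder <- c("none", names(config$snrLevels))
    vs <- summarizeVariance(recs, binOrder)
    gap <- accuracyProbabilityGap(recsT)
    curves <- merge(vs, gap, by = "bin", suffixes = c("Vdp", "Twin"),
                    sort = FALSE)
    curves$snrDb <- c(NA, config$snrLevels)[match(curves$bin, binOrder)]
    utils::write.csv(curves, file.path(outDir, "curves.csv"),
                     row.names = FALSE)
  } else if (st == "attack") {
    net <- loadModelOrStop(outDir, "vdp")
    twin <- loadModelOrStop(outDir, "twin")
    set.seed(stageSeed(config$seed, "attack"))
    nTest <- nrow2(d$test$images)
    sub <- sample.int(nTest, min(config$attackSamples, nTest))
    X <- d$test$images[sub, , , , drop = FALSE]
    y <- d$test$labels[sub]
    rows <- NULL
    for (atk in config$attacks) {
      b <- noiseBin(paste0(atk$kind, "-", atk$epsilon), atk$kind,
                    epsilon = atk$epsilon, alpha = atk$alpha,
                    steps = atk$steps,
                    seed = stageSeed(config$seed, "attack"))
      Xa <- applyBin(b, X, model = net, labels = y)
      ra <- predictBatch(net, Xa, y, bin = b$label)
      rt <- predictBatch(twin, Xa, y, bin = b$label)
      vs <- summarizeVariance(ra)
      rows <- rbind(rows, data.frame(
        attack = atk$kind, level = atk$epsilon,
        accuracyDeterministic = 100 * mean(rt$correct),
        accuracyBdnn = 100 * mean(ra$correct),
        medianCombined = vs$medianCombined, medianCorrect = vs$medianCorrect,
        medianIncorrect = vs$medianIncorrect))
      expLog(outDir, "attack %s eps=%g done", atk$kind, atk$epsilon)
    }
    utils::write.csv(rows, file.path(outDir, "attack.csv"), row.names = FALSE)
  } else if (st == "threshold-fit") {
    net <- loadModelOrStop(outDir, "vdp")
    rspec <- do.call(thresholdRegressorSpec,
                     utils::modifyList(list(seed = stageSeed(config$seed,
                                                             "regressor")),
                                       config$regressor))
    reg <- trainThresholdRegressor(net, d$train$images,
                                   noiseLevels = unname(config$snrLevels),
                                   spec = rspec)
    payload <- list(spec = unclass(reg@spec), targetScale = reg@targetScale,
                    inputShape = inputShape,
                    params = serializeLayers(reg@net), fitLog = reg@fitLog)
    jsonlite::write_json(payload, file.path(outDir, "regressor.json"),
                         digits = NA, auto_unbox = TRUE)
  } else if (st == "threshold-apply") {
    net <- loadModelOrStop(outDir, "vdp")
    reg <- loadRegressor(file.path(outDir, "regressor.json"))
    recs <- utils::read.csv(file.path(outDir, "records_vdp.csv"))
    binOrder <- c("none", names(config$snrLevels))
    vs <- summarizeVariance(recs, binOrder)
    taus <- list(
      `fixed-correct` = selectFixedThreshold(vs, "correct-at-min-noise"),
      `fixed-combined` = selectFixedThreshold(vs, "combined-at-min-noise"))
    if (!is.null(config$manualThreshold))
      taus$`fixed-manual` <- config$manualThreshold
    rows <- NULL
    for (b in binOrder) {
      rb <- recs[recs$bin == b, ]
      Xb <- applyBin(expBins(config)[[match(b, binOrder)]], d$test$images)
      for (nm in names(taus)) {
        rep <- applyThreshold(rb, taus[[nm]])
        rows <- rbind(rows, data.frame(bin = b, thresholdType = nm,
                                       thresholdValue = taus[[nm]],
                                       preAccuracy = rep$preAccuracy,
                                       abstainedPct = rep$abstainedPct,
                                       postAccuracy = rep$postAccuracy))
      }
      repL <- applyLearnedThreshold(rb, Xb, reg)
      rows <- rbind(rows, data.frame(bin = b, thresholdType = "learned",
                                     thresholdValue = NA_real_,
                                     preAccuracy = repL$preAccuracy,
                                     abstainedPct = repL$abstainedPct,
                                     postAccuracy = repL$postAccuracy))
    }
    utils::write.csv(rows, file.path(outDir, "thresholds.csv"),
                     row.names = FALSE)
  }
  invisible(TRUE)
}

nrow2 <- function(x) if (is.matrix(x)) nrow(x) else dim(x)[1]

loadRegressor <- function(path) {
  if (!file.exists(path))
    stop("no trained regressor at '", path, "'; run threshold-fit first")
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  spec <- payload$spec
  inputShape <- as.integer(unlist(payload$inputShape))
  st <- initLayerStack(regressorLayers(spec$architecture, inputShape),
                       inputShape, initLogVar = 0, stochastic = FALSE)
  new("ThresholdRegressor",
      net = deserializeLayers(st$layers, payload$params),
      spec = lapply(spec, function(x) x),
      targetScale = lapply(payload$targetScale, as.numeric),
      fitLog = do.call(rbind, lapply(payload$fitLog, as.data.frame)))
}

writeSummaryReport <- function(config) {
  outDir <- config$outDir
  lines <- c("Failure-detection experiment summary",
             paste("config hash:", configHash(config)), "")
  for (f in c("curves.csv", "attack.csv", "thresholds.csv")) {
    p <- file.path(outDir, f)
    if (file.exists(p)) {
      lines <- c(lines, paste0("== ", f, " =="),
                 utils::capture.output(print(utils::read.csv(p))), "")
    }
  }
  writeLines(lines, file.path(outDir, "report.txt"))
  invisible(file.path(outDir, "report.txt"))
}
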