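# Experiment orchestration: the three arms of the comparison —
#   baseline : CNN trained and evaluated on the original images
#   cvae     : VAE (noiseFactor 0) reconstructs all partitions, CNN trained
#              and evaluated on the reconstructions
#   dvae     : as cvae with noiseFactor 0.2
# Seeds for the VAE and the CNN are derived independently from the master
# seed, so changing one model's seed never perturbs the other's checkpoint.

#' Configure a reconstruct-then-classify experiment
#'
#' @param data data source: a [DatasetBundle], a [PatchSet] (split with
#'   `splitSizes`), a path to a PNG class directory, a path to a patch
#'   archive, or `"synthetic"` for the built-in synthetic preset.
#' @param arms subset of `c("baseline", "cvae", "dvae")`.
#' @param seed master integer seed; VAE/CNN/data seeds derive from it.
#' @param vaeConfig base [vaeConfig()] for the VAE arms (noise factors are
#'   set per arm: 0 for `cvae`, `dvaeNoiseFactor` for `dvae`).
#' @param cnnConfig [cnnConfig()] shared by all arms.
#' @param dvaeNoiseFactor corruption scale of the denoising arm.
#' @param vaeSeed,cnnSeed optional explicit model seeds; by default each is
#'   derived independently from the master seed and the arm label, so
#'   overriding one never changes the other model's training.
#' @param nPerClass synthetic preset: images per class.
#' @param perClass balanced subsample size per class for directory input
#'   (`NULL` = use everything available, balanced to the smaller class).
#' @param splitSizes `c(train, test, validation)`; `NULL` derives a
#'   56/20/24 split (the proportions of the full-scale 28,000/10,000/12,000 protocol).
#' @param stratify stratify the split by class.
#' @param evalOnOriginal evaluate VAE arms on original rather than
#'   reconstructed test images (the reconstruction-throughout protocol is
#'   the default).
#' @param outDir optional output directory for the report, checkpoints and
#'   config echo.
#' @param textureParams [textureParams()] for the synthetic preset.
#' @return a validated named list.
#' @export
experimentConfig <- function(data = "synthetic",
                             arms = c("baseline", "cvae", "dvae"),
                             seed = 1L,
                             vaeConfig = histovae::vaeConfig(epochs = 10L),
                             cnnConfig = histovae::cnnConfig(epochs = 5L),
                             dvaeNoiseFactor = 0.2,
                             vaeSeed = NULL,
                             cnnSeed = NULL,
                             nPerClass = 300L,
                             perClass = NULL,
                             splitSizes = NULL,
                             stratify = FALSE,
                             evalOnOriginal = FALSE,
                             outDir = NULL,
                             textureParams = histovae::textureParams()) {
  if (length(arms) < 1L) stop("at least one arm required", call. = FALSE)
  arms <- match.arg(arms, c("baseline", "cvae", "dvae"), several.ok = TRUE)
  list(data = data, arms = arms, seed = as.integer(seed),
       vaeConfig = vaeConfig, cnnConfig = cnnConfig,
       dvaeNoiseFactor = dvaeNoiseFactor, vaeSeed = vaeSeed,
       cnnSeed = cnnSeed, nPerClass = as.integer(nPerClass),
       perClass = perClass, splitSizes = splitSizes, stratify = stratify,
       evalOnOriginal = evalOnOriginal, outDir = outDir,
       textureParams = textureParams)
}

# Default split proportions 56/20/24 (train/test/validation).
defaultSplitSizes <- function(n) {
  train <- floor(0.56 * n); test <- floor(0.20 * n)
  c(train, test, n - train - test)
}

# Resolve an experiment's data source to a DatasetBundle.
resolveData <- function(config) {
  src <- config$data
  if (is(src, "DatasetBundle")) return(src)
  if (is(src, "PatchSet")) {
    sizes <- config$splitSizes %||% defaultSplitSizes(length(src))
    return(splitDataset(src, sizes, deriveSeed(config$seed, saltOf("split")),
                        stratify = config$stratify))
  }
  if (is.character(src) && identical(src, "synthetic")) {
    ds <- generateDataset(config$nPerClass, config$textureParams,
                          seed = deriveSeed(config$seed, saltOf("synthetic")))
    sizes <- config$splitSizes %||% defaultSplitSizes(length(ds))
    return(splitDataset(ds, sizes, deriveSeed(config$seed, saltOf("split")),
                        stratify = config$stratify))
  }
  if (is.character(src) && length(src) == 1L) {
    if (dir.exists(src)) {
      patches <- loadPatchDir(src)
      if (!is.null(config$perClass))
        patches <- sampleBalanced(patches, config$perClass,
                                  deriveSeed(config$seed, saltOf("sample")))
      ds <- preprocessPatches(patches)
      sizes <- config$splitSizes %||% defaultSplitSizes(length(ds))
      return(splitDataset(ds, sizes, deriveSeed(config$seed, saltOf("split")),
                          stratify = config$stratify))
    }
    if (file.exists(src)) {
      obj <- loadPatchArchive(src)
      if (is(obj, "DatasetBundle")) return(obj)
      if (is(obj, "PatchSet")) {
        sizes <- config$splitSizes %||% defaultSplitSizes(length(obj))
        return(splitDataset(obj, sizes,
                            deriveSeed(config$seed, saltOf("split")),
                            stratify = config$stratify))
      }
      stop("archive does not contain a PatchSet or DatasetBundle",
           call. = FALSE)
    }
    stop("data source not found: ", src, call. = FALSE)
  }
  stop("unrecognised data source", call. = FALSE)
}

# Reconstruct every partition of a bundle through a trained VAE.
reconstructBundle <- function(vae, data, seed) {
  part <- function(ps, salt) {
    PatchSet(reconstruct(vae, ps, seed = deriveSeed(seed, saltOf(salt))),
             patchLabels(ps))
  }
  DatasetBundle(train = part(trainSet(data), "rec-train"),
                validation = part(validationSet(data), "rec-val"),
                test = part(testSet(data), "rec-test"),
                splitSeed = data@splitSeed)
}

#' Run one experimental arm
#'
#' `baseline` trains and evaluates the CNN on the original images. `cvae`
#' and `dvae` first train a VAE (noise factor 0 and `dvaeNoiseFactor`
#' respectively) on the training partition, reconstruct train, validation
#' and test partitions, then train the CNN on the reconstructions and
#' evaluate it on the reconstructed test partition (or the original one
#' under `evalOnOriginal`).
#'
#' @param arm `"baseline"`, `"cvae"` or `"dvae"`.
#' @param data a [DatasetBundle].
#' @param config an [experimentConfig()].
#' @return list with the [MetricReport] (`report`), the trained models
#'   (`cnn`, `vae` or `NULL`) and the seeds used.
#' @export
runArm <- function(arm, data, config) {
  if (!arm %in% c("baseline", "cvae", "dvae"))
    stop("unknown arm label: ", arm, call. = FALSE)
  vaeSeed <- config$vaeSeed %||% deriveSeed(config$seed, c(saltOf("vae"), saltOf(arm)))
  cnnSeed <- config$cnnSeed %||% deriveSeed(config$seed, c(saltOf("cnn"), saltOf(arm)))
  vae <- NULL
  if (arm == "baseline") {
    cnnData <- data
    evalData <- testSet(data)
  } else {
    vcfg <- config$vaeConfig
    vcfg$noiseFactor <- if (arm == "dvae") config$dvaeNoiseFactor else 0
    vcfg$seed <- vaeSeed
    vae <- trainVae(buildVae(vcfg), data)
    cnnData <- reconstructBundle(vae, data,
                                 deriveSeed(vaeSeed, saltOf("reconstruct")))
    evalData <- if (config$evalOnOriginal) testSet(data) else testSet(cnnData)
  }
  ccfg <- config$cnnConfig
  ccfg$seed <- cnnSeed
  cnn <- trainCnn(buildCnn(ccfg), cnnData)
  report <- evaluateModel(cnn, patchImages(evalData), patchLabels(evalData))
  list(report = report, cnn = cnn, vae = vae,
       seeds = list(vae = if (is.null(vae)) NA_integer_ else vaeSeed,
                    cnn = cnnSeed))
}

#' Run the full arm comparison
#'
#' Resolves the data source, runs every requested arm with independently
#' derived seeds, and assembles a [ComparisonReport]. A failing arm is
#' recorded with its error message while the remaining arms still run. With
#' `outDir` set, writes `report.csv` and `report.json` (metric rows in the
#' canonical order, one column per arm), model checkpoints and a config
#' echo.
#'
#' @param config an [experimentConfig()].
#' @return a [ComparisonReport]; failed arms are listed in
#'   `attr(, "failures")`.
#' @export
runExperiment <- function(config = experimentConfig()) {
  if (length(config$arms) < 1L) stop("at least one arm required", call. = FALSE)
  data <- resolveData(config)
  reports <- list(); models <- list(); failures <- list(); seeds <- list()
  for (arm in config$arms) {
    res <- tryCatch(runArm(arm, data, config), error = function(e) e)
    if (inherits(res, "error")) {
      failures[[arm]] <- conditionMessage(res)
      warning("arm '", arm, "' failed: ", conditionMessage(res),
              call. = FALSE)
    } else {
      reports[[arm]] <- res$report
      models[[arm]] <- res[c("cnn", "vae")]
      seeds[[arm]] <- res$seeds
    }
  }
  if (length(reports) == 0L)
    stop("every arm failed; first error: ", failures[[1]], call. = FALSE)
  out <- new("ComparisonReport", reports = reports,
             configs = list(experiment = config),
             seeds = c(list(master = config$seed), seeds))
  attr(out, "failures") <- failures
  if (!is.null(config$outDir)) writeExperimentOutputs(out, models, config)
  out
}

writeExperimentOutputs <- function(report, models, config) {
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  tab <- reportTable(report)
  utils::write.csv(tab, file.path(config$outDir, "report.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(metrics = tab, seeds = report@seeds,
         failures = attr(report, "failures")),
    file.path(config$outDir, "report.json"), auto_unbox = TRUE, digits = NA)
  for (arm in names(models)) {
    saveRDS(models[[arm]],
            file.path(config$outDir, paste0("checkpoint_", arm, ".rds")))
  }
  cfgEcho <- config
  cfgEcho$data <- if (is.character(config$data)) config$data else
    class(config$data)[1]
  cfgEcho$textureParams <- NULL
  saveRDS(config, file.path(config$outDir, "config.rds"))
  jsonlite::write_json(cfgEcho, file.path(config$outDir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(config$outDir)
}
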