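#' PatchSet: a batch of normalised grayscale patches with class labels
#'
#' The universal currency between pipeline stages: a rank-4 array of
#' `n` grayscale 64x64 images with intensities in `[0, 1]` (dimension order
#' `(n, 64, 64, 1)`), plus an integer class label in `{0, 1}` per image
#' (0 = IDC negative, 1 = IDC positive).
#'
#' @slot pixels numeric array `(n, 64, 64, 1)`, values in `[0, 1]`.
#' @slot labels integer vector of length `n` with values in `{0, 1}`.
#' @exportClass PatchSet
setClass("PatchSet",
  representation(pixels = "array", labels = "integer"))

setValidity("PatchSet", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 4L) return("pixels must be a rank-4 array (n, h, w, 1)")
  if (d[4] != 1L) return("pixels must have a single channel")
  if (d[2] != d[3]) return("pixels must be square")
  if (length(object@labels) != d[1])
    return("labels length must equal the number of images")
  if (d[1] > 0L) {
    r <- range(object@pixels)
    if (!is.finite(r[1]) || r[1] < 0 || r[2] > 1)
      return("pixel intensities must lie in [0, 1]")
    if (!all(object@labels %in% c(0L, 1L)))
      return("labels must be 0 or 1")
  }
  TRUE
})

#' DatasetBundle: train/validation/test partitions of a patch collection
#'
#' Holds the three disjoint partitions produced by [splitDataset()] (or
#' assembled directly), each a [PatchSet] with index-aligned labels.
#'
#' @slot train,validation,test [PatchSet] partitions.
#' @slot splitSeed integer seed used for the partitioning permutation
#'   (`NA` when the bundle was assembled manually).
#' @exportClass DatasetBundle
setClass("DatasetBundle",
  representation(train = "PatchSet", validation = "PatchSet",
                 test = "PatchSet", splitSeed = "integer"),
  prototype(splitSeed = NA_integer_))

#' TextureParams: parameters of the two-class synthetic texture generator
#'
#' Describes the blob phenotype of each synthetic class. Class 0 emulates
#' IDC-negative tissue (a few large pale blobs on a pale background), class 1
#' IDC-positive tissue (many small dark nucleus-like blobs). All intensity
#' levels live in `[0, 1]`; radii are in pixels.
#'
#' @slot blobCount integer matrix `2 x 2`; row = class, columns = inclusive
#'   (min, max) of the per-patch blob count.
#' @slot blobRadius numeric matrix `2 x 2`; row = class, columns = (min, max)
#'   blob radius in pixels.
#' @slot blobIntensity numeric length-2; blob fill level per class.
#' @slot backgroundLevel numeric scalar; background fill level.
#' @slot noiseSd numeric scalar; sd of additive Gaussian pixel noise.
#' @exportClass TextureParams
setClass("TextureParams",
  representation(blobCount = "matrix", blobRadius = "matrix",
                 blobIntensity = "numeric", backgroundLevel = "numeric",
                 noiseSd = "numeric"))

setValidity("TextureParams", function(object) {
  if (!all(dim(object@blobCount) == c(2L, 2L)) ||
      !all(dim(object@blobRadius) == c(2L, 2L)))
    return("blobCount and blobRadius must be 2 x 2 (class x min/max)")
  if (any(object@blobCount[, 1] > object@blobCount[, 2]) ||
      any(object@blobRadius[, 1] > object@blobRadius[, 2]))
    return("blob count/radius intervals must be non-empty (min <= max)")
  if (any(object@blobCount < 0)) return("blob counts must be non-negative")
  lv <- c(object@blobIntensity, object@backgroundLevel)
  if (length(object@blobIntensity) != 2L || any(lv < 0) || any(lv > 1))
    return("intensity levels must be length-2/scalar values in [0, 1]")
  if (length(object@noiseSd) != 1L || object@noiseSd < 0)
    return("noiseSd must be a single non-negative number")
  TRUE
})

# Shared representation for the two trainable models. `spec` is the ordered
# list of layer descriptors consumed by the engine, `params` the named list
# of weight arrays, `optState` the Adam moment estimates, `history` the
# per-epoch training log.
setClass("NeuralModel",
  representation(spec = "list", params = "list", optState = "list",
                 config = "list", history = "data.frame",
                 trained = "logical"),
  prototype(trained = FALSE, history = data.frame()),
  contains = "VIRTUAL")

#' VaeModel: convolutional variational autoencoder (optionally denoising)
#'
#' Encoder `(64,64,1) -> Conv(32,k3,s2) -> Conv(64,k3,s2) -> flatten(16384)
#' -> Dense(10, ReLU) -> [Dense(latentDim) mean, Dense(latentDim) log-var]
#' -> reparameterised sample`; decoder `latentDim -> Dense(16384, ReLU) ->
#' reshape(16,16,64) -> ConvT(64,k3,s2) -> ConvT(32,k3,s2) ->
#' ConvT(1,k3,s1, sigmoid)`. Built by [buildVae()], trained by [trainVae()].
#'
#' @exportClass VaeModel
setClass("VaeModel", contains = "NeuralModel")

#' CnnModel: the 10-layer patch classifier
#'
#' `input -> Conv(64,k3,s2) -> Conv(128,k3,s2) -> MaxPool(1,1) ->
#' Dropout(0.2) -> Conv(256,k3,s2) -> MaxPool(1,1) -> Dropout(0.2) ->
#' flatten(16384) -> Dense(2, sigmoid)`. Built by [buildCnn()], trained by
#' [trainCnn()].
#'
#' @exportClass CnnModel
setClass("CnnModel", contains = "NeuralModel")

#' MetricReport: the evaluation battery for one experimental arm
#'
#' Loss, accuracy and the two-class metric battery combined across classes
#' by support-weighted (default) or macro averaging.
#'
#' @slot loss,accuracy,precision,recall,f1,specificity,kappa,rocAuc numeric
#'   scalars in their natural ranges.
#' @slot averaging `"weighted"` or `"macro"`.
#' @exportClass MetricReport
setClass("MetricReport",
  representation(loss = "numeric", accuracy = "numeric",
                 precision = "numeric", recall = "numeric", f1 = "numeric",
                 specificity = "numeric", kappa = "numeric",
                 rocAuc = "numeric", averaging = "character"))

setValidity("MetricReport", function(object) {
  inUnit <- c(accuracy = object@accuracy, precision = object@precision,
              recall = object@recall, f1 = object@f1,
              specificity = object@specificity, rocAuc = object@rocAuc)
  bad <- names(inUnit)[!is.na(inUnit) & (inUnit < 0 | inUnit > 1)]
  if (length(bad)) return(paste0(paste(bad, collapse = ", "), " must lie in [0, 1]"))
  if (!is.na(object@kappa) && (object@kappa < -1 || object@kappa > 1))
    return("kappa must lie in [-1, 1]")
  if (!object@averaging %in% c("weighted", "macro"))
    return("averaging must be 'weighted' or 'macro'")
  TRUE
})

#' ComparisonReport: metric reports for the experimental arms
#'
#' One [MetricReport-class] per arm (`baseline`, `cvae`, `dvae`) plus the
#' configurations and seeds that produced them. [reportTable()] renders the
#' comparison in the canonical row schema.
#'
#' @slot reports named list of [MetricReport-class] objects, one per arm.
#' @slot configs named list of the per-arm configurations.
#' @slot seeds named list of the seeds used.
#' @exportClass ComparisonReport
setClass("ComparisonReport",
  representation(reports = "list", configs = "list", seeds = "list"))

setValidity("ComparisonReport", function(object) {
  if (length(object@reports) < 1L) return("at least one arm report required")
  if (is.null(names(object@reports)) || any(!nzchar(names(object@reports))))
    return("arm reports must be named")
  if (!all(vapply(object@reports, is, logical(1), "MetricReport")))
    return("every report must be a MetricReport")
  TRUE
})
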