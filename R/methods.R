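#' Construct a PatchSet
#'
#' @param pixels numeric array `(n, h, h, 1)` of intensities in `[0, 1]`.
#' @param labels integer-like vector of class labels in `{0, 1}`.
#' @return a [PatchSet].
#' @examples
#' ps <- PatchSet(array(0.5, c(2, 64, 64, 1)), c(0, 1))
#' patchLabels(ps)
#' @export
PatchSet <- function(pixels, labels) {
  new("PatchSet", pixels = pixels, labels = as.integer(labels))
}

#' Construct a DatasetBundle from three PatchSets
#'
#' @param train,validation,test [PatchSet] partitions.
#' @param splitSeed optional integer seed recorded from the splitting step.
#' @return a [DatasetBundle].
#' @export
DatasetBundle <- function(train, validation, test, splitSeed = NA_integer_) {
  new("DatasetBundle", train = train, validation = validation, test = test,
      splitSeed = as.integer(splitSeed))
}

#' @rdname histovae-generics
#' @export
setMethod("patchImages", "PatchSet", function(x) x@pixels)

#' @rdname histovae-generics
#' @export
setMethod("patchLabels", "PatchSet", function(x) x@labels)

#' @describeIn PatchSet number of patches.
#' @param x a `PatchSet`.
#' @export
setMethod("length", "PatchSet", function(x) dim(x@pixels)[1])

#' @describeIn PatchSet subset patches by index.
#' @param i index vector.
#' @param j,drop ignored.
#' @param ... ignored.
#' @export
setMethod("[", "PatchSet", function(x, i, j, ..., drop = FALSE) {
  PatchSet(x@pixels[i, , , , drop = FALSE], x@labels[i])
})

setMethod("show", "PatchSet", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("PatchSet: %d patches of %dx%d grayscale\n", d[1], d[2], d[3]))
  if (d[1] > 0) {
    tab <- table(factor(object@labels, levels = c(0, 1)))
    cat(sprintf("  labels: %d negative (0), %d positive (1)\n", tab[1], tab[2]))
    cat(sprintf("  intensity range: [%.3f, %.3f]\n",
                min(object@pixels), max(object@pixels)))
  }
})

#' @rdname histovae-generics
#' @export
setMethod("trainSet", "DatasetBundle", function(x) x@train)

#' @rdname histovae-generics
#' @export
setMethod("validationSet", "DatasetBundle", function(x) x@validation)

#' @rdname histovae-generics
#' @export
setMethod("testSet", "DatasetBundle", function(x) x@test)

setMethod("show", "DatasetBundle", function(object) {
  cat(sprintf("DatasetBundle: train %d / validation %d / test %d patches\n",
              length(object@train), length(object@validation),
              length(object@test)))
  if (!is.na(object@splitSeed))
    cat(sprintf("  split seed: %d\n", object@splitSeed))
})

#' @rdname histovae-generics
#' @export
setMethod("trainingHistory", "NeuralModel", function(object) object@history)

#' @rdname histovae-generics
#' @export
setMethod("isTrained", "NeuralModel", function(object) isTRUE(object@trained))

setMethod("show", "VaeModel", function(object) {
  cfg <- object@config
  kind <- if (cfg$noiseFactor > 0) "denoising (DVAE)" else "convolutional (CVAE)"
  cat(sprintf("VaeModel: %s, latent dim %d%s\n", kind, cfg$latentDim,
              if (cfg$noiseFactor > 0)
                sprintf(", noise factor %.3g", cfg$noiseFactor) else ""))
  cat(sprintf("  %s; %d parameters\n",
              if (isTRUE(object@trained))
                sprintf("trained %d epochs", nrow(object@history)) else "untrained",
              sum(vapply(object@params, length, integer(1)))))
})

setMethod("show", "CnnModel", function(object) {
  cat(sprintf("CnnModel: 10-layer strided CNN (filters 64/128/256), dropout %.2g\n",
              object@config$dropoutRate))
  cat(sprintf("  %s; %d parameters\n",
              if (isTRUE(object@trained))
                sprintf("trained %d epochs", nrow(object@history)) else "untrained",
              sum(vapply(object@params, length, integer(1)))))
})

# Canonical metric row labels of the comparison table.
metricRowLabels <- function() {
  c("Loss", "Accuracy", "Precision", "Recall or Sensitivity", "F1 Score",
    "Specificity", "Cohen's Kappa", "ROC AUC")
}

metricValues <- function(report) {
  c(report@loss, report@accuracy, report@precision, report@recall,
    report@f1, report@specificity, report@kappa, report@rocAuc)
}

setMethod("show", "MetricReport", function(object) {
  cat(sprintf("MetricReport (%s averaging)\n", object@averaging))
  v <- metricValues(object)
  for (i in seq_along(v))
    cat(sprintf("  %-22s %.4f\n", metricRowLabels()[i], v[i]))
})

#' @describeIn reportTable render a single report as a two-column data frame.
#' @export
setMethod("reportTable", "MetricReport", function(object, ...) {
  data.frame(Metric = metricRowLabels(), Value = metricValues(object),
             stringsAsFactors = FALSE)
})

#' @describeIn reportTable render the arm comparison: one metric per row,
#'   one column per arm.
#' @export
setMethod("reportTable", "ComparisonReport", function(object, ...) {
  out <- data.frame(Metric = metricRowLabels(), stringsAsFactors = FALSE)
  for (arm in names(object@reports))
    out[[arm]] <- metricValues(object@reports[[arm]])
  out
})

#' Access the per-arm reports of a ComparisonReport
#'
#' `report$arm` and `report[[arm]]` extract one arm's [MetricReport];
#' `names(report)` lists the arm labels.
#'
#' @param x a `ComparisonReport`.
#' @param name,i arm label (`"baseline"`, `"cvae"`, `"dvae"`) or index.
#' @param ... ignored.
#' @name ComparisonReport-access
#' @rdname ComparisonReport-access
NULL

#' @rdname ComparisonReport-access
#' @export
setMethod("$", "ComparisonReport", function(x, name) x@reports[[name]])

#' @rdname ComparisonReport-access
#' @export
setMethod("[[", "ComparisonReport", function(x, i, ...) x@reports[[i]])

#' @rdname ComparisonReport-access
#' @export
setMethod("names", "ComparisonReport", function(x) names(x@reports))

setMethod("show", "ComparisonReport", function(object) {
  cat("ComparisonReport\n")
  tab <- reportTable(object)
  fmt <- format(tab, digits = 4)
  writeLines(paste0("  ", capture.output(print(fmt, row.names = FALSE))))
})
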