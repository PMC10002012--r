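#' @name histovae-generics
#' @title Accessor and action generics
#' @description Accessors for the package's S4 containers and the shared
#'   model actions (`reconstruct`, `trainingHistory`, `isTrained`).
#' @param object,x an S4 object from this package.
#' @param ... passed to methods.
NULL

#' @rdname histovae-generics
#' @export
setGeneric("patchImages", function(x) standardGeneric("patchImages"))

#' @rdname histovae-generics
#' @export
setGeneric("patchLabels", function(x) standardGeneric("patchLabels"))

#' @rdname histovae-generics
#' @export
setGeneric("trainSet", function(x) standardGeneric("trainSet"))

#' @rdname histovae-generics
#' @export
setGeneric("validationSet", function(x) standardGeneric("validationSet"))

#' @rdname histovae-generics
#' @export
setGeneric("testSet", function(x) standardGeneric("testSet"))

#' @rdname histovae-generics
#' @export
setGeneric("trainingHistory", function(object) standardGeneric("trainingHistory"))

#' @rdname histovae-generics
#' @export
setGeneric("isTrained", function(object) standardGeneric("isTrained"))

#' Reconstruct an image batch through a trained autoencoder
#'
#' @param object a [VaeModel].
#' @param batch a [PatchSet] or a numeric array `(n, 64, 64, 1)` in `[0, 1]`.
#' @param ... method arguments (`seed`, `deterministic`, `batchSize`).
#' @return an array `(n, 64, 64, 1)` of reconstructions in `(0, 1)`.
#' @export
setGeneric("reconstruct", function(object, batch, ...) standardGeneric("reconstruct"))

#' @rdname histovae-generics
#' @export
setGeneric("reportTable", function(object, ...) standardGeneric("reportTable"))
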