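# Seeded two-class synthetic texture generator. The phenotypes emulate the
# grayscale appearance of the two patch classes: class 0 (IDC negative) has
# a few large pale blobs on a pale background, class 1 (IDC positive) has
# many small dark nucleus-like blobs. This is a statistical stand-in, not a
# histology simulation; its job is to give downstream stages a separable,
# fully reproducible two-class image population.

#' Default synthetic texture parameters
#'
#' Defaults are chosen so the two classes differ strongly in blob density
#' and darkness, making them easily separable by a small CNN: class 0 draws
#' 3-6 blobs of radius 6-10 px at level 0.65, class 1 draws 25-40 blobs of
#' radius 2-4 px at level 0.25, both on a 0.85 background with additive
#' Gaussian noise (sd 0.05) clipped to `[0, 1]`.
#'
#' @param blobCount integer `2 x 2` matrix (row = class, cols = min/max).
#' @param blobRadius numeric `2 x 2` matrix (row = class, cols = min/max), px.
#' @param blobIntensity per-class blob fill level in `[0, 1]`.
#' @param backgroundLevel background fill level in `[0, 1]`.
#' @param noiseSd sd of additive Gaussian pixel noise.
#' @return a [TextureParams] object.
#' @export
textureParams <- function(blobCount = rbind(c(3L, 6L), c(25L, 40L)),
                          blobRadius = rbind(c(6, 10), c(2, 4)),
                          blobIntensity = c(0.65, 0.25),
                          backgroundLevel = 0.85,
                          noiseSd = 0.05) {
  new("TextureParams",
      blobCount = matrix(as.integer(blobCount), 2L, 2L),
      blobRadius = matrix(as.numeric(blobRadius), 2L, 2L),
      blobIntensity = as.numeric(blobIntensity),
      backgroundLevel = as.numeric(backgroundLevel),
      noiseSd = as.numeric(noiseSd))
}

#' Generate one synthetic 64 x 64 grayscale patch
#'
#' Background filled at `backgroundLevel`; a seeded number of filled discs
#' with class-dependent count, radius and intensity composited by
#' darkest-wins (min); Gaussian noise added; clipped to `[0, 1]`. The same
#' `(label, params, seed)` triple always yields the identical image.
#'
#' @param label class index, 0 or 1.
#' @param params a [TextureParams].
#' @param seed integer seed.
#' @param size image side length.
#' @return numeric matrix `size x size` with values in `[0, 1]`.
#' @export
generatePatch <- function(label, params = textureParams(), seed = 1L,
                          size = 64L) {
  if (!label %in% c(0, 1)) stop("label must be 0 or 1", call. = FALSE)
  validObject(params)
  cls <- label + 1L
  withSeed(seed, {
    img <- matrix(params@backgroundLevel, size, size)
    cr <- params@blobCount[cls, ]
    nBlobs <- if (cr[1] == cr[2]) cr[1] else sample(cr[1]:cr[2], 1L)
    if (nBlobs > 0) {
      xs <- runif(nBlobs, 1, size)
      ys <- runif(nBlobs, 1, size)
      rs <- runif(nBlobs, params@blobRadius[cls, 1], params@blobRadius[cls, 2])
      rowc <- matrix(seq_len(size), size, size)
      colc <- matrix(seq_len(size), size, size, byrow = TRUE)
      for (b in seq_len(nBlobs)) {
        inside <- (rowc - xs[b])^2 + (colc - ys[b])^2 <= rs[b]^2
        img[inside] <- pmin(img[inside], params@blobIntensity[cls])
      }
    }
    if (params@noiseSd > 0)
      img <- img + matrix(rnorm(size * size, 0, params@noiseSd), size, size)
    pmin(pmax(img, 0), 1)
  })
}

#' Generate a balanced synthetic two-class dataset
#'
#' `2 * nPerClass` patches with exactly balanced labels. Each image's seed is
#' derived from `(seed, label, within-class index)`, so the first `k` images
#' of a class are identical across runs regardless of `nPerClass`.
#'
#' @param nPerClass images per class (>= 1).
#' @param params a [TextureParams].
#' @param seed master integer seed.
#' @param size image side length.
#' @return a [PatchSet]: class 0 block followed by class 1 block.
#' @export
generateDataset <- function(nPerClass, params = textureParams(), seed = 1L,
                            size = 64L) {
  if (nPerClass < 1L) stop("nPerClass must be >= 1", call. = FALSE)
  n <- 2L * nPerClass
  pixels <- array(0, c(n, size, size, 1))
  labels <- rep(0:1, each = nPerClass)
  for (i in seq_len(n)) {
    lab <- labels[i]
    k <- if (lab == 0L) i else i - nPerClass
    pixels[i, , , 1] <- generatePatch(lab, params,
                                      seed = deriveSeed(seed, c(lab, k)),
                                      size = size)
  }
  PatchSet(pixels, labels)
}

#' Write a dataset as a PNG class-directory tree
#'
#' Writes 8-bit grayscale PNGs under `root/0` and `root/1`, the layout
#' [loadPatchDir()] reads, so a write/load cycle round-trips labels exactly
#' and pixels to within 1/255 (8-bit quantisation).
#'
#' @param dataset a [PatchSet].
#' @param rootPath output directory (created if needed).
#' @return `rootPath`, invisibly.
#' @export
writePatchDir <- function(dataset, rootPath) {
  if (!is(dataset, "PatchSet")) stop("dataset must be a PatchSet",
                                     call. = FALSE)
  if (length(dataset) == 0L) stop("refusing to write an empty dataset",
                                  call. = FALSE)
  ok <- dir.create(rootPath, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(rootPath))
    stop("cannot create output directory: ", rootPath, call. = FALSE)
  labels <- patchLabels(dataset)
  pixels <- patchImages(dataset)
  for (cls in 0:1) dir.create(file.path(rootPath, cls), showWarnings = FALSE)
  counter <- c(0L, 0L)
  for (i in seq_len(length(dataset))) {
    cls <- labels[i]
    counter[cls + 1L] <- counter[cls + 1L] + 1L
    f <- file.path(rootPath, cls,
                   sprintf("patch_%05d.png", counter[cls + 1L]))
    png::writePNG(pixels[i, , , 1], f)
  }
  invisible(rootPath)
}
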