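# Preprocessing: labelled PNG patch directories -> normalised 64x64
# grayscale PatchSets, balanced subsampling and seeded train/test/validation
# splitting. Operation order is grayscale -> resize -> normalise, so
# interpolation happens on integer-scale intensities.

#' Load labelled patch images from a class-directory layout
#'
#' Reads every PNG under `root/0` and `root/1` (the layout of the IDC
#' patch dataset: one subdirectory per class). Files are ordered
#' lexicographically by path so later seeded sampling depends only on the
#' seed, never on filesystem enumeration order. Grayscale PNGs are expanded
#' to three identical channels; alpha channels are dropped. Unreadable files
#' are skipped with a warning.
#'
#' @param rootPath directory containing class subdirectories `"0"` and `"1"`.
#' @return a list of raw patches; each element has `pixels` (integer array
#'   `(h, w, 3)` in 0-255), `label` (0 or 1) and `sourcePath`.
#' @export
loadPatchDir <- function(rootPath) {
  if (!dir.exists(rootPath))
    stop("patch root directory does not exist: ", rootPath, call. = FALSE)
  patches <- list()
  for (cls in c("0", "1")) {
    sub <- file.path(rootPath, cls)
    if (!dir.exists(sub))
      stop("missing class subdirectory '", cls, "' under ", rootPath,
           call. = FALSE)
    files <- sort(list.files(sub, pattern = "\\.png$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0L)
      stop("class subdirectory '", cls, "' under ", rootPath,
           " contains no PNG files", call. = FALSE)
    for (f in files) {
      img <- tryCatch(png::readPNG(f), error = function(e) {
        warning("skipping unreadable PNG: ", f, call. = FALSE)
        NULL
      })
      if (is.null(img)) next
      if (is.matrix(img)) img <- array(rep(img, 3L), c(dim(img), 3L))
      if (length(dim(img)) == 3L && dim(img)[3] >= 4L)
        img <- img[, , 1:3, drop = FALSE]
      if (length(dim(img)) == 3L && dim(img)[3] == 2L)      # gray + alpha
        img <- array(rep(img[, , 1L], 3L), c(dim(img)[1:2], 3L))
      patches[[length(patches) + 1L]] <- list(
        pixels = array(as.integer(round(img * 255)), dim(img)),
        label = as.integer(cls), sourcePath = f)
    }
  }
  patches
}

#' Convert an RGB patch to grayscale (ITU-R BT.601 luma)
#'
#' `Y = 0.299 R + 0.587 G + 0.114 B`, rounded to the nearest integer — the
#' default conversion of mainstream image libraries. An image whose three
#' channels are equal maps exactly onto that channel.
#'
#' @param patch a raw patch from [loadPatchDir()] or an integer array
#'   `(h, w, 3)` with values 0-255.
#' @return integer matrix `(h, w)`.
#' @examples
#' toGrayscale(array(c(255L, 0L, 0L), c(1, 1, 3)))  # pure red -> 76
#' @export
toGrayscale <- function(patch) {
  px <- if (is.list(patch)) patch$pixels else patch
  d <- dim(px)
  if (length(d) != 3L || d[3] != 3L)
    stop("grayscale conversion expects a 3-channel (h, w, 3) image",
         call. = FALSE)
  y <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  matrix(as.integer(round(y)), d[1], d[2])
}

#' Resize a single-channel image to 64 x 64 by bilinear interpolation
#'
#' Uses the half-pixel-centre sampling grid with edge clamping: target pixel
#' centre `(i + 0.5)` maps to source coordinate `(i + 0.5) * h/64 - 0.5`.
#' A constant image stays constant and a 64x64 input is returned unchanged
#' (up to numeric type).
#'
#' @param image numeric matrix `(h, w)`, `h, w >= 2`.
#' @param size target side length (64 for this pipeline).
#' @return numeric matrix `size x size`.
#' @export
resize64 <- function(image, size = 64L) {
  if (!is.matrix(image)) stop("resize expects a single-channel matrix",
                              call. = FALSE)
  h <- nrow(image); w <- ncol(image)
  if (h < 2L || w < 2L)
    stop("degenerate image: both dimensions must be >= 2", call. = FALSE)
  image <- matrix(as.numeric(image), h, w)
  interpAxis <- function(nSrc, nDst) {
    src <- (seq_len(nDst) - 0.5) * nSrc / nDst - 0.5
    src <- pmin(pmax(src, 0), nSrc - 1)
    i0 <- pmin(floor(src), nSrc - 2)
    list(i0 = as.integer(i0) + 1L, frac = src - i0)
  }
  ax <- interpAxis(h, size); ay <- interpAxis(w, size)
  top <- image[ax$i0, ay$i0, drop = FALSE]
  bot <- image[ax$i0 + 1L, ay$i0, drop = FALSE]
  topR <- image[ax$i0, ay$i0 + 1L, drop = FALSE]
  botR <- image[ax$i0 + 1L, ay$i0 + 1L, drop = FALSE]
  fx <- matrix(ax$frac, size, size)
  fy <- matrix(ay$frac, size, size, byrow = TRUE)
  (1 - fy) * ((1 - fx) * top + fx * bot) +
    fy * ((1 - fx) * topR + fx * botR)
}

#' Normalise integer-scale intensities to [0, 1]
#'
#' Divides by 255 and assembles a [PatchSet]. Accepts a list of
#' single-channel 64x64 matrices (with labels) or a rank-4 array.
#'
#' @param images numeric array `(n, 64, 64, 1)` (or list of `64 x 64`
#'   matrices) with values in 0-255.
#' @param labels class labels aligned with `images`.
#' @return a [PatchSet].
#' @export
normalizeImages <- function(images, labels) {
  if (is.list(images)) {
    n <- length(images)
    arr <- array(0, c(n, 64, 64, 1))
    for (i in seq_len(n)) arr[i, , , 1] <- images[[i]]
    images <- arr
  }
  r <- range(images)
  if (!is.finite(r[1]) || r[1] < 0 || r[2] > 255)
    stop("intensities outside 0-255 cannot be normalised", call. = FALSE)
  PatchSet(images / 255, labels)
}

#' Draw a balanced subsample of raw patches
#'
#' Selects exactly `perClass` patches per class without replacement, using a
#' seeded generator after lexicographic ordering by source path, so the
#' selection is a function of the seed alone.
#'
#' @param patches list of raw patches from [loadPatchDir()].
#' @param perClass number of patches to keep per class.
#' @param seed integer seed.
#' @return list of raw patches, class 0 block then class 1 block.
#' @export
sampleBalanced <- function(patches, perClass, seed) {
  labels <- vapply(patches, function(p) p$label, integer(1))
  paths <- vapply(patches, function(p) p$sourcePath %||% "", character(1))
  out <- list()
  withSeed(seed, {
    for (cls in 0:1) {
      idx <- which(labels == cls)
      idx <- idx[order(paths[idx])]
      if (length(idx) < perClass)
        stop(sprintf("class %d has only %d patches; %d requested per class",
                     cls, length(idx), perClass), call. = FALSE)
      out <- c(out, patches[sort(sample(idx, perClass))])
    }
  })
  out
}

#' Seeded train/test/validation index partition
#'
#' A single seeded permutation of `1:n` sliced into contiguous blocks, in the
#' order train, test, validation.
#'
#' @param n total sample count.
#' @param sizes integer vector `c(train, test, validation)`; must sum to `n`.
#' @param seed integer seed.
#' @param labels optional class labels; when supplied with
#'   `stratify = TRUE`, each class is permuted and allocated proportionally
#'   (largest-remainder rounding) so partitions preserve class balance.
#' @param stratify logical.
#' @return named list of integer index vectors `train`, `test`, `validation`.
#' @export
splitIndices <- function(n, sizes, seed, labels = NULL, stratify = FALSE) {
  sizes <- as.integer(sizes)
  if (length(sizes) != 3L || any(sizes < 0L))
    stop("sizes must be three non-negative counts (train, test, validation)",
         call. = FALSE)
  if (sum(sizes) != n)
    stop(sprintf("split sizes %s sum to %d but %d samples were supplied",
                 paste(sizes, collapse = "/"), sum(sizes), n), call. = FALSE)
  withSeed(seed, {
    if (!stratify || is.null(labels)) {
      perm <- sample.int(n)
    } else {
      # Per-class pools carved sequentially into the three partitions with
      # largest-remainder rounding, capped by what remains of each pool, so
      # partition sizes are exact and pools are never overrun.
      classes <- sort(unique(labels))
      pools <- lapply(classes, function(cl) sample(which(labels == cl)))
      remaining <- vapply(pools, length, integer(1))
      taken <- integer(length(classes))
      perm <- unlist(lapply(1:3, function(j) {
        if (j < 3L) {
          raw <- sizes[j] * remaining / sum(remaining)
          a <- pmin(as.integer(floor(raw)), remaining)
          while (sum(a) < sizes[j]) {
            cand <- which(a < remaining)
            pick <- cand[which.max(raw[cand] - a[cand])]
            a[pick] <- a[pick] + 1L
          }
        } else a <- remaining
        sel <- unlist(lapply(seq_along(classes), function(ci) {
          pools[[ci]][taken[ci] + seq_len(a[ci])]
        }))
        taken <<- taken + a
        remaining <<- remaining - a
        sample(sel)
      }))
    }
  })
  list(train = perm[seq_len(sizes[1])],
       test = perm[sizes[1] + seq_len(sizes[2])],
       validation = perm[sizes[1] + sizes[2] + seq_len(sizes[3])])
}

#' Split a patch collection into train/test/validation partitions
#'
#' @param batch a [PatchSet] (or rank-4 pixel array).
#' @param labels labels when `batch` is a bare array.
#' @param sizes `c(train, test, validation)` counts summing to the batch size.
#' @param seed integer seed.
#' @param stratify preserve class proportions across partitions.
#' @return a [DatasetBundle]; the index partition is attached as
#'   `attr(, "indices")`.
#' @export
splitDataset <- function(batch, sizes, seed, labels = NULL, stratify = FALSE) {
  if (is(batch, "PatchSet")) {
    labels <- patchLabels(batch)
    pixels <- patchImages(batch)
  } else {
    pixels <- asPixelArray(batch)
    if (is.null(labels)) stop("labels required with a bare pixel array",
                              call. = FALSE)
    labels <- as.integer(labels)
  }
  n <- dim(pixels)[1]
  idx <- splitIndices(n, sizes, seed, labels = labels, stratify = stratify)
  part <- function(i) PatchSet(pixels[i, , , , drop = FALSE], labels[i])
  out <- DatasetBundle(train = part(idx$train),
                       validation = part(idx$validation),
                       test = part(idx$test),
                       splitSeed = seed)
  attr(out, "indices") <- idx
  out
}

#' Preprocess raw patches into a normalised PatchSet
#'
#' Applies the full chain grayscale -> bilinear resize to 64x64 ->
#' divide-by-255 normalisation.
#'
#' @param patches list of raw patches from [loadPatchDir()].
#' @return a [PatchSet].
#' @export
preprocessPatches <- function(patches) {
  if (length(patches) == 0L) stop("no patches to preprocess", call. = FALSE)
  imgs <- lapply(patches, function(p) resize64(toGrayscale(p)))
  labels <- vapply(patches, function(p) p$label, integer(1))
  normalizeImages(imgs, labels)
}

#' Save / load a preprocessed dataset archive
#'
#' Single-file archive of a [DatasetBundle] (or [PatchSet]) with the seed and
#' partition sizes recorded alongside.
#'
#' @param data a [DatasetBundle] or [PatchSet].
#' @param file archive path.
#' @param meta optional named list recorded with the data (seeds, sizes).
#' @return `file`, invisibly (for `savePatchArchive`); the stored object with
#'   metadata in `attr(, "meta")` (for `loadPatchArchive`).
#' @export
savePatchArchive <- function(data, file, meta = list()) {
  saveRDS(list(data = data, meta = meta,
               written = format(Sys.time(), tz = "UTC")), file)
  invisible(file)
}

#' @rdname savePatchArchive
#' @export
loadPatchArchive <- function(file) {
  obj <- readRDS(file)
  out <- obj$data
  attr(out, "meta") <- obj$meta
  out
}
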