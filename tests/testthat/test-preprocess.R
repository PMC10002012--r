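test_that("grayscale conversion uses BT.601 luma with integer rounding", {
  mono <- function(r, g, b) array(rep(c(r, g, b), each = 4L), c(2, 2, 3))
  expect_equal(toGrayscale(mono(255L, 255L, 255L)), matrix(255L, 2, 2))
  expect_equal(toGrayscale(mono(0L, 0L, 0L)), matrix(0L, 2, 2))
  # 0.299 * 255 = 76.245 -> 76
  expect_equal(toGrayscale(mono(255L, 0L, 0L)), matrix(76L, 2, 2))
  # equal channels come back exactly
  set.seed(3)
  v <- matrix(sample(0:255, 30, replace = TRUE), 5, 6)
  expect_equal(toGrayscale(array(rep(v, 3), c(5, 6, 3))), v)
  expect_error(toGrayscale(array(0L, c(4, 4, 2))), "3-channel")
})

test_that("bilinear resize matches a scalar-loop oracle and its fixed points", {
  # constant image -> constant, same value
  expect_equal(resize64(matrix(7, 50, 50)), matrix(7, 64, 64))
  # 64x64 input unchanged
  set.seed(4)
  img <- matrix(runif(64 * 64, 0, 255), 64, 64)
  expect_equal(resize64(img), img)
  # linear horizontal ramp stays monotone along rows
  ramp <- matrix(rep(seq(0, 255, length.out = 50), each = 50), 50, 50)
  out <- resize64(ramp)
  expect_true(all(diff(t(out)) >= -1e-9))
  # random small images against the brute-force oracle
  for (d in list(c(7, 9), c(50, 50), c(2, 5))) {
    x <- matrix(runif(prod(d), 0, 255), d[1], d[2])
    expect_equal(resize64(x), bruteBilinear(x), tolerance = 1e-12)
  }
  expect_error(resize64(matrix(1, 1, 10)), "degenerate")
})

test_that("normalisation divides by 255 and enforces the 0-255 domain", {
  imgs <- array(0, c(3, 64, 64, 1))
  imgs[1, , , ] <- 255; imgs[2, , , ] <- 0; imgs[3, , , ] <- 51
  ps <- normalizeImages(imgs, c(0, 1, 0))
  expect_equal(patchImages(ps)[1, 1, 1, 1], 1)
  expect_equal(patchImages(ps)[2, 1, 1, 1], 0)
  expect_equal(patchImages(ps)[3, 1, 1, 1], 0.2)
  expect_error(normalizeImages(array(300, c(1, 64, 64, 1)), 0), "0-255")
  expect_error(normalizeImages(array(-1, c(1, 64, 64, 1)), 0), "0-255")
  # bounded for arbitrary valid input, and x/255*255 round-trips
  set.seed(9)
  r <- array(runif(2 * 64 * 64, 0, 255), c(2, 64, 64, 1))
  px <- patchImages(normalizeImages(r, c(0, 1)))
  expect_true(all(px >= 0 & px <= 1))
  expect_equal(px * 255, r)
})

test_that("balanced sampling is seeded, exact and validates class sizes", {
  mkPatch <- function(lab, i) list(pixels = array(0L, c(5, 5, 3)),
                                   label = lab,
                                   sourcePath = sprintf("p%02d_%d", i, lab))
  pool <- c(lapply(1:30, mkPatch, lab = 0L), lapply(1:30, mkPatch, lab = 1L))
  s1 <- sampleBalanced(pool, 10L, seed = 1L)
  s2 <- sampleBalanced(pool, 10L, seed = 1L)
  s3 <- sampleBalanced(pool, 10L, seed = 2L)
  labs <- vapply(s1, `[[`, integer(1), "label")
  expect_length(s1, 20L)
  expect_equal(sum(labs == 0L), 10L)
  expect_equal(sum(labs == 1L), 10L)
  expect_identical(s1, s2)
  expect_false(identical(
    vapply(s1, `[[`, character(1), "sourcePath"),
    vapply(s3, `[[`, character(1), "sourcePath")))
  # exact per-class count for every seed
  for (seed in 1:10) {
    labs <- vapply(sampleBalanced(pool, 7L, seed), `[[`, integer(1), "label")
    expect_equal(unname(table(labs)), c(7L, 7L), ignore_attr = TRUE)
  }
  expect_error(sampleBalanced(pool, 31L, seed = 1L), "class 0 has only 30")
})

test_that("splitting partitions exactly, disjointly and reproducibly", {
  idx <- splitIndices(10L, c(6L, 2L, 2L), seed = 5L)
  expect_identical(idx, splitIndices(10L, c(6L, 2L, 2L), seed = 5L))
  expect_equal(lengths(idx), c(train = 6L, test = 2L, validation = 2L))
  expect_equal(sort(unname(unlist(idx))), 1:10)
  expect_error(splitIndices(10L, c(6L, 2L, 1L), seed = 1L), "sum to 9")
  # partition property over several n / seeds
  for (seed in 1:5) {
    n <- 30L
    idx <- splitIndices(n, c(17L, 6L, 7L), seed)
    expect_equal(sort(unname(unlist(idx))), seq_len(n))
    expect_length(intersect(idx$train, idx$test), 0L)
    expect_length(intersect(idx$train, idx$validation), 0L)
    expect_length(intersect(idx$test, idx$validation), 0L)
  }
})

test_that("stratified splitting preserves class balance at exact sizes", {
  labels <- rep(c(0L, 1L), c(40L, 20L))
  idx <- splitIndices(60L, c(30L, 15L, 15L), seed = 3L,
                      labels = labels, stratify = TRUE)
  expect_equal(lengths(idx), c(train = 30L, test = 15L, validation = 15L))
  expect_equal(sort(unname(unlist(idx))), 1:60)
  expect_equal(sum(labels[idx$train] == 1L), 10L)
  expect_equal(sum(labels[idx$test] == 1L), 5L)
})

test_that("splitDataset carries aligned labels into a DatasetBundle", {
  ds <- tinyDataset(5L)
  bundle <- splitDataset(ds, c(6L, 2L, 2L), seed = 7L)
  expect_s4_class(bundle, "DatasetBundle")
  expect_equal(length(trainSet(bundle)), 6L)
  expect_equal(length(testSet(bundle)), 2L)
  expect_equal(length(validationSet(bundle)), 2L)
  idx <- attr(bundle, "indices")
  expect_equal(patchLabels(trainSet(bundle)), patchLabels(ds)[idx$train])
  expect_equal(patchImages(testSet(bundle)),
               patchImages(ds)[idx$test, , , , drop = FALSE])
})

test_that("patch directories load with labels from the class subfolders", {
  root <- withr::local_tempdir()
  for (cls in c("0", "1")) dir.create(file.path(root, cls))
  set.seed(2)
  for (i in 1:3)
    png::writePNG(matrix(runif(25), 5, 5),
                  file.path(root, "0", sprintf("a%d.png", i)))
  for (i in 1:2)
    png::writePNG(matrix(runif(25), 5, 5),
                  file.path(root, "1", sprintf("b%d.png", i)))
  patches <- loadPatchDir(root)
  expect_length(patches, 5L)
  expect_equal(vapply(patches, `[[`, integer(1), "label"),
               c(0L, 0L, 0L, 1L, 1L))
  expect_equal(dim(patches[[1]]$pixels), c(5L, 5L, 3L))

  unlink(file.path(root, "1", c("b1.png", "b2.png")))
  expect_error(loadPatchDir(root), "'1'")
  expect_error(loadPatchDir(file.path(root, "missing")), "does not exist")
})

test_that("preprocessing chains grayscale, resize and normalisation", {
  set.seed(5)
  px <- array(sample(0:255, 50 * 50 * 3, replace = TRUE), c(50, 50, 3))
  patches <- list(list(pixels = px, label = 1L, sourcePath = "x"))
  ps <- preprocessPatches(patches)
  expect_s4_class(ps, "PatchSet")
  expect_equal(dim(patchImages(ps)), c(1L, 64L, 64L, 1L))
  expect_equal(patchImages(ps)[1, , , 1],
               bruteBilinear(matrix(as.numeric(toGrayscale(px)), 50, 50)) / 255,
               tolerance = 1e-12)
})

test_that("patch archives round-trip data and metadata", {
  f <- withr::local_tempfile(fileext = ".rds")
  ds <- tinyDataset(3L)
  savePatchArchive(ds, f, meta = list(seed = 11L, sizes = c(4L, 1L, 1L)))
  back <- loadPatchArchive(f)
  expect_equal(patchImages(back), patchImages(ds))
  expect_equal(attr(back, "meta")$seed, 11L)
})
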