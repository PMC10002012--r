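# Independent brute-force oracles. Deliberately written as naive scalar
# loops, sharing no code with the package implementations they check.

bruteConfusion <- function(yTrue, yPred) {
  cm <- matrix(0L, 2, 2)
  for (k in seq_along(yTrue))
    cm[yTrue[k] + 1L, yPred[k] + 1L] <- cm[yTrue[k] + 1L, yPred[k] + 1L] + 1L
  cm
}

# Per-class one-vs-rest metrics combined by support weighting.
bruteBattery <- function(yTrue, yPred) {
  n <- length(yTrue)
  vals <- matrix(0, 2, 4)
  for (cls in 0:1) {
    tp <- fp <- fn <- tn <- 0
    for (k in seq_len(n)) {
      t1 <- yTrue[k] == cls; p1 <- yPred[k] == cls
      if (t1 && p1) tp <- tp + 1
      else if (!t1 && p1) fp <- fp + 1
      else if (t1 && !p1) fn <- fn + 1
      else tn <- tn + 1
    }
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    spec <- if (fp + tn > 0) tn / (fp + tn) else 0
    vals[cls + 1, ] <- c(prec, rec, f1, spec)
  }
  w <- c(sum(yTrue == 0), sum(yTrue == 1)) / n
  out <- as.numeric(w %*% vals)
  names(out) <- c("precision", "recall", "f1", "specificity")
  out
}

bruteKappa <- function(yTrue, yPred) {
  n <- length(yTrue)
  p0 <- sum(yTrue == yPred) / n
  pe <- 0
  for (cls in 0:1)
    pe <- pe + (sum(yTrue == cls) / n) * (sum(yPred == cls) / n)
  if (abs(1 - pe) < 1e-14) return(0)
  (p0 - pe) / (1 - pe)
}

# O(n^2) pairwise Mann-Whitney count, ties worth one half.
bruteAuc <- function(yTrue, scores) {
  pos <- scores[yTrue == 1]; neg <- scores[yTrue == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (if (p > q) 1 else if (p == q) 0.5 else 0)
  tot / (length(pos) * length(neg))
}

# Scalar-loop bilinear interpolation on the half-pixel-centre grid.
bruteBilinear <- function(img, size = 64L) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, size, size)
  for (i in seq_len(size)) {
    for (j in seq_len(size)) {
      sx <- (i - 0.5) * h / size - 0.5
      sy <- (j - 0.5) * w / size - 0.5
      sx <- min(max(sx, 0), h - 1); sy <- min(max(sy, 0), w - 1)
      x0 <- min(floor(sx), h - 2); y0 <- min(floor(sy), w - 2)
      fx <- sx - x0; fy <- sy - y0
      out[i, j] <- (1 - fy) * ((1 - fx) * img[x0 + 1, y0 + 1] +
                               fx * img[x0 + 2, y0 + 1]) +
                   fy * ((1 - fx) * img[x0 + 1, y0 + 2] +
                         fx * img[x0 + 2, y0 + 2])
    }
  }
  out
}

# Naive strided same-padded convolution for tiny shapes.
bruteConv <- function(x, w, s, pt, pl, Ho, Wo) {
  d <- dim(x); k <- dim(w)
  out <- array(0, c(Ho, Wo, k[4], d[4]))
  for (n in seq_len(d[4])) for (co in seq_len(k[4]))
    for (ho in seq_len(Ho)) for (wo in seq_len(Wo)) {
      acc <- 0
      for (ci in seq_len(d[3])) for (ki in seq_len(k[1]))
        for (kj in seq_len(k[2])) {
          hi <- (ho - 1) * s - pt + ki; wi <- (wo - 1) * s - pl + kj
          if (hi >= 1 && hi <= d[1] && wi >= 1 && wi <= d[2])
            acc <- acc + x[hi, wi, ci, n] * w[ki, kj, ci, co]
        }
      out[ho, wo, co, n] <- acc
    }
  out
}

# Per-pixel binary cross-entropy summed per image, then batch-averaged.
bruteReconLoss <- function(x, xHat) {
  n <- dim(x)[1]
  tot <- 0
  for (i in seq_len(n)) {
    img <- x[i, , , 1]; rec <- pmin(pmax(xHat[i, , , 1], 1e-7), 1 - 1e-7)
    for (a in seq_len(nrow(img))) for (b in seq_len(ncol(img)))
      tot <- tot - (img[a, b] * log(rec[a, b]) +
                    (1 - img[a, b]) * log(1 - rec[a, b]))
  }
  tot / n
}

# A tiny, quickly separable dataset for training smoke tests.
tinyDataset <- function(nPerClass = 20L, seed = 11L) {
  generateDataset(nPerClass, textureParams(), seed = seed)
}
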