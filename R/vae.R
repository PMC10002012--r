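# Convolutional variational autoencoder and its denoising variant.
#
# The model maximises the evidence lower bound: per-image reconstruction
# loss (pixelwise binary cross-entropy against the sigmoid decoder output,
# summed over pixels by default) plus the closed-form KL divergence of the
# diagonal-Gaussian posterior N(mu, sigma^2) from the standard normal prior.
# The denoising variant corrupts the encoder input with scaled Gaussian
# noise while the reconstruction loss still compares against the CLEAN
# image, which pushes the model toward feature extraction rather than the
# identity map.

#' Configuration for the convolutional (denoising) VAE
#'
#' @param latentDim latent dimension (default 5).
#' @param noiseFactor scale of Gaussian corruption of encoder inputs; 0
#'   gives the plain convolutional VAE, 0.2 the denoising variant.
#' @param learningRate initial Adam step size.
#' @param lrDecayFactor multiplier applied to the learning rate when the
#'   validation loss fails to improve for `lrPatience` consecutive epochs.
#' @param lrPatience plateau patience in epochs.
#' @param epochs training epochs.
#' @param batchSize minibatch size.
#' @param seed integer seed governing initialisation, shuffling, latent
#'   noise and input corruption.
#' @param lossScale `"sum"` (pixel-summed reconstruction loss, default) or
#'   `"mean"` (per-pixel mean).
#' @return a named list (validated).
#' @export
vaeConfig <- function(latentDim = 5L, noiseFactor = 0, learningRate = 1e-3,
                      lrDecayFactor = 0.5, lrPatience = 2L, epochs = 30L,
                      batchSize = 64L, seed = 1L, lossScale = c("sum", "mean")) {
  lossScale <- match.arg(lossScale)
  if (latentDim < 1L) stop("latentDim must be >= 1", call. = FALSE)
  assertScalarNumber(noiseFactor, "noiseFactor", lower = 0)
  assertScalarNumber(learningRate, "learningRate", lower = 1e-12)
  list(latentDim = as.integer(latentDim), noiseFactor = noiseFactor,
       learningRate = learningRate, lrDecayFactor = lrDecayFactor,
       lrPatience = as.integer(lrPatience), epochs = as.integer(epochs),
       batchSize = as.integer(batchSize), seed = as.integer(seed),
       lossScale = lossScale)
}

#' Reparameterised latent sample
#'
#' `z = mu + exp(0.5 * logVar) * eps`, elementwise; the sampling step that
#' lets gradients flow through the latent draw.
#'
#' @param zMean,zLogVar posterior mean and log-variance (equal-length
#'   vectors or `n x d` matrices).
#' @param noiseDraw standard-normal draw of the same shape.
#' @return the latent sample, same shape as `zMean`.
#' @examples
#' reparameterize(1, 2 * log(2), 1)  # 1 + 2 * 1 = 3
#' @export
reparameterize <- function(zMean, zLogVar, noiseDraw) {
  if (length(zMean) != length(zLogVar) || length(zMean) != length(noiseDraw))
    stop("zMean, zLogVar and noiseDraw must have identical dimensions",
         call. = FALSE)
  zMean + exp(0.5 * zLogVar) * noiseDraw
}

#' KL divergence of a diagonal Gaussian posterior from the standard normal
#'
#' Closed form `-1/2 * sum_d (1 + logVar_d - mu_d^2 - exp(logVar_d))`,
#' non-negative and zero exactly at `mu = 0, logVar = 0`. Row-wise when
#' given matrices (one posterior per row).
#'
#' @param zMean,zLogVar posterior mean and log-variance.
#' @return non-negative scalar (or vector, one value per row).
#' @examples
#' klDivergence(1, 0)        # 0.5
#' klDivergence(0, log(4))   # (3 - log(4)) / 2
#' @export
klDivergence <- function(zMean, zLogVar) {
  if (!all(is.finite(zMean)) || !all(is.finite(zLogVar)))
    stop("non-finite posterior parameters", call. = FALSE)
  term <- 1 + zLogVar - zMean^2 - exp(zLogVar)
  if (is.matrix(zMean)) -0.5 * rowSums(term) else -0.5 * sum(term)
}

#' Reconstruction loss: pixelwise binary cross-entropy
#'
#' `-x * log(xHat) - (1 - x) * log(1 - xHat)` summed over the pixels of each
#' image (or averaged, under `scale = "mean"`), then averaged over the
#' batch. Predictions are clipped away from {0, 1} for numerical safety.
#'
#' @param x clean images, array `(n, h, w, 1)` in `[0, 1]` (or [PatchSet]).
#' @param xHat reconstructions of identical shape, values in `(0, 1)`.
#' @param scale `"sum"` or `"mean"` over pixels.
#' @return non-negative scalar.
#' @export
reconstructionLoss <- function(x, xHat, scale = c("sum", "mean")) {
  scale <- match.arg(scale)
  x <- asPixelArray(x); xHat <- asPixelArray(xHat)
  if (!identical(dim(x), dim(xHat)))
    stop("x and xHat must have identical shapes", call. = FALSE)
  eps <- 1e-7
  p <- pmin(pmax(xHat, eps), 1 - eps)
  bce <- -(x * log(p) + (1 - x) * log(1 - p))
  n <- dim(x)[1]
  perImage <- rowSums(matrix(bce, nrow = n))
  if (scale == "mean") perImage <- perImage / prod(dim(x)[-1])
  mean(perImage)
}

#' Corrupt an image batch with scaled Gaussian noise
#'
#' `x + noiseFactor * eps` with `eps` i.i.d. standard normal, clipped to
#' `[0, 1]`. `noiseFactor = 0` returns the batch unchanged (and draws no
#' random numbers).
#'
#' @param batch array `(n, h, w, 1)` or [PatchSet].
#' @param noiseFactor non-negative noise scale (0.2 for the denoising VAE).
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return corrupted pixel array of the same shape.
#' @export
addNoise <- function(batch, noiseFactor, seed = NULL) {
  if (noiseFactor < 0) stop("noiseFactor must be non-negative", call. = FALSE)
  x <- asPixelArray(batch)
  if (noiseFactor == 0) return(x)
  withSeed(seed, {
    x <- x + noiseFactor * array(rnorm(length(x)), dim(x))
  })
  pmin(pmax(x, 0), 1)
}

# Layer stacks of the reference topology (64x64x1 grayscale input).
vaeArchitecture <- function(latentDim) {
  enc <- list(
    layerConv(c(64L, 64L, 1L), 32L, 2L, "relu"),
    layerConv(c(32L, 32L, 32L), 64L, 2L, "relu"),
    layerFlatten(c(16L, 16L, 64L)),
    layerDense(16384L, 10L, "relu"))
  heads <- list(mean = layerDense(10L, latentDim, "linear"),
                logvar = layerDense(10L, latentDim, "linear"))
  dec <- list(
    layerDense(latentDim, 16384L, "relu"),
    layerReshape(16384L, c(16L, 16L, 64L)),
    layerConvT(c(16L, 16L, 64L), 64L, 2L, "relu"),
    layerConvT(c(32L, 32L, 64L), 32L, 2L, "relu"),
    layerConvT(c(64L, 64L, 32L), 1L, 1L, "sigmoid"))
  list(encoder = enc, heads = heads, decoder = dec)
}

#' Build the convolutional (denoising) VAE
#'
#' Encoder: `(64,64,1) -> Conv(32,k3,s2,ReLU,same) -> Conv(64,k3,s2,ReLU,
#' same) -> flatten (16,384) -> Dense(10,ReLU) -> [Dense(latentDim) mean |
#' Dense(latentDim) log-variance] -> sample`. Decoder: `latentDim ->
#' Dense(16,384,ReLU) -> reshape (16,16,64) -> ConvT(64,k3,s2,ReLU,same) ->
#' ConvT(32,k3,s2,ReLU,same) -> ConvT(1,k3,s1,sigmoid,same) -> (64,64,1)`.
#' Weights are Glorot-uniform, drawn under the config seed.
#'
#' @param config a [vaeConfig()] list.
#' @return an untrained [VaeModel].
#' @export
buildVae <- function(config = vaeConfig()) {
  if (config$latentDim < 1L) stop("latentDim must be >= 1", call. = FALSE)
  arch <- vaeArchitecture(config$latentDim)
  params <- withSeed(deriveSeed(config$seed, saltOf("vae-init")), {
    c(seqInit(arch$encoder, "enc"),
      seqInit(list(arch$heads$mean), "zmean"),
      seqInit(list(arch$heads$logvar), "zlogvar"),
      seqInit(arch$decoder, "dec"))
  })
  new("VaeModel", spec = arch, params = params, optState = list(),
      config = config, history = data.frame(), trained = FALSE)
}

# Full VAE forward pass on an engine-layout batch (64,64,1,n).
# eps: latent noise draw, n x latentDim (NULL -> use the mean, no sampling).
vaeForward <- function(model, xIn, eps, training = FALSE) {
  arch <- model@spec; params <- model@params
  encOut <- seqForward(arch$encoder, params, "enc", xIn, training)
  mu <- seqForward(list(arch$heads$mean), params, "zmean", encOut$out)
  lv <- seqForward(list(arch$heads$logvar), params, "zlogvar", encOut$out)
  z <- if (is.null(eps)) mu$out else reparameterize(mu$out, lv$out, eps)
  decOut <- seqForward(arch$decoder, params, "dec", z, training)
  list(xHat = decOut$out, zMean = mu$out, zLogVar = lv$out, z = z,
       caches = list(enc = encOut$caches, mu = mu$caches, lv = lv$caches,
                     dec = decOut$caches))
}

# Loss + gradients for one minibatch; xClean is the loss target (engine
# layout), xIn the (possibly corrupted) encoder input.
vaeBatchGrad <- function(model, xIn, xClean, eps, lossScale) {
  arch <- model@spec; params <- model@params
  fw <- vaeForward(model, xIn, eps, training = TRUE)
  n <- dim(xClean)[4]
  nPix <- prod(dim(xClean)[1:3])
  epsC <- 1e-7
  p <- pmin(pmax(fw$xHat, epsC), 1 - epsC)
  bce <- -(xClean * log(p) + (1 - xClean) * log(1 - p))
  scaleDiv <- if (lossScale == "mean") nPix else 1
  reconLoss <- sum(bce) / (n * scaleDiv)
  klPer <- klDivergence(fw$zMean, fw$zLogVar)
  klLoss <- mean(klPer)
  # sigmoid + BCE fuse exactly: gradient at the decoder pre-activation is
  # (xHat - x), stable even where the sigmoid saturates
  dPre <- (fw$xHat - xClean) / (n * scaleDiv)
  dec <- seqBackward(arch$decoder, params, "dec", fw$caches$dec, dPre,
                     lastPre = TRUE)
  dz <- dec$dx
  sd <- exp(0.5 * fw$zLogVar)
  dMu <- dz + fw$zMean / n
  dLv <- dz * eps * 0.5 * sd + (-0.5 * (1 - exp(fw$zLogVar))) / n
  mu <- seqBackward(list(arch$heads$mean), params, "zmean", fw$caches$mu, dMu)
  lv <- seqBackward(list(arch$heads$logvar), params, "zlogvar",
                    fw$caches$lv, dLv)
  dEncTop <- mu$dx + lv$dx
  enc <- seqBackward(arch$encoder, params, "enc", fw$caches$enc, dEncTop)
  list(loss = reconLoss + klLoss, recon = reconLoss, kl = klLoss,
       grads = c(enc$grads, mu$grads, lv$grads, dec$grads))
}

# Validation losses without parameter updates (latent noise still sampled,
# from the current stream).
vaeEvalLoss <- function(model, x, lossScale) {
  n <- dim(x)[4]
  eps <- matrix(rnorm(n * model@config$latentDim), n)
  fw <- vaeForward(model, x, eps, training = FALSE)
  recon <- reconstructionLoss(fromEngineLayout(x), fromEngineLayout(fw$xHat),
                              scale = lossScale)
  kl <- mean(klDivergence(fw$zMean, fw$zLogVar))
  c(recon = recon, kl = kl)
}

#' Train the (denoising) VAE
#'
#' Seeded Adam optimisation of the evidence lower bound with a
#' reduce-on-plateau learning-rate schedule: the step size is multiplied by
#' `lrDecayFactor` whenever the validation loss has not improved for
#' `lrPatience` consecutive epochs. With `noiseFactor > 0` the encoder
#' receives freshly corrupted inputs every minibatch while the loss targets
#' the clean images; with `noiseFactor = 0` no corruption draw is made, so
#' the denoising path degenerates bit-for-bit to the plain VAE.
#'
#' @param model an (untrained) [VaeModel] from [buildVae()].
#' @param data a [DatasetBundle] (train + validation partitions used), or a
#'   [PatchSet] used for both.
#' @param config optional [vaeConfig()] overriding the model's config.
#' @return the trained [VaeModel]; per-epoch losses in
#'   [trainingHistory()] (columns `loss = recon + kl` on train and
#'   validation, and the learning rate).
#' @export
trainVae <- function(model, data, config = NULL) {
  if (!is(model, "VaeModel")) stop("model must be a VaeModel", call. = FALSE)
  cfg <- config %||% model@config
  if (is(data, "DatasetBundle")) {
    xTrain <- patchImages(trainSet(data))
    xVal <- patchImages(validationSet(data))
  } else {
    xTrain <- asPixelArray(data); xVal <- xTrain
  }
  n <- dim(xTrain)[1]
  if (n == 0L) stop("empty training set", call. = FALSE)
  xTrainE <- toEngineLayout(xTrain)
  xValE <- toEngineLayout(xVal)
  params <- model@params
  opt <- adamInit(params)
  lr <- cfg$learningRate
  hist <- vector("list", cfg$epochs)
  bestVal <- Inf; wait <- 0L
  withSeed(deriveSeed(cfg$seed, saltOf("vae-train")), {
    for (epoch in seq_len(cfg$epochs)) {
      batches <- shuffledBatches(n, cfg$batchSize)
      epLoss <- epRecon <- epKl <- 0
      for (idx in batches) {
        xb <- xTrainE[, , , idx, drop = FALSE]
        xIn <- if (cfg$noiseFactor > 0) {
          xn <- xb + cfg$noiseFactor * array(rnorm(length(xb)), dim(xb))
          pmin(pmax(xn, 0), 1)
        } else xb
        eps <- matrix(rnorm(length(idx) * cfg$latentDim), length(idx))
        model@params <- params
        bg <- vaeBatchGrad(model, xIn, xb, eps, cfg$lossScale)
        upd <- adamStep(params, bg$grads, opt, lr)
        params <- upd$params; opt <- upd$state
        w <- length(idx) / n
        epLoss <- epLoss + bg$loss * w
        epRecon <- epRecon + bg$recon * w
        epKl <- epKl + bg$kl * w
      }
      model@params <- params
      vl <- vaeEvalLoss(model, xValE, cfg$lossScale)
      valLoss <- sum(vl)
      hist[[epoch]] <- data.frame(
        epoch = epoch, loss = epLoss, recon = epRecon, kl = epKl,
        valLoss = valLoss, valRecon = vl[["recon"]], valKl = vl[["kl"]],
        lr = lr)
      if (valLoss < bestVal - 1e-10) {
        bestVal <- valLoss; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$lrPatience) {
          lr <- lr * cfg$lrDecayFactor
          wait <- 0L
        }
      }
    }
  })
  model@params <- params
  model@optState <- opt
  model@config <- cfg
  model@history <- do.call(rbind, hist)
  model@trained <- TRUE
  model
}

#' @describeIn reconstruct encode, sample the latent, and decode a batch
#'   through a [VaeModel]. With `deterministic = TRUE` the posterior mean is
#'   decoded instead of a sample. Reconstructing with an untrained model is
#'   allowed (with a warning) so reconstruction quality can be compared
#'   before and after training.
#' @param seed integer seed for the latent draw.
#' @param deterministic decode the posterior mean instead of sampling.
#' @param batchSize images processed per forward pass.
#' @export
setMethod("reconstruct", "VaeModel",
  function(object, batch, seed = 1L, deterministic = FALSE, batchSize = 128L) {
    if (length(object@params) == 0L)
      stop("invalid model: no parameters present", call. = FALSE)
    if (!isTRUE(object@trained))
      warning("reconstructing with an untrained model", call. = FALSE)
    x <- asPixelArray(batch)
    n <- dim(x)[1]
    out <- array(0, dim(x))
    withSeed(seed, {
      for (start in seq(1L, n, by = batchSize)) {
        idx <- start:min(start + batchSize - 1L, n)
        xb <- toEngineLayout(x[idx, , , , drop = FALSE])
        eps <- if (deterministic) NULL else
          matrix(rnorm(length(idx) * object@config$latentDim), length(idx))
        fw <- vaeForward(object, xb, eps, training = FALSE)
        out[idx, , , ] <- fromEngineLayout(fw$xHat)
      }
    })
    out
  })

#' Encode a batch to its posterior parameters and a latent sample
#'
#' @param model a [VaeModel].
#' @param batch a [PatchSet] or pixel array.
#' @param seed integer seed for the latent draw.
#' @return list with `zMean`, `zLogVar`, `z` (`n x latentDim` matrices).
#' @export
encodeBatch <- function(model, batch, seed = 1L) {
  x <- toEngineLayout(asPixelArray(batch))
  n <- dim(x)[4]
  withSeed(seed, {
    eps <- matrix(rnorm(n * model@config$latentDim), n)
    fw <- vaeForward(model, x, eps, training = FALSE)
    list(zMean = fw$zMean, zLogVar = fw$zLogVar, z = fw$z)
  })
}
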