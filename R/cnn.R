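# The 10-layer strided CNN classifier. Layer enumeration (input, Conv(64),
# Conv(128), MaxPool(1,1), Dropout, Conv(256), MaxPool(1,1), Dropout,
# Flatten, Dense(2, sigmoid)) is kept verbatim from the reference
# architecture: the (1,1) max-pools are structural no-ops, and all
# downsampling comes from the stride-2 convolutions (64 -> 32 -> 16 -> 8,
# so the flatten width is 8*8*256 = 16,384).

#' Configuration for the CNN classifier
#'
#' @param learningRate Adam step size (default 0.0005).
#' @param dropoutRate fraction of activations dropped during training
#'   (default 0.2); inert at inference.
#' @param epochs training epochs.
#' @param batchSize minibatch size.
#' @param seed integer seed (initialisation, shuffling, dropout masks).
#' @param head `"sigmoid"` (the reference head; the two unit outputs are
#'   normalised to sum 1 inside the categorical cross-entropy, the behaviour
#'   of the framework family this head-loss pairing comes from) or `"softmax"`.
#' @return a named list (validated).
#' @export
cnnConfig <- function(learningRate = 5e-4, dropoutRate = 0.2, epochs = 20L,
                      batchSize = 64L, seed = 1L,
                      head = c("sigmoid", "softmax")) {
  head <- match.arg(head)
  assertScalarNumber(learningRate, "learningRate", lower = 1e-12)
  if (!is.numeric(dropoutRate) || dropoutRate < 0 || dropoutRate >= 1)
    stop("dropoutRate must lie in [0, 1)", call. = FALSE)
  list(learningRate = learningRate, dropoutRate = dropoutRate,
       epochs = as.integer(epochs), batchSize = as.integer(batchSize),
       seed = as.integer(seed), head = head)
}

cnnArchitecture <- function(dropoutRate, head) {
  list(
    layerConv(c(64L, 64L, 1L), 64L, 2L, "relu"),
    layerConv(c(32L, 32L, 64L), 128L, 2L, "relu"),
    layerMaxPool11(c(16L, 16L, 128L)),
    layerDropout(c(16L, 16L, 128L), dropoutRate),
    layerConv(c(16L, 16L, 128L), 256L, 2L, "relu"),
    layerMaxPool11(c(8L, 8L, 256L)),
    layerDropout(c(8L, 8L, 256L), dropoutRate),
    layerFlatten(c(8L, 8L, 256L)),
    layerDense(16384L, 2L, if (head == "softmax") "linear" else "sigmoid"))
}

#' Build the 10-layer CNN classifier
#'
#' Ten layers counted including the input layer: one input layer, three stride-2 3x3
#' convolutions with 64/128/256 filters (ReLU, same padding), two (1,1)
#' max-pools, two dropout layers, one flatten and one Dense(2) output head.
#' Weights are Glorot-uniform, drawn under the config seed.
#'
#' @param config a [cnnConfig()] list.
#' @return an untrained [CnnModel].
#' @export
buildCnn <- function(config = cnnConfig()) {
  if (config$dropoutRate < 0 || config$dropoutRate >= 1)
    stop("dropoutRate must lie in [0, 1)", call. = FALSE)
  arch <- cnnArchitecture(config$dropoutRate, config$head)
  params <- withSeed(deriveSeed(config$seed, saltOf("cnn-init")),
                     seqInit(arch, "cnn"))
  new("CnnModel", spec = arch, params = params, optState = list(),
      config = config, history = data.frame(), trained = FALSE)
}

# Forward pass to per-class scores (n x 2). Softmax head applies its own
# normalisation here; the sigmoid head reports raw unit scores in (0, 1).
cnnScores <- function(model, x, training = FALSE) {
  fw <- seqForward(model@spec, model@params, "cnn", x, training)
  out <- fw$out
  if (model@config$head == "softmax") {
    m <- apply(out, 1, max)
    e <- exp(out - m)
    out <- e / rowSums(e)
  }
  list(scores = out, caches = fw$caches)
}

# Categorical cross-entropy on one-hot labels. Sigmoid-head scores are
# normalised to sum 1 before the log (so a (0.5, 0.5) output costs ln 2 and
# a saturated correct one-hot costs 0); returns the per-sample mean.
categoricalCrossentropy <- function(scores, yOneHot) {
  eps <- 1e-7
  p <- pmin(pmax(scores, eps), 1 - eps)
  p <- p / rowSums(p)
  p <- pmin(pmax(p, eps), 1)
  -mean(rowSums(yOneHot * log(p)))
}

# Gradient of the mean loss at the head pre-activation, for both heads.
cnnLossGrad <- function(model, scores, yOneHot) {
  n <- nrow(scores)
  eps <- 1e-7
  if (model@config$head == "softmax") {
    (scores - yOneHot) / n                       # classic softmax + CE fuse
  } else {
    p <- pmin(pmax(scores, eps), 1 - eps)
    s <- rowSums(p)
    q <- p / s
    # dL/dp_k = (1/s - y_k / p_k) / n, then through the sigmoid
    dp <- (1 / s - yOneHot / p) / n
    dp * scores * (1 - scores)
  }
}

oneHot <- function(labels) {
  y <- matrix(0, length(labels), 2)
  y[cbind(seq_along(labels), labels + 1L)] <- 1
  y
}

#' Train the CNN classifier
#'
#' Seeded Adam minimisation of categorical cross-entropy on one-hot labels
#' (fixed learning rate, default 0.0005). After every epoch the full metric
#' battery is computed on the validation partition and recorded in the
#' history.
#'
#' @param model an (untrained) [CnnModel] from [buildCnn()].
#' @param data a [DatasetBundle] (train + validation used) or [PatchSet].
#' @param config optional [cnnConfig()] overriding the model's config.
#' @return the trained [CnnModel].
#' @export
trainCnn <- function(model, data, config = NULL) {
  if (!is(model, "CnnModel")) stop("model must be a CnnModel", call. = FALSE)
  cfg <- config %||% model@config
  if (is(data, "DatasetBundle")) {
    xTrain <- patchImages(trainSet(data)); yTrain <- patchLabels(trainSet(data))
    xVal <- patchImages(validationSet(data)); yVal <- patchLabels(validationSet(data))
  } else {
    xTrain <- asPixelArray(data); yTrain <- patchLabels(data)
    xVal <- xTrain; yVal <- yTrain
  }
  n <- dim(xTrain)[1]
  if (n == 0L) stop("empty training set", call. = FALSE)
  if (length(unique(yTrain)) < 2L)
    stop("training set contains a single class; two classes required",
         call. = FALSE)
  xTrainE <- toEngineLayout(xTrain)
  params <- model@params
  opt <- adamInit(params)
  hist <- vector("list", cfg$epochs)
  withSeed(deriveSeed(cfg$seed, saltOf("cnn-train")), {
    for (epoch in seq_len(cfg$epochs)) {
      batches <- shuffledBatches(n, cfg$batchSize)
      epLoss <- 0; epHits <- 0
      for (idx in batches) {
        xb <- xTrainE[, , , idx, drop = FALSE]
        yb <- oneHot(yTrain[idx])
        model@params <- params
        fw <- cnnScores(model, xb, training = TRUE)
        loss <- categoricalCrossentropy(fw$scores, yb)
        dPre <- cnnLossGrad(model, fw$scores, yb)
        bk <- seqBackward(model@spec, params, "cnn", fw$caches, dPre,
                          lastPre = TRUE)
        upd <- adamStep(params, bk$grads, opt, cfg$learningRate)
        params <- upd$params; opt <- upd$state
        epLoss <- epLoss + loss * length(idx) / n
        epHits <- epHits + sum(max.col(fw$scores, ties.method = "first") ==
                                 yTrain[idx] + 1L)
      }
      model@params <- params
      valEval <- evaluateModel(model, xVal, yVal)
      hist[[epoch]] <- data.frame(
        epoch = epoch, loss = epLoss, accuracy = epHits / n,
        valLoss = valEval@loss, valAccuracy = valEval@accuracy,
        valPrecision = valEval@precision, valRecall = valEval@recall,
        valF1 = valEval@f1, valSpecificity = valEval@specificity,
        valKappa = valEval@kappa, valRocAuc = valEval@rocAuc,
        lr = cfg$learningRate)
    }
  })
  model@params <- params
  model@optState <- opt
  model@config <- cfg
  model@history <- do.call(rbind, hist)
  model@trained <- TRUE
  model
}

#' Predict class scores and hard labels for a patch batch
#'
#' Dropout is inert at inference, so prediction is deterministic. The hard
#' label is the index of the larger score; exact ties resolve to the
#' lower-index class (class 0).
#'
#' @param object a [CnnModel].
#' @param batch a [PatchSet] or pixel array `(n, 64, 64, 1)`.
#' @param batchSize images per forward pass.
#' @param ... ignored.
#' @return list with `scores` (`n x 2` matrix), `labels` (integer vector in
#'   `{0, 1}`) and `positiveScore` (class-1 score, for ROC analysis).
#' @export
setMethod("predict", "CnnModel", function(object, batch, batchSize = 256L, ...) {
  x <- asPixelArray(batch)
  n <- dim(x)[1]
  scores <- matrix(0, n, 2)
  for (start in seq(1L, n, by = batchSize)) {
    idx <- start:min(start + batchSize - 1L, n)
    xb <- toEngineLayout(x[idx, , , , drop = FALSE])
    scores[idx, ] <- cnnScores(object, xb, training = FALSE)$scores
  }
  labels <- as.integer(scores[, 2] > scores[, 1])   # tie -> class 0
  list(scores = scores, labels = labels, positiveScore = scores[, 2])
})

# Evaluate a CNN on an image batch with the full metric battery.
evaluateModel <- function(model, x, yTrue, averaging = "weighted") {
  pred <- predict(model, x)
  loss <- categoricalCrossentropy(pred$scores, oneHot(yTrue))
  evaluatePredictions(yTrue, pred$labels, pred$positiveScore, loss,
                      averaging = averaging)
}
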