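# Internal seeded training engine.
#
# Tensors flow through layers either as column-major arrays (H, W, C, N) for
# spatial layers or as matrices (N, features) for dense layers; flatten and
# reshape convert between the two. Convolutions use the im2col kernels in
# src/; transposed convolutions are the exact adjoint operator, so their
# forward pass reuses the convolution input-gradient kernel and vice versa.
# All stochastic draws (init, dropout, latent noise) come from R's RNG so a
# single set.seed() makes a whole training run reproducible.

# Same-padding geometry for a strided convolution: output size ceil(H/s),
# extra padding placed bottom/right (the convention of the framework family
# this architecture family comes from).
sameConvGeom <- function(h, w, k, s) {
  ho <- ceiling(h / s); wo <- ceiling(w / s)
  padH <- max((ho - 1) * s + k - h, 0)
  padW <- max((wo - 1) * s + k - w, 0)
  list(ho = as.integer(ho), wo = as.integer(wo),
       pt = as.integer(padH %/% 2), pl = as.integer(padW %/% 2))
}

layerConv <- function(indim, filters, stride, act, kernel = 3L) {
  g <- sameConvGeom(indim[1], indim[2], kernel, stride)
  list(type = "conv", indim = indim,
       outdim = c(g$ho, g$wo, filters), kernel = kernel,
       stride = as.integer(stride), pt = g$pt, pl = g$pl, act = act)
}

# Transposed convolution with same padding: output spatial size = input * s.
# Geometry is that of the matching forward convolution outdim -> indim.
layerConvT <- function(indim, filters, stride, act, kernel = 3L) {
  outdim <- c(indim[1] * stride, indim[2] * stride, filters)
  g <- sameConvGeom(outdim[1], outdim[2], kernel, stride)
  stopifnot(g$ho == indim[1], g$wo == indim[2])
  list(type = "convt", indim = indim, outdim = outdim, kernel = kernel,
       stride = as.integer(stride), pt = g$pt, pl = g$pl, act = act)
}

layerDense <- function(indim, units, act) {
  list(type = "dense", indim = indim, outdim = units, act = act)
}

layerFlatten <- function(indim) {
  list(type = "flatten", indim = indim, outdim = prod(indim))
}

layerReshape <- function(indim, outdim) {
  stopifnot(indim == prod(outdim))
  list(type = "reshape", indim = indim, outdim = outdim)
}

layerDropout <- function(dim, rate) {
  list(type = "dropout", indim = dim, outdim = dim, rate = rate)
}

# Pool size (1, 1): structurally present, computationally the identity.
layerMaxPool11 <- function(dim) {
  list(type = "maxpool11", indim = dim, outdim = dim)
}

glorotUniform <- function(dims, fanIn, fanOut) {
  lim <- sqrt(6 / (fanIn + fanOut))
  array(runif(prod(dims), -lim, lim), dims)
}

# Initialise weights for a sequential stack; names are "<prefix><i>_w"/"_b".
# Draws from the current RNG stream.
seqInit <- function(spec, prefix) {
  params <- list()
  for (i in seq_along(spec)) {
    ly <- spec[[i]]
    if (ly$type == "conv") {
      k <- ly$kernel; cin <- ly$indim[3]; cout <- ly$outdim[3]
      params[[paste0(prefix, i, "_w")]] <-
        glorotUniform(c(k, k, cin, cout), k * k * cin, k * k * cout)
      params[[paste0(prefix, i, "_b")]] <- numeric(cout)
    } else if (ly$type == "convt") {
      # stored in forward-convolution orientation: (k, k, outCh, inCh)
      k <- ly$kernel; cin <- ly$indim[3]; cout <- ly$outdim[3]
      params[[paste0(prefix, i, "_w")]] <-
        glorotUniform(c(k, k, cout, cin), k * k * cin, k * k * cout)
      params[[paste0(prefix, i, "_b")]] <- numeric(cout)
    } else if (ly$type == "dense") {
      params[[paste0(prefix, i, "_w")]] <-
        glorotUniform(c(ly$indim, ly$outdim), ly$indim, ly$outdim)
      params[[paste0(prefix, i, "_b")]] <- numeric(ly$outdim)
    }
  }
  params
}

applyActivation <- function(x, act) {
  switch(act,
    relu = list(out = x * (x > 0), cache = (x > 0)),
    sigmoid = { s <- 1 / (1 + exp(-x)); list(out = s, cache = s) },
    linear = list(out = x, cache = NULL),
    stop("unknown activation: ", act))
}

activationGrad <- function(dy, act, cache) {
  switch(act,
    relu = dy * cache,
    sigmoid = dy * cache * (1 - cache),
    linear = dy)
}

# Forward pass through a sequential stack. Returns the output and per-layer
# caches needed for the backward pass.
seqForward <- function(spec, params, prefix, x, training = FALSE) {
  caches <- vector("list", length(spec))
  for (i in seq_along(spec)) {
    ly <- spec[[i]]
    nmW <- paste0(prefix, i, "_w"); nmB <- paste0(prefix, i, "_b")
    if (ly$type == "conv") {
      y <- cpp_conv_fwd(x, params[[nmW]], ly$stride, ly$pt, ly$pl,
                        ly$outdim[1], ly$outdim[2])
      y <- y + rep(params[[nmB]], each = prod(ly$outdim[1:2]))
      a <- applyActivation(y, ly$act)
      caches[[i]] <- list(x = x, act = a$cache)
      x <- a$out
    } else if (ly$type == "convt") {
      y <- cpp_conv_bwd_input(x, params[[nmW]], ly$stride, ly$pt, ly$pl,
                              ly$outdim[1], ly$outdim[2])
      y <- y + rep(params[[nmB]], each = prod(ly$outdim[1:2]))
      a <- applyActivation(y, ly$act)
      caches[[i]] <- list(x = x, act = a$cache)
      x <- a$out
    } else if (ly$type == "dense") {
      y <- x %*% params[[nmW]]
      y <- y + rep(params[[nmB]], each = nrow(y))
      a <- applyActivation(y, ly$act)
      caches[[i]] <- list(x = x, act = a$cache)
      x <- a$out
    } else if (ly$type == "flatten") {
      n <- dim(x)[4]
      caches[[i]] <- list(dim = dim(x))
      x <- t(matrix(x, ncol = n))
    } else if (ly$type == "reshape") {
      n <- nrow(x)
      caches[[i]] <- NULL
      x <- array(t(x), c(ly$outdim, n))
    } else if (ly$type == "dropout") {
      if (training && ly$rate > 0) {
        mask <- array((runif(length(x)) >= ly$rate) / (1 - ly$rate), dim(x))
        caches[[i]] <- list(mask = mask)
        x <- x * mask
      } else caches[[i]] <- list(mask = NULL)
    } else if (ly$type == "maxpool11") {
      caches[[i]] <- NULL
    } else stop("unknown layer type: ", ly$type)
  }
  list(out = x, caches = caches)
}

# Backward pass; returns gradient w.r.t. the stack input plus named weight
# gradients matching seqInit's parameter names. With `lastPre = TRUE` the
# incoming gradient is taken to be expressed at the final layer's
# pre-activation (used by fused loss/activation gradients such as
# sigmoid + cross-entropy, which are exact even at saturation).
seqBackward <- function(spec, params, prefix, caches, dy, lastPre = FALSE) {
  grads <- list()
  for (i in rev(seq_along(spec))) {
    ly <- spec[[i]]
    nmW <- paste0(prefix, i, "_w"); nmB <- paste0(prefix, i, "_b")
    cc <- caches[[i]]
    skipAct <- lastPre && i == length(spec)
    if (ly$type == "conv") {
      da <- if (skipAct) dy else activationGrad(dy, ly$act, cc$act)
      grads[[nmB]] <- rowSums(colSums(da, dims = 2))
      grads[[nmW]] <- cpp_conv_bwd_filter(cc$x, da, ly$kernel, ly$kernel,
                                          ly$stride, ly$pt, ly$pl)
      dy <- cpp_conv_bwd_input(da, params[[nmW]], ly$stride, ly$pt, ly$pl,
                               ly$indim[1], ly$indim[2])
    } else if (ly$type == "convt") {
      da <- if (skipAct) dy else activationGrad(dy, ly$act, cc$act)
      grads[[nmB]] <- rowSums(colSums(da, dims = 2))
      # adjoint roles: the upstream gradient plays the forward-convolution
      # input, the layer input plays the forward-convolution output gradient
      grads[[nmW]] <- cpp_conv_bwd_filter(da, cc$x, ly$kernel, ly$kernel,
                                          ly$stride, ly$pt, ly$pl)
      dy <- cpp_conv_fwd(da, params[[nmW]], ly$stride, ly$pt, ly$pl,
                         ly$indim[1], ly$indim[2])
    } else if (ly$type == "dense") {
      da <- if (skipAct) dy else activationGrad(dy, ly$act, cc$act)
      grads[[nmB]] <- colSums(da)
      grads[[nmW]] <- crossprod(cc$x, da)
      dy <- tcrossprod(da, params[[nmW]])
    } else if (ly$type == "flatten") {
      dy <- array(t(dy), cc$dim)
    } else if (ly$type == "reshape") {
      n <- dim(dy)[4]
      dy <- t(matrix(dy, ncol = n))
    } else if (ly$type == "dropout") {
      if (!is.null(cc$mask)) dy <- dy * cc$mask
    }
    # maxpool11: identity
  }
  list(dx = dy, grads = grads)
}

adamInit <- function(params) {
  list(t = 0,
       m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One Adam update over every parameter with an available gradient.
adamStep <- function(params, grads, state, lr,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  state$t <- state$t + 1
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / corr1
    vhat <- state$v[[nm]] / corr2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# (n, h, w, 1) user-facing layout <-> (h, w, 1, n) engine layout
toEngineLayout <- function(x) aperm(x, c(2, 3, 4, 1))
fromEngineLayout <- function(x) aperm(x, c(4, 1, 2, 3))

asPixelArray <- function(batch) {
  if (is(batch, "PatchSet")) return(patchImages(batch))
  if (!is.array(batch) || length(dim(batch)) != 4L)
    stop("batch must be a PatchSet or a rank-4 array (n, h, w, 1)", call. = FALSE)
  batch
}

shuffledBatches <- function(n, batchSize) {
  perm <- sample.int(n)
  split(perm, ceiling(seq_along(perm) / batchSize))
}
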