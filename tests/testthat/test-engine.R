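# The training engine: convolution kernels against naive oracles, the
# transposed convolution as the exact adjoint, and finite-difference checks
# of the full backward passes.

test_that("strided same-padded convolution matches the naive oracle", {
  set.seed(1)
  cases <- list(list(d = c(6, 6, 2, 3), f = 4L, s = 2L),
                list(d = c(5, 7, 1, 2), f = 3L, s = 1L),
                list(d = c(8, 8, 3, 1), f = 2L, s = 2L))
  for (cs in cases) {
    x <- array(rnorm(prod(cs$d)), cs$d)
    w <- array(rnorm(9 * cs$d[3] * cs$f), c(3, 3, cs$d[3], cs$f))
    g <- histovae:::sameConvGeom(cs$d[1], cs$d[2], 3L, cs$s)
    got <- histovae:::cpp_conv_fwd(x, w, cs$s, g$pt, g$pl, g$ho, g$wo)
    want <- bruteConv(x, w, cs$s, g$pt, g$pl, g$ho, g$wo)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("transposed convolution is the exact adjoint of convolution", {
  set.seed(2)
  w <- array(rnorm(3 * 3 * 2 * 4), c(3, 3, 2, 4))
  g <- histovae:::sameConvGeom(6L, 6L, 3L, 2L)
  for (rep in 1:5) {
    u <- array(rnorm(6 * 6 * 2), c(6, 6, 2, 1))
    v <- array(rnorm(3 * 3 * 4), c(3, 3, 4, 1))
    lhs <- sum(histovae:::cpp_conv_fwd(u, w, 2L, g$pt, g$pl, 3L, 3L) * v)
    rhs <- sum(u * histovae:::cpp_conv_bwd_input(v, w, 2L, g$pt, g$pl, 6L, 6L))
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("VAE backward pass matches finite differences", {
  set.seed(42)
  vm <- buildVae(vaeConfig(latentDim = 3L, seed = 9L))
  x <- array(runif(2 * 64 * 64), c(64, 64, 1, 2))
  eps <- matrix(rnorm(6), 2)
  bg <- histovae:::vaeBatchGrad(vm, x, x, eps, "sum")
  lossOf <- function(params) {
    vm2 <- vm; vm2@params <- params
    fw <- histovae:::vaeForward(vm2, x, eps)
    p <- pmin(pmax(fw$xHat, 1e-7), 1 - 1e-7)
    sum(-(x * log(p) + (1 - x) * log(1 - p))) / 2 +
      mean(klDivergence(fw$zMean, fw$zLogVar))
  }
  for (nm in c("enc1_w", "enc4_w", "zmean1_w", "zlogvar1_b",
               "dec1_w", "dec3_w", "dec5_b")) {
    p <- vm@params
    i <- sample(length(p[[nm]]), 1)
    h <- 1e-5
    p1 <- p; p1[[nm]][i] <- p1[[nm]][i] + h
    p2 <- p; p2[[nm]][i] <- p2[[nm]][i] - h
    num <- (lossOf(p1) - lossOf(p2)) / (2 * h)
    expect_equal(bg$grads[[nm]][i], num, tolerance = 5e-3,
                 label = paste("gradient of", nm))
  }
})

test_that("CNN backward pass matches finite differences", {
  set.seed(7)
  cm <- buildCnn(cnnConfig(seed = 5L, dropoutRate = 0))
  x <- array(runif(2 * 64 * 64), c(64, 64, 1, 2))
  y <- histovae:::oneHot(c(0L, 1L))
  fw <- histovae:::cnnScores(cm, x, training = TRUE)
  dPre <- histovae:::cnnLossGrad(cm, fw$scores, y)
  bk <- histovae:::seqBackward(cm@spec, cm@params, "cnn", fw$caches, dPre,
                               lastPre = TRUE)
  lossOf <- function(params) {
    m2 <- cm; m2@params <- params
    histovae:::categoricalCrossentropy(histovae:::cnnScores(m2, x)$scores, y)
  }
  for (nm in c("cnn1_w", "cnn2_w", "cnn5_w", "cnn9_w", "cnn9_b")) {
    p <- cm@params
    i <- sample(length(p[[nm]]), 1)
    h <- 1e-5
    p1 <- p; p1[[nm]][i] <- p1[[nm]][i] + h
    p2 <- p; p2[[nm]][i] <- p2[[nm]][i] - h
    num <- (lossOf(p1) - lossOf(p2)) / (2 * h)
    expect_equal(bk$grads[[nm]][i], num, tolerance = 1e-4,
                 label = paste("gradient of", nm))
  }
})

test_that("one Adam step reproduces the closed-form first update", {
  p <- list(w = array(c(1, 2), 2))
  g <- list(w = array(c(0.5, -0.25), 2))
  st <- histovae:::adamInit(p)
  upd <- histovae:::adamStep(p, g, st, lr = 0.1)
  # t = 1: mhat = g, vhat = g^2 -> step = lr * g / (|g| + eps) = lr * sign(g)
  expect_equal(upd$params$w, c(1, 2) - 0.1 * sign(c(0.5, -0.25)),
               tolerance = 1e-5, ignore_attr = TRUE)
})
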