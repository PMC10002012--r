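test_that("confusion counts match definitions and the loop oracle", {
  expect_equal(unname(confusionCounts(c(0, 1, 0, 1), c(0, 1, 0, 1))),
               matrix(c(2L, 0L, 0L, 2L), 2, 2))
  expect_equal(unname(confusionCounts(c(0, 0, 1, 1), c(1, 1, 0, 0))),
               matrix(c(0L, 2L, 2L, 0L), 2, 2))
  set.seed(5)
  for (rep in 1:10) {
    yt <- sample(0:1, 8, replace = TRUE)
    yp <- sample(0:1, 8, replace = TRUE)
    expect_equal(unname(confusionCounts(yt, yp)), bruteConfusion(yt, yp))
  }
  expect_error(confusionCounts(c(0, 1), c(0, 1, 1)), "equal length")
  expect_error(confusionCounts(c(0, 2), c(0, 1)), "labels 0 and 1")
})

test_that("every metric agrees with brute force on all 2^8 patterns", {
  # exhaustive over prediction patterns against two fixed truths
  truths <- list(c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L),
                 c(0L, 0L, 0L, 0L, 0L, 1L, 1L, 1L))
  for (yt in truths) {
    for (code in 0:255) {
      yp <- as.integer(intToBits(code)[1:8])
      cm <- confusionCounts(yt, yp)
      got <- suppressMessages(classMetrics(cm))
      want <- bruteBattery(yt, yp)
      expect_equal(got, want, tolerance = 1e-12)
      expect_equal(cohensKappa(cm), bruteKappa(yt, yp), tolerance = 1e-12)
    }
  }
})

test_that("ROC AUC equals the pairwise count and external references", {
  set.seed(11)
  for (rep in 1:20) {
    yt <- c(0L, 1L, sample(0:1, 8, replace = TRUE))
    sc <- round(runif(10), 2)                       # induce ties
    expect_equal(rocAuc(yt, sc), bruteAuc(yt, sc), tolerance = 1e-12)
  }
  # independent package oracle
  yt <- c(0L, 0L, 1L, 1L, 0L, 1L, 0L, 1L, 1L, 0L)
  sc <- c(0.1, 0.4, 0.35, 0.8, 0.8, 0.8, 0.2, 0.9, 0.5, 0.5)
  expect_equal(rocAuc(yt, sc),
               as.numeric(suppressMessages(pROC::auc(yt, sc))),
               tolerance = 1e-12)
  expect_equal(rocAuc(c(0, 1, 0, 1), rep(0.3, 4)), 0.5)
  expect_equal(rocAuc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_error(rocAuc(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(21)
  yt <- sample(0:1, 30, replace = TRUE, prob = c(0.4, 0.6))
  sc <- round(rnorm(30), 1)
  base <- rocAuc(yt, sc)
  expect_equal(rocAuc(yt, exp(sc)), base, tolerance = 1e-12)
  expect_equal(rocAuc(yt, 2 * sc - 7), base, tolerance = 1e-12)
  expect_equal(rocAuc(yt, rank(sc, ties.method = "average")), base,
               tolerance = 1e-12)
})

test_that("Cohen's kappa has the right fixed points and hand value", {
  # perfect agreement
  expect_equal(cohensKappa(confusionCounts(c(0, 1, 0, 1), c(0, 1, 0, 1))), 1)
  # constant predictors score 0 whatever the truth marginals
  for (rep in 1:5) {
    set.seed(rep)
    yt <- sample(0:1, 20, replace = TRUE, prob = c(0.3, 0.7))
    expect_equal(cohensKappa(confusionCounts(yt, rep(0L, 20))), 0)
    expect_equal(cohensKappa(confusionCounts(yt, rep(1L, 20))), 0)
  }
  # truth-independent predictors score ~0 in expectation; exact hand value:
  # cm ((20,5),(10,15)): P0 = 35/50, Pe = (30*25 + 20*25)/2500 = 0.5
  cm <- matrix(c(20L, 10L, 5L, 15L), 2, 2)
  expect_equal(cohensKappa(cm), (0.7 - 0.5) / 0.5)
  expect_warning(k <- cohensKappa(matrix(c(5L, 0L, 0L, 0L), 2, 2)), "Pe = 1")
  expect_equal(k, 0)
})

test_that("complement symmetry: swapping both labelings preserves metrics", {
  set.seed(31)
  for (rep in 1:10) {
    yt <- sample(0:1, 15, replace = TRUE)
    yp <- sample(0:1, 15, replace = TRUE)
    if (length(unique(yt)) < 2) next
    a <- suppressMessages(evaluatePredictions(yt, yp))
    b <- suppressMessages(evaluatePredictions(1L - yt, 1L - yp))
    expect_equal(a@accuracy, b@accuracy)
    expect_equal(a@kappa, b@kappa, tolerance = 1e-12)
    expect_equal(a@f1, b@f1, tolerance = 1e-12)
  }
})

test_that("the assembled report is complete and within range", {
  yt <- c(0L, 0L, 1L, 1L)
  r <- evaluatePredictions(yt, yt, scores = c(0.1, 0.2, 0.8, 0.9), loss = 0.3)
  expect_s4_class(r, "MetricReport")
  expect_equal(r@accuracy, 1); expect_equal(r@precision, 1)
  expect_equal(r@recall, 1); expect_equal(r@f1, 1)
  expect_equal(r@specificity, 1); expect_equal(r@kappa, 1)
  expect_equal(r@rocAuc, 1); expect_equal(r@loss, 0.3)
  # constant predictor on balanced truth
  rc <- suppressMessages(
    evaluatePredictions(yt, rep(0L, 4), scores = rep(0.5, 4)))
  expect_equal(rc@accuracy, 0.5)
  expect_equal(rc@kappa, 0)
  expect_equal(rc@rocAuc, 0.5)
  # ranges on random input
  set.seed(41)
  yt <- sample(0:1, 25, replace = TRUE)
  yp <- sample(0:1, 25, replace = TRUE)
  rr <- suppressMessages(evaluatePredictions(yt, yp, scores = runif(25)))
  for (v in c(rr@accuracy, rr@precision, rr@recall, rr@f1, rr@specificity,
              rr@rocAuc))
    expect_true(v >= 0 && v <= 1)
  expect_true(rr@kappa >= -1 && rr@kappa <= 1)
  expect_equal(reportTable(rr)$Metric[1:2], c("Loss", "Accuracy"))
})
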