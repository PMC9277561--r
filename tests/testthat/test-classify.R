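test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(20)
  for (k in 1:25) {
    n <- sample(10:40, 1)
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(pos) || all(pos)) next
    sc <- round(rnorm(n), sample(0:2, 1))   # rounding forces ties
    ref <- suppressMessages(as.numeric(
      pROC::auc(pROC::roc(pos, sc, direction = "<", quiet = TRUE))))
    expect_equal(aucFromScores(sc, pos), ref)
  }
})

test_that("AUC is invariant to strictly monotone score transforms", {
  set.seed(21)
  sc <- rnorm(40)
  pos <- rep(c(TRUE, FALSE), 20)
  a <- aucFromScores(sc, pos)
  expect_equal(aucFromScores(exp(sc), pos), a)
  expect_equal(aucFromScores(rank(sc), pos), a)
})

test_that("balanced accuracy is the mean of sensitivity and specificity", {
  expect_equal(balancedAccuracy(1, 0), 0.5)
  expect_equal(balancedAccuracy(0.7, 0.8), 0.75)
  expect_equal(balancedAccuracy(1, 1), 1)
  expect_error(balancedAccuracy(1.2, 0.5))
})

test_that("stratified folds balance both classes and detect failure", {
  pos <- rep(c(TRUE, FALSE), c(17, 31))
  folds <- eegresponse:::stratifiedFolds(pos, 5, seed = 3)
  for (f in 1:5) {
    expect_gte(sum(pos[folds == f]), 3)
    expect_gte(sum(!pos[folds == f]), 6)
  }
  expect_identical(folds, eegresponse:::stratifiedFolds(pos, 5, seed = 3))
  expect_error(eegresponse:::stratifiedFolds(rep(c(TRUE, FALSE),
                                                 c(3, 20)), 5, 1),
               "per class")
})

test_that("grid search is exhaustive with a smallest-(C, gamma) tie-break", {
  spec1 <- classifierSpec(cGrid = 7, gammaGrid = 0.3)
  expect_equal(gridSearchParams(matrix(rnorm(20), 10),
                                rep(c(TRUE, FALSE), 5), spec1),
               c(C = 7, gamma = 0.3))
  # constant features: every grid point scores identically
  specG <- classifierSpec(cGrid = c(10, 0.1, 1), gammaGrid = c(1, 0.01))
  x <- matrix(1, 12, 2)
  got <- gridSearchParams(x, rep(c(TRUE, FALSE), 6), specG, seed = 2)
  expect_equal(got, c(C = 0.1, gamma = 0.01))
  # linearly separable: the chosen parameters must fit the training data
  set.seed(22)
  xs <- rbind(matrix(rnorm(20, 5), 10), matrix(rnorm(20, -5), 10))
  pos <- rep(c(TRUE, FALSE), each = 10)
  par <- gridSearchParams(xs, pos, classifierSpec(), seed = 2)
  dv <- eegresponse:::fitPredictSvm(xs, pos, xs, par["C"], par["gamma"])
  expect_true(all((dv > 0) == pos))
})

test_that("well-separated classes give a perfect pooled-CV ranking", {
  set.seed(23)
  x <- rbind(matrix(rnorm(24 * 2, 6), 24), matrix(rnorm(24 * 2, 0), 24))
  pos <- rep(c(TRUE, FALSE), each = 24)
  cv <- crossValidatedSvm(x, pos, classifierSpec(cGrid = 10^(-1:1),
                                                 gammaGrid = 10^(-2:0)))
  expect_equal(aucValue(cv), 1.0)
  expect_gte(cv@balancedAccuracy, 0.95)
  expect_length(cvScores(cv), 48)
  expect_equal(cv@balancedAccuracy,
               (cv@sensitivity + cv@specificity) / 2)
  expect_equal(nrow(cv@foldParams), 5)
})

test_that("cross-validation is reproducible and rejects bad input", {
  set.seed(24)
  x <- matrix(rnorm(60), 30)
  pos <- rep(c(TRUE, FALSE), 15)
  sp <- pointSpec(cvSeed = 9)
  a <- crossValidatedSvm(x, pos, sp)
  b <- crossValidatedSvm(x, pos, sp)
  expect_identical(cvScores(a), cvScores(b))
  expect_identical(aucValue(a), aucValue(b))
  xx <- x
  xx[3, 1] <- NA
  expect_error(crossValidatedSvm(xx, pos, sp), "finite")
})

test_that("a label-equal feature is learnable but a duplicate adds nothing", {
  set.seed(25)
  n <- 40
  noise <- matrix(rnorm(n * 2), n)
  pos <- rep(c(TRUE, FALSE), each = n / 2)
  # canary: a feature equal to the label must be found by training folds
  cv <- crossValidatedSvm(cbind(noise, as.numeric(pos)), pos,
                          classifierSpec(cGrid = c(1, 10),
                                         gammaGrid = c(0.1, 1)))
  expect_gte(aucValue(cv), 0.99)
  # duplicating an informative column barely moves the pooled AUC
  info <- cbind(rnorm(n) + 2 * as.numeric(pos))
  base <- crossValidatedSvm(info, pos, pointSpec())
  dup <- crossValidatedSvm(cbind(info, info), pos, pointSpec())
  expect_lt(abs(aucValue(base) - aucValue(dup)), 0.02)
})

test_that("single-channel screening returns one fit per channel", {
  set.seed(26)
  tb <- makeBandTable(n = 20)
  lab <- evenLabels(20)
  out <- singleChannelScreen(tb, lab, "delta", pointSpec(nFolds = 4))
  expect_equal(out$channel, c("A", "B", "C", "D"))
  expect_equal(out$balanced_accuracy,
               (out$sensitivity + out$specificity) / 2)
  res <- attr(out, "results")
  expect_length(res, 4)
  expect_s4_class(res$A, "CVResult")
})

test_that("forward selection walks all channels once and tracks its best", {
  set.seed(27)
  tb <- makeBandTable(n = 24, channels = c("A", "B", "C", "D", "E"))
  lab <- evenLabels(24)
  # plant one strong channel
  tb@values[lab, "C", "delta"] <- tb@values[lab, "C", "delta"] * 8
  tr <- forwardChannelSelection(tb, lab, "delta", pointSpec(nFolds = 4))
  st <- selectionSteps(tr)
  expect_equal(nrow(st), 5)
  expect_setequal(st$channel, c("A", "B", "C", "D", "E"))
  expect_equal(st$step, 1:5)
  expect_equal(aucValue(tr), max(st$auc))
  expect_identical(bestSubset(tr), st$channel[seq_len(which.max(st$auc))])
  # the greedy trace can only match or beat the best single channel
  sc <- singleChannelScreen(tb, lab, "delta", pointSpec(nFolds = 4))
  expect_gte(aucValue(tr), max(sc$auc) - 0.02)
  # step cap limits the walk
  tr2 <- forwardChannelSelection(tb, lab, "delta", pointSpec(nFolds = 4),
                                 maxSteps = 2)
  expect_equal(nrow(selectionSteps(tr2)), 2)
})

test_that("permutation p-values follow the add-one formula exactly", {
  set.seed(28)
  n <- 20
  x <- cbind(rnorm(n) + 3 * rep(c(1, 0), each = n / 2))
  pos <- rep(c(TRUE, FALSE), each = n / 2)
  pr <- svmPermutationTest(x, pos, pointSpec(nFolds = 4), nPerm = 19,
                           seed = 5)
  expect_equal(pr@pValue,
               (1 + sum(pr@nullAucs >= pr@observedAuc)) / 20)
  pr2 <- svmPermutationTest(x, pos, pointSpec(nFolds = 4), nPerm = 19,
                            seed = 5)
  expect_identical(pr@nullAucs, pr2@nullAucs)
  expect_error(svmPermutationTest(x, pos, pointSpec(), nPerm = 0), "nPerm")
})
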