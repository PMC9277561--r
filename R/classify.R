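# Responder prediction from pre-treatment band powers: cross-validated
# RBF-SVM with nested hyperparameter grid search, single-channel screening,
# greedy forward channel selection, and label-permutation significance.

#' Area under the ROC curve from scores
#'
#' Rank-based (Mann-Whitney) AUC with midrank tie handling; invariant to
#' any strictly monotone transform of the scores.
#'
#' @param scores numeric decision values, larger = more positive-like.
#' @param positive logical vector, TRUE for the positive class.
#' @return AUC in [0, 1].
#' @export
aucFromScores <- function(scores, positive) {
  stopifnot(length(scores) == length(positive),
            any(positive), any(!positive))
  r <- rank(scores)
  nPos <- sum(positive)
  nNeg <- sum(!positive)
  (sum(r[positive]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Balanced accuracy
#'
#' @param sensitivity,specificity rates in [0, 1].
#' @return \code{(sensitivity + specificity) / 2}.
#' @export
balancedAccuracy <- function(sensitivity, specificity) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  (sensitivity + specificity) / 2
}

# stratified fold assignment; deterministic given labels and seed
stratifiedFolds <- function(positive, k, seed) {
  if (sum(positive) < k || sum(!positive) < k)
    stop("need at least ", k, " subjects per class for stratified ",
         k, "-fold CV")
  folds <- integer(length(positive))
  st <- streamAt(seed, 0L)
  for (cls in c(TRUE, FALSE)) {
    idx <- which(positive == cls)
    res <- withStream(st, idx[sample.int(length(idx))])
    st <- res$stream
    folds[res$value] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

fitPredictSvm <- function(trainX, trainY, testX, C, gamma) {
  y <- factor(ifelse(trainY, "resp", "nonresp"),
              levels = c("resp", "nonresp"))
  fit <- e1071::svm(trainX, y, kernel = "radial", cost = C, gamma = gamma,
                    scale = FALSE)
  pr <- stats::predict(fit, testX, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  # libsvm orders the binary problem by appearance in the training data;
  # orient so larger decision value = more responder-like
  if (!startsWith(colnames(dv)[1L], "resp")) dv <- -dv
  drop(dv)
}

#' Hyperparameter grid search
#'
#' Exhaustive search over \code{cGrid x gammaGrid} scored by inner
#' stratified cross-validation accuracy on the training data; determinstic
#' tie-break to the smallest C, then the smallest gamma. A single-point
#' grid is returned directly.
#'
#' @param x standardized training features (subjects x d).
#' @param positive logical training labels (TRUE = responder).
#' @param spec a \linkS4class{ClassifierSpec}.
#' @param seed seed for the inner fold assignment.
#' @return Named numeric vector \code{c(C = ..., gamma = ...)}.
#' @export
gridSearchParams <- function(x, positive, spec, seed = spec@cvSeed) {
  stopifnot(any(positive), any(!positive))
  if (length(spec@cGrid) == 0L || length(spec@gammaGrid) == 0L)
    stop("empty hyperparameter grid")
  if (length(spec@cGrid) == 1L && length(spec@gammaGrid) == 1L)
    return(c(C = spec@cGrid, gamma = spec@gammaGrid))
  k <- min(spec@innerFolds, sum(positive), sum(!positive))
  folds <- stratifiedFolds(positive, k, seed)
  best <- c(C = spec@cGrid[1L], gamma = spec@gammaGrid[1L])
  bestAcc <- -Inf
  for (C in spec@cGrid) for (gamma in spec@gammaGrid) {
    correct <- 0L
    for (f in seq_len(k)) {
      tr <- folds != f
      dv <- fitPredictSvm(x[tr, , drop = FALSE], positive[tr],
                          x[!tr, , drop = FALSE], C, gamma)
      correct <- correct + sum((dv > 0) == positive[!tr])
    }
    acc <- correct / length(positive)
    if (acc > bestAcc + 1e-12) {
      bestAcc <- acc
      best <- c(C = C, gamma = gamma)
    }
  }
  best
}

#' Cross-validated RBF-SVM with pooled scoring
#'
#' Outer stratified k-fold cross-validation; within each training fold the
#' features are standardized (training-fold statistics only) and an inner
#' grid search picks (C, gamma), so no information from a test fold ever
#' reaches model fitting. Every subject is tested exactly once and the
#' held-out decision values are pooled into a single ROC curve.
#' Sensitivity and specificity are taken at decision threshold 0 with
#' responders as the positive class.
#'
#' @param x numeric feature matrix, subjects x d (d >= 1).
#' @param positive logical labels (TRUE = responder), or a factor/character
#'   vector equal to \code{"responder"} for positives.
#' @param spec a \linkS4class{ClassifierSpec}.
#' @return A \linkS4class{CVResult}.
#' @export
crossValidatedSvm <- function(x, positive, spec = classifierSpec()) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (!is.logical(positive)) positive <- as.character(positive) == "responder"
  stopifnot(nrow(x) == length(positive), ncol(x) >= 1L)
  if (!all(is.finite(x))) stop("features must be finite (no NaN/NA)")
  folds <- stratifiedFolds(positive, spec@nFolds, spec@cvSeed)
  scores <- numeric(length(positive))
  fp <- vector("list", spec@nFolds)
  for (f in seq_len(spec@nFolds)) {
    tr <- folds != f
    if (!any(positive[tr]) || !any(!positive[tr]))
      stop("a class is absent from training fold ", f)
    trX <- x[tr, , drop = FALSE]
    teX <- x[!tr, , drop = FALSE]
    if (spec@scaleFeatures) {
      mu <- colMeans(trX)
      sdv <- apply(trX, 2L, stats::sd)
      sdv[sdv == 0] <- 1
      trX <- sweep(sweep(trX, 2L, mu), 2L, sdv, "/")
      teX <- sweep(sweep(teX, 2L, mu), 2L, sdv, "/")
    }
    par <- gridSearchParams(trX, positive[tr], spec,
                            seed = spec@cvSeed + f)
    scores[!tr] <- fitPredictSvm(trX, positive[tr], teX,
                                 par["C"], par["gamma"])
    fp[[f]] <- data.frame(fold = f, C = unname(par["C"]),
                          gamma = unname(par["gamma"]))
  }
  if (!is.null(rownames(x))) names(scores) <- rownames(x)
  pred <- scores > 0
  sens <- mean(pred[positive])
  spc <- mean(!pred[!positive])
  new("CVResult", auc = aucFromScores(scores, positive),
      sensitivity = sens, specificity = spc,
      balancedAccuracy = balancedAccuracy(sens, spc),
      foldParams = do.call(rbind, fp), scores = scores,
      labels = positive)
}

bandFeatureMatrix <- function(table, band, channels = NULL) {
  stopifnot(is(table, "BandPowerTable"))
  if (!band %in% bandNames(table)) stop("unknown band: ", band)
  if (is.null(channels)) channels <- channelLabels(table)
  miss <- setdiff(channels, channelLabels(table))
  if (length(miss)) stop("unknown channel(s): ", paste(miss, collapse = ", "))
  arr <- table@values[, channels, band, drop = FALSE]
  matrix(arr, nrow = dim(arr)[1L], dimnames = dimnames(arr)[1:2])
}

#' Single-channel classification screen
#'
#' Runs \code{\link{crossValidatedSvm}} once per channel on that channel's
#' band power alone (d = 1), e.g. to map classification performance over
#' the scalp.
#'
#' @param table pre-treatment \linkS4class{BandPowerTable}.
#' @param labels responder labels (named logical covering the table's
#'   subjects).
#' @param band band name.
#' @param spec a \linkS4class{ClassifierSpec}.
#' @return data.frame with one row per channel (channel, auc, sensitivity,
#'   specificity, balanced_accuracy); the full \linkS4class{CVResult}
#'   objects are attached as attribute \code{"results"}.
#' @export
singleChannelScreen <- function(table, labels, band,
                                spec = classifierSpec()) {
  x <- bandFeatureMatrix(table, band)
  positive <- alignLabels(labels, rownames(x))
  results <- lapply(colnames(x), function(ch)
    crossValidatedSvm(x[, ch, drop = FALSE], positive, spec))
  names(results) <- colnames(x)
  out <- data.frame(
    channel = colnames(x),
    auc = vapply(results, function(r) r@auc, 0),
    sensitivity = vapply(results, function(r) r@sensitivity, 0),
    specificity = vapply(results, function(r) r@specificity, 0),
    balanced_accuracy = vapply(results, function(r) r@balancedAccuracy, 0),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "results") <- results
  attr(out, "band") <- band
  out
}

alignLabels <- function(labels, subjects) {
  if (!is.logical(labels)) labels <- as.character(labels) == "responder"
  if (!is.null(names(labels))) {
    if (!all(subjects %in% names(labels)))
      stop("labels missing for subject(s): ",
           paste(setdiff(subjects, names(labels)), collapse = ", "))
    labels <- labels[subjects]
  } else if (length(labels) != length(subjects)) {
    stop("labels must be named or match the number of subjects")
  }
  if (anyNA(labels)) stop("NA responder labels are not allowed here")
  unname(labels)
}

#' Greedy forward channel selection
#'
#' Starts from the best single channel by pooled cross-validated AUC and,
#' at each step, tentatively adds every unused channel, re-running the full
#' cross-validated SVM (including the inner grid search), then commits the
#' AUC-maximizing channel (earliest in montage order on ties). The fold
#' assignment is held fixed across evaluations so comparisons are paired.
#'
#' @param table pre-treatment \linkS4class{BandPowerTable}.
#' @param labels responder labels.
#' @param band band name.
#' @param spec a \linkS4class{ClassifierSpec}.
#' @param maxSteps optional cap on the number of selection steps (default:
#'   continue until all channels are used).
#' @return A \linkS4class{ChannelSelectionTrace}.
#' @export
forwardChannelSelection <- function(table, labels, band,
                                    spec = classifierSpec(),
                                    maxSteps = NULL) {
  x <- bandFeatureMatrix(table, band)
  if (ncol(x) < 2L) stop("forward selection needs at least 2 channels")
  positive <- alignLabels(labels, rownames(x))
  channels <- colnames(x)
  if (is.null(maxSteps)) maxSteps <- length(channels)
  maxSteps <- min(maxSteps, length(channels))
  selected <- character()
  rows <- vector("list", maxSteps)
  for (step in seq_len(maxSteps)) {
    remaining <- setdiff(channels, selected)
    tentative <- lapply(remaining, function(ch)
      crossValidatedSvm(x[, c(selected, ch), drop = FALSE], positive, spec))
    aucs <- vapply(tentative, function(r) r@auc, 0)
    pick <- which.max(aucs)   # first maximum = earliest montage order
    best <- tentative[[pick]]
    selected <- c(selected, remaining[pick])
    rows[[step]] <- data.frame(
      step = step, channel = remaining[pick], auc = best@auc,
      sensitivity = best@sensitivity, specificity = best@specificity,
      balanced_accuracy = best@balancedAccuracy,
      stringsAsFactors = FALSE)
  }
  steps <- do.call(rbind, rows)
  k <- which.max(steps$auc)
  new("ChannelSelectionTrace", band = band, steps = steps,
      bestSubset = steps$channel[seq_len(k)], bestAuc = max(steps$auc))
}

#' Label-permutation test of classifier significance
#'
#' Recomputes the full cross-validated SVM (fold assignment, inner grid
#' search and all) under random label permutations and compares the
#' observed pooled AUC against the permutation null. The p-value uses the
#' add-one correction \code{(1 + #\{null >= observed\}) / (nPerm + 1)}.
#'
#' @param x feature matrix (subjects x d), e.g. the selected channels'
#'   pre-treatment band powers.
#' @param positive responder labels.
#' @param spec a \linkS4class{ClassifierSpec}.
#' @param nPerm number of permutations (default 1000).
#' @param seed seed for the permutation stream.
#' @return A \linkS4class{PermutationResult}.
#' @export
svmPermutationTest <- function(x, positive, spec = classifierSpec(),
                               nPerm = 1000, seed = 1) {
  if (nPerm < 1) stop("nPerm must be >= 1")
  if (!is.matrix(x)) x <- as.matrix(x)
  if (!is.logical(positive)) positive <- as.character(positive) == "responder"
  observed <- crossValidatedSvm(x, positive, spec)@auc
  nullAucs <- numeric(nPerm)
  st <- streamAt(seed, 0L)
  for (b in seq_len(nPerm)) {
    res <- withStream(st, sample(positive))
    st <- res$stream
    nullAucs[b] <- crossValidatedSvm(x, res$value, spec)@auc
  }
  p <- (1 + sum(nullAucs >= observed)) / (nPerm + 1)
  new("PermutationResult", observedAuc = observed, nullAucs = nullAucs,
      pValue = p)
}

#' @rdname svmPermutationTest
#' @param table pre-treatment \linkS4class{BandPowerTable}.
#' @param labels responder labels (named logical).
#' @param band band name.
#' @param channels channel subset to test (e.g. a trace's
#'   \code{bestSubset}).
#' @export
permutationTest <- function(table, labels, band, channels,
                            spec = classifierSpec(), nPerm = 1000,
                            seed = 1) {
  if (length(channels) == 0L) stop("channel subset must be non-empty")
  x <- bandFeatureMatrix(table, band, channels)
  positive <- alignLabels(labels, rownames(x))
  svmPermutationTest(x, positive, spec, nPerm, seed)
}
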