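#' @import methods
NULL

# ---------------------------------------------------------------------------
# EEGRecording

#' EEGRecording: one subject-session multichannel time series
#'
#' Container for a single resting-state EEG recording: a channels x samples
#' matrix in microvolts, channel labels in montage order, the sampling rate,
#' and a provenance log of every processing step applied so far.
#'
#' @slot subjectId subject identifier.
#' @slot session either \code{"pre"} or \code{"post"}.
#' @slot channelLabels character vector, one label per data row.
#' @slot fs sampling rate in Hz.
#' @slot data numeric matrix, channels x samples, in microvolts.
#' @slot provenance character vector of applied processing steps, in order.
#' @export
setClass("EEGRecording",
  representation(subjectId = "character", session = "character",
                 channelLabels = "character", fs = "numeric",
                 data = "matrix", provenance = "character"))

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (length(object@session) != 1L ||
      !object@session %in% c("pre", "post"))
    msg <- c(msg, "session must be 'pre' or 'post'")
  if (nrow(object@data) != length(object@channelLabels))
    msg <- c(msg, "data rows must correspond 1:1 with channelLabels")
  if (anyDuplicated(object@channelLabels))
    msg <- c(msg, "channel labels must be unique")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (!all(is.finite(object@data)))
    msg <- c(msg, "all samples must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecording
#'
#' @param subjectId subject identifier.
#' @param session \code{"pre"} or \code{"post"}.
#' @param data channels x samples numeric matrix (microvolts).
#' @param channelLabels one label per row of \code{data}.
#' @param fs sampling rate in Hz.
#' @param provenance character vector of processing steps already applied.
#' @return An \linkS4class{EEGRecording}.
#' @export
eegRecording <- function(subjectId, session, data, channelLabels, fs,
                         provenance = character()) {
  new("EEGRecording", subjectId = as.character(subjectId),
      session = as.character(session), data = data,
      channelLabels = as.character(channelLabels), fs = fs,
      provenance = provenance)
}

#' @rdname eegRecording-accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname eegRecording-accessors
#' @export
setGeneric("sessionLabel", function(x) standardGeneric("sessionLabel"))
#' @rdname eegRecording-accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))
#' @rdname eegRecording-accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname eegRecording-accessors
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))
#' @rdname eegRecording-accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' Accessors for EEGRecording
#'
#' @param x an \linkS4class{EEGRecording}.
#' @name eegRecording-accessors
#' @return The corresponding slot value.
NULL

#' @rdname eegRecording-accessors
#' @export
setMethod("subjectId", "EEGRecording", function(x) x@subjectId)
#' @rdname eegRecording-accessors
#' @export
setMethod("sessionLabel", "EEGRecording", function(x) x@session)
#' @rdname eegRecording-accessors
#' @export
setMethod("channelLabels", "EEGRecording", function(x) x@channelLabels)
#' @rdname eegRecording-accessors
#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@fs)
#' @rdname eegRecording-accessors
#' @export
setMethod("signalMatrix", "EEGRecording", function(x) x@data)
#' @rdname eegRecording-accessors
#' @export
setMethod("provenance", "EEGRecording", function(x) x@provenance)

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording '%s' (%s): %d channels x %d samples @ %g Hz (%.1f s)\n",
              object@subjectId, object@session, nrow(object@data),
              ncol(object@data), object@fs, ncol(object@data) / object@fs))
  if (length(object@provenance))
    cat("  provenance:", paste(object@provenance, collapse = " -> "), "\n")
})

# ---------------------------------------------------------------------------
# PSDEstimate

#' PSDEstimate: Welch power spectral density of a recording
#'
#' @slot freqs frequency grid in Hz, spanning [0, fs/2] with spacing
#'   \code{1/segLenS}.
#' @slot psd channels x frequencies matrix of one-sided power density
#'   (microvolt^2/Hz).
#' @slot fs sampling rate of the analysed signal.
#' @slot segLenS Welch segment length in seconds.
#' @slot overlap fractional overlap between consecutive segments.
#' @slot window taper label (currently \code{"hamming"}).
#' @slot nSegments number of averaged periodograms.
#' @export
setClass("PSDEstimate",
  representation(freqs = "numeric", psd = "matrix", fs = "numeric",
                 segLenS = "numeric", overlap = "numeric",
                 window = "character", nSegments = "integer"))

setValidity("PSDEstimate", function(object) {
  msg <- character()
  if (ncol(object@psd) != length(object@freqs))
    msg <- c(msg, "psd columns must match frequency grid")
  if (any(object@psd < 0))
    msg <- c(msg, "psd must be non-negative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PSDEstimate", function(object) {
  cat(sprintf("PSDEstimate: %d channel(s), %d bins [0, %g] Hz, %g s %s segments, %d averaged\n",
              nrow(object@psd), length(object@freqs), max(object@freqs),
              object@segLenS, object@window, object@nSegments))
})

# ---------------------------------------------------------------------------
# BandPowerTable / ChangeRateTable

#' BandPowerTable: subjects x channels x bands mean PSD for one session
#'
#' @slot session \code{"pre"} or \code{"post"}.
#' @slot values 3-d numeric array with dimnames (subject, channel, band);
#'   mean one-sided PSD within each band, microvolt^2/Hz.
#' @export
setClass("BandPowerTable",
  representation(session = "character", values = "array"))

setValidity("BandPowerTable", function(object) {
  msg <- character()
  d <- dim(object@values)
  dn <- dimnames(object@values)
  if (length(d) != 3L || is.null(dn) || any(vapply(dn, is.null, TRUE)))
    msg <- c(msg, "values must be a 3-d array with full dimnames")
  else if (!all(d == lengths(dn)))
    msg <- c(msg, "dimnames lengths must match array extents")
  if (!all(is.finite(object@values)) || any(object@values < 0))
    msg <- c(msg, "band powers must be finite and non-negative")
  if (!object@session %in% c("pre", "post"))
    msg <- c(msg, "session must be 'pre' or 'post'")
  if (length(msg)) msg else TRUE
})

#' Construct a BandPowerTable
#'
#' @param values subjects x channels x bands array; dimnames are taken from
#'   (or set by) \code{subjects}, \code{channels}, \code{bands}.
#' @param session \code{"pre"} or \code{"post"}.
#' @param subjects,channels,bands optional axis labels when \code{values}
#'   has no dimnames.
#' @return A \linkS4class{BandPowerTable}.
#' @export
bandPowerTable <- function(values, session,
                           subjects = NULL, channels = NULL, bands = NULL) {
  if (!is.null(subjects) || !is.null(channels) || !is.null(bands))
    dimnames(values) <- list(subject = subjects, channel = channels,
                             band = bands)
  new("BandPowerTable", session = session, values = values)
}

#' ChangeRateTable: per-subject relative band-power change
#'
#' Holds \code{(P_pre - P_post) / P_pre} per subject, channel and band.
#' Positive values denote a power decrease after treatment. Entries where
#' the pre-treatment power was not strictly positive are NA (invalid).
#'
#' @slot values 3-d numeric array with dimnames (subject, channel, band).
#' @export
setClass("ChangeRateTable", representation(values = "array"))

setValidity("ChangeRateTable", function(object) {
  d <- dim(object@values)
  if (length(d) != 3L || is.null(dimnames(object@values)))
    return("values must be a 3-d array with dimnames")
  TRUE
})

#' @rdname bandTable-accessors
#' @export
setGeneric("bandValues", function(x) standardGeneric("bandValues"))
#' @rdname bandTable-accessors
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))
#' @rdname bandTable-accessors
#' @export
setGeneric("bandNames", function(x) standardGeneric("bandNames"))

#' Accessors for band-power and change-rate tables
#'
#' \code{bandValues} returns the underlying 3-d array (subject x channel x
#' band); \code{subjectIds}, \code{channelLabels} and \code{bandNames} return
#' the axis labels.
#'
#' @param x a \linkS4class{BandPowerTable} or \linkS4class{ChangeRateTable}.
#' @name bandTable-accessors
NULL

for (cl in c("BandPowerTable", "ChangeRateTable")) {
  setMethod("bandValues", cl, function(x) x@values)
  setMethod("subjectIds", cl, function(x) dimnames(x@values)[[1L]])
  setMethod("channelLabels", cl, function(x) dimnames(x@values)[[2L]])
  setMethod("bandNames", cl, function(x) dimnames(x@values)[[3L]])
}

#' @rdname bandTable-accessors
#' @export
setMethod("sessionLabel", "BandPowerTable", function(x) x@session)

setMethod("show", "BandPowerTable", function(object) {
  d <- dim(object@values)
  cat(sprintf("BandPowerTable (%s): %d subjects x %d channels x %d bands\n",
              object@session, d[1], d[2], d[3]))
})

setMethod("show", "ChangeRateTable", function(object) {
  d <- dim(object@values)
  cat(sprintf("ChangeRateTable: %d subjects x %d channels x %d bands (%d invalid entries)\n",
              d[1], d[2], d[3], sum(is.na(object@values))))
})

# ---------------------------------------------------------------------------
# ClassifierSpec

#' ClassifierSpec: RBF-SVM and cross-validation settings
#'
#' @slot kernel kernel name; only \code{"rbf"} is supported.
#' @slot cGrid candidate SVM cost values (decades of 10 spanning
#'   0.001-100 by default).
#' @slot gammaGrid candidate RBF width values (same default span).
#' @slot nFolds number of outer stratified cross-validation folds.
#' @slot innerFolds number of inner stratified folds used by the
#'   hyperparameter grid search.
#' @slot cvSeed integer seed controlling fold assignment.
#' @slot scaleFeatures standardize features using training-fold statistics.
#' @export
setClass("ClassifierSpec",
  representation(kernel = "character", cGrid = "numeric",
                 gammaGrid = "numeric", nFolds = "integer",
                 innerFolds = "integer", cvSeed = "integer",
                 scaleFeatures = "logical"))

setValidity("ClassifierSpec", function(object) {
  msg <- character()
  if (!identical(object@kernel, "rbf"))
    msg <- c(msg, "kernel must be 'rbf'")
  if (any(object@cGrid <= 0) || any(object@gammaGrid <= 0))
    msg <- c(msg, "cGrid and gammaGrid must be positive")
  if (object@nFolds < 2L)
    msg <- c(msg, "nFolds must be >= 2")
  if (object@innerFolds < 2L)
    msg <- c(msg, "innerFolds must be >= 2")
  if (length(msg)) msg else TRUE
})

#' Construct a ClassifierSpec
#'
#' Defaults follow common practice for small-cohort EEG classification:
#' an RBF kernel with cost and gamma searched over logarithmic decades
#' between 0.001 and 100, five outer stratified folds, and a three-fold
#' inner grid search on each training fold.
#'
#' @param cGrid,gammaGrid positive candidate values for the SVM cost and
#'   RBF width.
#' @param nFolds outer stratified folds (default 5).
#' @param innerFolds inner folds for grid search (default 3).
#' @param cvSeed seed controlling fold assignment.
#' @param scaleFeatures standardize using training-fold statistics only.
#' @return A \linkS4class{ClassifierSpec}.
#' @export
classifierSpec <- function(cGrid = 10^(-3:2), gammaGrid = 10^(-3:2),
                           nFolds = 5, innerFolds = 3, cvSeed = 1,
                           scaleFeatures = TRUE) {
  new("ClassifierSpec", kernel = "rbf", cGrid = sort(cGrid),
      gammaGrid = sort(gammaGrid), nFolds = as.integer(nFolds),
      innerFolds = as.integer(innerFolds), cvSeed = as.integer(cvSeed),
      scaleFeatures = scaleFeatures)
}

# ---------------------------------------------------------------------------
# CVResult

#' CVResult: pooled cross-validated classifier performance
#'
#' Every subject is tested exactly once; the held-out decision scores are
#' pooled into a single ROC curve. Sensitivity refers to the responder
#' (positive) class at decision threshold 0, and balanced accuracy is
#' exactly \code{(sensitivity + specificity) / 2}.
#'
#' @slot auc area under the pooled ROC curve.
#' @slot sensitivity true-positive rate for responders at threshold 0.
#' @slot specificity true-negative rate for non-responders at threshold 0.
#' @slot balancedAccuracy mean of sensitivity and specificity.
#' @slot foldParams data.frame of the (C, gamma) chosen in each fold.
#' @slot scores named numeric vector of pooled decision values, one per
#'   subject, oriented so larger means more responder-like.
#' @slot labels logical vector (TRUE = responder) aligned with scores.
#' @export
setClass("CVResult",
  representation(auc = "numeric", sensitivity = "numeric",
                 specificity = "numeric", balancedAccuracy = "numeric",
                 foldParams = "data.frame", scores = "numeric",
                 labels = "logical"))

setValidity("CVResult", function(object) {
  msg <- character()
  if (length(object@scores) != length(object@labels))
    msg <- c(msg, "one decision score per subject required")
  if (abs(object@balancedAccuracy -
          (object@sensitivity + object@specificity) / 2) > 1e-12)
    msg <- c(msg, "balancedAccuracy must equal (sensitivity+specificity)/2")
  if (length(msg)) msg else TRUE
})

#' @rdname cvResult-accessors
#' @export
setGeneric("aucValue", function(x) standardGeneric("aucValue"))
#' @rdname cvResult-accessors
#' @export
setGeneric("cvScores", function(x) standardGeneric("cvScores"))

#' Accessors for CVResult
#' @param x a \linkS4class{CVResult}.
#' @name cvResult-accessors
NULL

#' @rdname cvResult-accessors
#' @export
setMethod("aucValue", "CVResult", function(x) x@auc)
#' @rdname cvResult-accessors
#' @export
setMethod("cvScores", "CVResult", function(x) x@scores)

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult: AUC %.3f | sensitivity %.3f | specificity %.3f | balanced accuracy %.3f (n = %d)\n",
              object@auc, object@sensitivity, object@specificity,
              object@balancedAccuracy, length(object@scores)))
})

# ---------------------------------------------------------------------------
# ChannelSelectionTrace

#' ChannelSelectionTrace: greedy forward channel selection path
#'
#' Step k of the trace uses exactly k channels; the first channel is the
#' best single channel by pooled cross-validated AUC, and each later step
#' commits the channel whose tentative addition maximizes AUC (earliest
#' channel in montage order on ties). \code{bestSubset} is the earliest
#' prefix attaining the maximal AUC.
#'
#' @slot band frequency band the features came from.
#' @slot steps data.frame with columns step, channel, auc, sensitivity,
#'   specificity, balanced_accuracy.
#' @slot bestSubset channels of the AUC-maximizing prefix.
#' @slot bestAuc maximal AUC over the trace.
#' @export
setClass("ChannelSelectionTrace",
  representation(band = "character", steps = "data.frame",
                 bestSubset = "character", bestAuc = "numeric"))

setValidity("ChannelSelectionTrace", function(object) {
  msg <- character()
  st <- object@steps
  if (nrow(st)) {
    if (anyDuplicated(st$channel))
      msg <- c(msg, "each channel may be added only once")
    if (!isTRUE(all.equal(object@bestAuc, max(st$auc))))
      msg <- c(msg, "bestAuc must equal the maximal step AUC")
    k <- which.max(st$auc)
    if (!identical(object@bestSubset, st$channel[seq_len(k)]))
      msg <- c(msg, "bestSubset must be the earliest AUC-maximizing prefix")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname trace-accessors
#' @export
setGeneric("selectionSteps", function(x) standardGeneric("selectionSteps"))
#' @rdname trace-accessors
#' @export
setGeneric("bestSubset", function(x) standardGeneric("bestSubset"))

#' Accessors for ChannelSelectionTrace
#' @param x a \linkS4class{ChannelSelectionTrace}.
#' @name trace-accessors
NULL

#' @rdname trace-accessors
#' @export
setMethod("selectionSteps", "ChannelSelectionTrace", function(x) x@steps)
#' @rdname trace-accessors
#' @export
setMethod("bestSubset", "ChannelSelectionTrace", function(x) x@bestSubset)
#' @rdname trace-accessors
#' @export
setMethod("aucValue", "ChannelSelectionTrace", function(x) x@bestAuc)

setMethod("show", "ChannelSelectionTrace", function(object) {
  cat(sprintf("ChannelSelectionTrace (%s): %d steps, best AUC %.3f with {%s}\n",
              object@band, nrow(object@steps), object@bestAuc,
              paste(object@bestSubset, collapse = ", ")))
})

# ---------------------------------------------------------------------------
# PermutationResult

#' PermutationResult: label-permutation significance of a classifier
#'
#' The p-value uses the add-one correction
#' \code{(1 + #\{null >= observed\}) / (nPerm + 1)}, so the smallest
#' attainable p is \code{1 / (nPerm + 1)}.
#'
#' @slot observedAuc AUC of the unpermuted labels.
#' @slot nullAucs AUCs under label permutation.
#' @slot pValue permutation p-value.
#' @export
setClass("PermutationResult",
  representation(observedAuc = "numeric", nullAucs = "numeric",
                 pValue = "numeric"))

setValidity("PermutationResult", function(object) {
  p <- (1 + sum(object@nullAucs >= object@observedAuc)) /
    (length(object@nullAucs) + 1)
  if (abs(p - object@pValue) > 1e-12)
    return("pValue inconsistent with null AUC counts")
  TRUE
})

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf("PermutationResult: observed AUC %.3f, p = %.4g (%d permutations)\n",
              object@observedAuc, object@pValue, length(object@nullAucs)))
})
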