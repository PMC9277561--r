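# Deterministic signal conditioning. The pipeline order is fixed:
# common-average re-reference -> baseline removal -> Butterworth band-pass
# (zero phase) -> fixed-length segmentation; every step appends to the
# recording's provenance and never mutates its input.

replaceData <- function(rec, data, step) {
  eegRecording(rec@subjectId, rec@session, data, rec@channelLabels, rec@fs,
               provenance = c(rec@provenance, step))
}

#' Common-average re-referencing
#'
#' Subtracts, at every time sample, the instantaneous mean across all
#' channels, so the across-channel mean of the output is zero everywhere.
#' Undefined (an error) for single-channel recordings.
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @return A new re-referenced \linkS4class{EEGRecording}.
#' @export
commonAverageReference <- function(rec) {
  stopifnot(is(rec, "EEGRecording"))
  if (nrow(rec@data) < 2L)
    stop("common-average re-referencing needs at least 2 channels")
  data <- sweep(rec@data, 2L, colMeans(rec@data))
  replaceData(rec, data, "common_average_reference")
}

#' Baseline (temporal mean) removal
#'
#' Subtracts each channel's own temporal mean, leaving every output channel
#' with mean (numerically) zero.
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @return A demeaned \linkS4class{EEGRecording}.
#' @export
removeBaseline <- function(rec) {
  stopifnot(is(rec, "EEGRecording"), ncol(rec@data) > 0L)
  data <- sweep(rec@data, 1L, rowMeans(rec@data))
  replaceData(rec, data, "remove_baseline")
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a Butterworth band-pass (default 1-50 Hz, order 4) forward and
#' backward (\code{signal::filtfilt}) for zero phase distortion. The order
#' refers to the underlying one-direction design; the two-pass magnitude
#' response is its square.
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param fLow,fHigh cutoff frequencies in Hz; must satisfy
#'   \code{0 < fLow < fHigh < fs/2}.
#' @param order Butterworth order (default 4).
#' @return A filtered \linkS4class{EEGRecording}.
#' @export
bandpassFilter <- function(rec, fLow = 1, fHigh = 50, order = 4) {
  stopifnot(is(rec, "EEGRecording"))
  fs <- rec@fs
  if (!(fLow > 0 && fLow < fHigh))
    stop("cutoffs must satisfy 0 < fLow < fHigh")
  if (fHigh >= fs / 2)
    stop("upper cutoff must be below the Nyquist frequency ", fs / 2, " Hz")
  bf <- signal::butter(order, c(fLow, fHigh) / (fs / 2), type = "pass")
  data <- t(apply(rec@data, 1L, function(x) signal::filtfilt(bf, x)))
  replaceData(rec, data,
              sprintf("bandpass_butterworth(%g-%g Hz, order %d, zero-phase)",
                      fLow, fHigh, order))
}

#' Extract a fixed-length segment
#'
#' Keeps a contiguous window of \code{lengthS} seconds starting at
#' \code{offsetS} (default: the leading window). Errors if the recording is
#' shorter than requested.
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param lengthS segment length in seconds (default 150).
#' @param offsetS start offset in seconds (default 0).
#' @return The segmented \linkS4class{EEGRecording}.
#' @export
takeSegment <- function(rec, lengthS = 150, offsetS = 0) {
  stopifnot(is(rec, "EEGRecording"), lengthS > 0, offsetS >= 0)
  n <- round(lengthS * rec@fs)
  from <- round(offsetS * rec@fs) + 1L
  if (from + n - 1L > ncol(rec@data))
    stop(sprintf("recording '%s' too short: %.3f s available, %g s from offset %g s requested",
                 rec@subjectId, ncol(rec@data) / rec@fs, lengthS, offsetS))
  if (from == 1L && n == ncol(rec@data)) return(rec)
  replaceData(rec, rec@data[, from:(from + n - 1L), drop = FALSE],
              sprintf("segment(%g s at %g s)", lengthS, offsetS))
}

#' Full preprocessing chain
#'
#' Applies, in this fixed order: common-average re-referencing, baseline
#' removal, zero-phase Butterworth band-pass, and (optionally) fixed-length
#' segmentation.
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param fLow,fHigh,order band-pass settings (see
#'   \code{\link{bandpassFilter}}).
#' @param segmentS segment length in seconds, or NULL to keep the full
#'   recording.
#' @param offsetS segment start offset in seconds.
#' @return The preprocessed \linkS4class{EEGRecording}.
#' @export
preprocessRecording <- function(rec, fLow = 1, fHigh = 50, order = 4,
                                segmentS = NULL, offsetS = 0) {
  rec <- removeBaseline(commonAverageReference(rec))
  rec <- bandpassFilter(rec, fLow, fHigh, order)
  if (!is.null(segmentS)) rec <- takeSegment(rec, segmentS, offsetS)
  rec
}
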