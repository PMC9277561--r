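# Welch PSD estimation and band-power averaging.

#' Welch power spectral density
#'
#' Splits each channel into \code{segLenS}-second segments advanced by
#' \code{(1 - overlap)} of a segment, applies a Hamming taper, and averages
#' one-sided density periodograms with window-power normalization, so that
#' for a demeaned signal the integral of the PSD over frequency equals the
#' signal variance (Parseval).
#'
#' @param x an \linkS4class{EEGRecording}, or a numeric vector / channels x
#'   samples matrix.
#' @param fs sampling rate in Hz (taken from the recording when \code{x} is
#'   an \linkS4class{EEGRecording}).
#' @param segLenS segment length in seconds (default 1).
#' @param overlap fractional overlap between consecutive segments
#'   (default 0.5).
#' @param window taper; only \code{"hamming"} is supported.
#' @return A \linkS4class{PSDEstimate} with one PSD row per channel and
#'   frequency grid \code{0, 1/segLenS, ..., fs/2}.
#' @examples
#' t <- seq(0, 10 - 1e-3, by = 1e-3)
#' est <- welchPsd(sin(2 * pi * 10 * t), fs = 1000)
#' sum(est@psd) * (est@freqs[2] - est@freqs[1])  # ~ 0.5, the sine power
#' @export
welchPsd <- function(x, fs = NULL, segLenS = 1, overlap = 0.5,
                     window = "hamming") {
  if (is(x, "EEGRecording")) {
    fs <- x@fs
    mat <- x@data
  } else if (is.matrix(x)) {
    mat <- x
  } else {
    mat <- matrix(as.numeric(x), nrow = 1L)
  }
  stopifnot(!is.null(fs), fs > 0, segLenS > 0, overlap >= 0, overlap < 1)
  if (!identical(window, "hamming"))
    stop("only the Hamming window is supported")
  nper <- round(segLenS * fs)
  if (ncol(mat) < nper)
    stop("signal shorter than one Welch segment (", nper, " samples)")
  step <- nper - floor(overlap * nper)
  nseg <- floor((ncol(mat) - nper) / step) + 1L
  w <- hammingWindow(nper)
  scale <- fs * sum(w^2)
  nf <- nper %/% 2 + 1L
  starts <- (seq_len(nseg) - 1L) * step
  psd <- matrix(0, nrow(mat), nf)
  segIdx <- outer(seq_len(nper), starts, "+")   # nper x nseg index matrix
  for (ch in seq_len(nrow(mat))) {
    segs <- matrix(mat[ch, segIdx], nper, nseg) * w
    P <- Mod(stats::mvfft(segs)[seq_len(nf), , drop = FALSE])^2 / scale
    p <- rowMeans(P)
    dbl <- 2:(nf - if (nper %% 2 == 0) 1L else 0L)
    p[dbl] <- 2 * p[dbl]
    psd[ch, ] <- p
  }
  rownames(psd) <- if (is(x, "EEGRecording")) x@channelLabels else
    rownames(mat)
  new("PSDEstimate", freqs = (0:(nf - 1L)) * fs / nper, psd = psd, fs = fs,
      segLenS = segLenS, overlap = overlap, window = window,
      nSegments = as.integer(nseg))
}

#' Mean band power from a PSD estimate
#'
#' Averages the PSD over the discrete frequency bins in the half-open
#' interval \code{[fLow, fHigh)}. \code{mode = "integral"} instead sums
#' bin powers times the bin width, giving total in-band power.
#'
#' @param est a \linkS4class{PSDEstimate}.
#' @param fLow,fHigh band edges in Hz (half-open, \code{fLow <= f < fHigh}).
#' @param mode \code{"mean"} (mean density, default) or \code{"integral"}.
#' @return Named numeric vector, one value per channel.
#' @export
bandPower <- function(est, fLow, fHigh, mode = c("mean", "integral")) {
  stopifnot(is(est, "PSDEstimate"), fLow < fHigh)
  mode <- match.arg(mode)
  sel <- est@freqs >= fLow & est@freqs < fHigh
  if (!any(sel))
    stop(sprintf("band [%g, %g) contains no frequency bins", fLow, fHigh))
  out <- if (mode == "mean") rowMeans(est@psd[, sel, drop = FALSE])
  else rowSums(est@psd[, sel, drop = FALSE]) * (est@freqs[2] - est@freqs[1])
  names(out) <- rownames(est@psd)
  out
}

# channels x bands matrix of band powers for one PSD estimate
bandPowerMatrix <- function(est, bands, mode = "mean") {
  out <- vapply(seq_len(nrow(bands)),
                function(b) bandPower(est, bands$f_low[b], bands$f_high[b],
                                      mode),
                numeric(nrow(est@psd)))
  if (!is.matrix(out)) out <- matrix(out, nrow = 1L)
  dimnames(out) <- list(rownames(est@psd), bands$name)
  out
}

#' Build per-session band-power tables from preprocessed recordings
#'
#' Runs \code{\link{welchPsd}} and \code{\link{bandPower}} on each
#' recording and assembles one \linkS4class{BandPowerTable} per session.
#' Subjects are ordered by first appearance in \code{recordings}; channels
#' keep the montage order of the first recording. All recordings must share
#' the sampling rate and channel set.
#'
#' @param recordings list of preprocessed \linkS4class{EEGRecording}s.
#' @param bands band definitions (default \code{\link{bandDefinitions}}).
#' @param segLenS,overlap Welch settings.
#' @param mode band-power mode (see \code{\link{bandPower}}).
#' @return Named list with one \linkS4class{BandPowerTable} per session
#'   present in the input (\code{$pre}, \code{$post}).
#' @export
buildBandPowerTable <- function(recordings, bands = bandDefinitions(),
                                segLenS = 1, overlap = 0.5, mode = "mean") {
  stopifnot(length(recordings) > 0)
  validateBands(bands)
  fs <- recordings[[1L]]@fs
  chans <- recordings[[1L]]@channelLabels
  bad <- vapply(recordings, function(r) {
    r@fs != fs || !identical(toupper(r@channelLabels), toupper(chans))
  }, logical(1))
  if (any(bad))
    stop("heterogeneous sampling rate or channel set for subject(s): ",
         paste(unique(vapply(recordings[bad], subjectId, "")),
               collapse = ", "))
  sessions <- vapply(recordings, sessionLabel, "")
  out <- list()
  for (sess in intersect(c("pre", "post"), unique(sessions))) {
    recs <- recordings[sessions == sess]
    subj <- vapply(recs, subjectId, "")
    if (anyDuplicated(subj))
      stop("duplicated ", sess, " recordings for subject(s): ",
           paste(unique(subj[duplicated(subj)]), collapse = ", "))
    vals <- array(NA_real_, c(length(subj), length(chans), nrow(bands)),
                  dimnames = list(subject = subj, channel = chans,
                                  band = bands$name))
    for (i in seq_along(recs)) {
      est <- welchPsd(recs[[i]], segLenS = segLenS, overlap = overlap)
      vals[i, , ] <- bandPowerMatrix(est, bands, mode)
    }
    out[[sess]] <- bandPowerTable(vals, sess)
  }
  out
}
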