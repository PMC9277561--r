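#' Canonical EEG frequency bands
#'
#' Returns the five-band partition used throughout the package: delta
#' (1-4 Hz), theta (4-8 Hz), low alpha (8-10 Hz), high alpha (10-12 Hz) and
#' beta (12-30 Hz). Band membership of a discrete frequency bin is half-open,
#' \code{f_low <= f < f_high}, so bins at shared edges (4, 8, 10, 12 Hz) are
#' never double-counted and beta's upper edge (30 Hz) is excluded.
#'
#' @param names optional subset of band names to return.
#' @return A data.frame with columns \code{name}, \code{f_low}, \code{f_high}
#'   (Hz), one row per band.
#' @examples
#' bandDefinitions()
#' @export
bandDefinitions <- function(names = NULL) {
  bands <- data.frame(
    name   = c("delta", "theta", "alpha_low", "alpha_high", "beta"),
    f_low  = c(1, 4, 8, 10, 12),
    f_high = c(4, 8, 10, 12, 30),
    stringsAsFactors = FALSE
  )
  if (!is.null(names)) {
    miss <- setdiff(names, bands$name)
    if (length(miss))
      stop("unknown band(s): ", paste(miss, collapse = ", "))
    bands <- bands[match(names, bands$name), , drop = FALSE]
    rownames(bands) <- NULL
  }
  bands
}

validateBands <- function(bands) {
  stopifnot(is.data.frame(bands),
            all(c("name", "f_low", "f_high") %in% names(bands)))
  if (anyDuplicated(bands$name))
    stop("band names must be unique")
  if (any(bands$f_low <= 0) || any(bands$f_high <= bands$f_low))
    stop("bands must satisfy 0 < f_low < f_high")
  invisible(bands)
}

#' Electrode montage of a 62-channel extended 10-20 cap
#'
#' Channel labels for a 62-electrode Quick-Cap-style montage placed
#' according to the extended international 10-20 system, in the canonical
#' anterior-to-posterior cap order. This order is also the deterministic
#' tie-break order used by forward channel selection.
#'
#' @return Character vector of 62 channel labels.
#' @export
defaultChannelLabels <- function() {
  c("FP1", "FPZ", "FP2", "AF3", "AF4",
    "F7", "F5", "F3", "F1", "FZ", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCZ", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "CZ", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPZ", "CP2", "CP4", "CP6", "TP8",
    "P7", "P5", "P3", "P1", "PZ", "P2", "P4", "P6", "P8",
    "PO7", "PO5", "PO3", "POZ", "PO4", "PO6", "PO8",
    "CB1", "O1", "OZ", "O2", "CB2")
}
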