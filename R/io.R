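# On-disk formats. EEG recordings are stored as a plain numeric CSV matrix
# (one row per channel, no header) plus a JSON sidecar naming the subject,
# session, sampling rate and channel labels. Tabular results are CSV;
# nested results (selection traces, manifests) are JSON.

sidecarName <- function(subjectId, session) {
  sprintf("%s_%s.json", subjectId, session)
}

#' Write an EEG recording as CSV matrix + JSON sidecar
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param dir output directory (created if missing).
#' @return Invisibly, the sidecar path.
#' @export
writeEEGRecording <- function(rec, dir) {
  stopifnot(is(rec, "EEGRecording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- sprintf("%s_%s", rec@subjectId, rec@session)
  dataFile <- paste0(base, ".csv")
  data.table::fwrite(data.table::as.data.table(rec@data),
                     file.path(dir, dataFile), col.names = FALSE)
  sidecar <- list(subject = rec@subjectId, session = rec@session,
                  fs = rec@fs, channel_labels = rec@channelLabels,
                  data_file = dataFile, provenance = rec@provenance)
  path <- file.path(dir, sidecarName(rec@subjectId, rec@session))
  jsonlite::write_json(sidecar, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read one EEG recording from its JSON sidecar
#'
#' @param sidecarPath path to the \code{<subject>_<session>.json} sidecar.
#' @return An \linkS4class{EEGRecording}.
#' @export
readEEGRecording <- function(sidecarPath) {
  meta <- jsonlite::read_json(sidecarPath, simplifyVector = TRUE)
  need <- c("subject", "session", "fs", "channel_labels", "data_file")
  if (!all(need %in% names(meta)))
    stop("malformed sidecar ", sidecarPath, ": needs fields ",
         paste(need, collapse = ", "))
  dataPath <- file.path(dirname(sidecarPath), meta$data_file)
  mat <- as.matrix(data.table::fread(dataPath, header = FALSE))
  dimnames(mat) <- NULL
  eegRecording(meta$subject, meta$session, mat,
               as.character(unlist(meta$channel_labels)), meta$fs,
               provenance = as.character(unlist(meta$provenance)))
}

#' Read a directory of EEG recordings
#'
#' Loads every \code{*.json} sidecar under \code{dir} and validates that
#' all recordings share one sampling rate and (optionally) an expected
#' channel count.
#'
#' @param dir directory containing sidecar + matrix files.
#' @param expectedChannels if given, recordings with a different channel
#'   count raise a validation error naming the file.
#' @return List of \linkS4class{EEGRecording}s.
#' @export
readEEGDataset <- function(dir, expectedChannels = NULL) {
  files <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  if (!length(files)) stop("no .json sidecars found under ", dir)
  recs <- lapply(files, readEEGRecording)
  if (!is.null(expectedChannels)) {
    nch <- vapply(recs, function(r) length(r@channelLabels), 0L)
    bad <- nch != expectedChannels
    if (any(bad))
      stop("expected ", expectedChannels, " channels but found ",
           paste(sprintf("%s (%d)", basename(files[bad]), nch[bad]),
                 collapse = ", "))
  }
  fs <- vapply(recs, samplingRate, 0)
  if (length(unique(fs)) != 1L)
    stop("sampling rate mismatch across recordings: ",
         paste(unique(fs), collapse = ", "), " Hz")
  recs
}

#' Write / read the clinical score table
#'
#' Columns: subject_id, group, sev_pre, sev_post, sx_pre, sx_post (and any
#' extra columns present, e.g. the derived responder flag).
#'
#' @param clinical data.frame of clinical scores.
#' @param path CSV path.
#' @return \code{readClinicalTable} returns the data.frame.
#' @export
writeClinicalTable <- function(clinical, path) {
  utils::write.csv(clinical, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeClinicalTable
#' @export
readClinicalTable <- function(path) {
  cl <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "sev_pre", "sev_post", "sx_pre", "sx_post")
  if (!all(need %in% names(cl)))
    stop("clinical table must have columns ", paste(need, collapse = ", "))
  cl
}

#' Write / read a band-power table as long-format CSV
#'
#' Long format: session, subject, channel, band, value.
#'
#' @param table a \linkS4class{BandPowerTable}.
#' @param path CSV path.
#' @return \code{readBandPowerTable} returns a named list of
#'   \linkS4class{BandPowerTable}s, one per session in the file.
#' @export
writeBandPowerTable <- function(table, path) {
  stopifnot(is(table, "BandPowerTable"))
  dn <- dimnames(table@values)
  long <- expand.grid(subject = dn[[1L]], channel = dn[[2L]],
                      band = dn[[3L]], KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  long$session <- table@session
  long$value <- as.vector(table@values)
  long <- long[, c("session", "subject", "channel", "band", "value")]
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeBandPowerTable
#' @export
readBandPowerTable <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("session", "subject", "channel", "band", "value")
  if (!all(need %in% names(long)))
    stop("band-power CSV must have columns ", paste(need, collapse = ", "))
  out <- list()
  for (sess in unique(long$session)) {
    sub <- long[long$session == sess, ]
    subjects <- unique(sub$subject)
    channels <- unique(sub$channel)
    bands <- unique(sub$band)
    vals <- array(NA_real_, c(length(subjects), length(channels),
                              length(bands)),
                  dimnames = list(subject = subjects, channel = channels,
                                  band = bands))
    vals[cbind(match(sub$subject, subjects), match(sub$channel, channels),
               match(sub$band, bands))] <- sub$value
    out[[sess]] <- bandPowerTable(vals, sess)
  }
  out
}

#' Generate and write a synthetic cohort to disk
#'
#' Streams the cohort subject by subject (raw recordings are written and
#' discarded, so memory stays flat) and writes the clinical table as
#' \code{clinical.csv}.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @param dir output directory.
#' @return Invisibly, the clinical data.frame.
#' @export
writeCohort <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- generateCohort(config, perRecording = function(rec)
    writeEEGRecording(rec, dir))
  writeClinicalTable(out$clinical, file.path(dir, "clinical.csv"))
  invisible(out$clinical)
}
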