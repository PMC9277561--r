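# End-to-end orchestration: synthesize or ingest a cohort, preprocess,
# extract band powers, run the pre/post change-rate statistics and the
# pre-treatment classification, and write stable on-disk result schemas.

#' Assemble a pipeline run configuration
#'
#' Input is either a \linkS4class{SyntheticConfig} (default) or a data
#' directory of recordings plus a clinical CSV. All stochastic stages
#' derive their seeds from \code{seed}.
#'
#' @param synthetic \linkS4class{SyntheticConfig} used when
#'   \code{inputDir} is NULL.
#' @param inputDir directory of EEG recordings (sidecar format, see
#'   \code{\link{readEEGDataset}}), or NULL for synthetic input.
#' @param clinicalFile clinical CSV path (required with \code{inputDir}).
#' @param bands band definitions.
#' @param fLow,fHigh,filterOrder band-pass settings.
#' @param segmentS analysis segment length in seconds (NULL = full length).
#' @param segLenS,overlap Welch settings.
#' @param classifier a \linkS4class{ClassifierSpec}.
#' @param responderThreshold improvement fraction for responder labeling.
#' @param bothScores require both Sev and Sx to improve.
#' @param alpha significance level for test gating and the reported
#'   significant-channel counts.
#' @param runClassification run the classification path (single-channel
#'   screen, forward selection, permutation test) per band.
#' @param maxSelectionSteps cap on forward-selection steps (NULL = all
#'   channels, as in the full analysis).
#' @param nPerm permutations for the significance test of each band's best
#'   model.
#' @param outputDir where result files are written.
#' @param seed master seed (synthetic generation uses the
#'   \code{synthetic} config's own seed; classification and permutation
#'   seeds derive from this one).
#' @param verbose print progress messages.
#' @return A list of class \code{"RunConfig"}.
#' @export
runConfig <- function(synthetic = syntheticConfig(), inputDir = NULL,
                      clinicalFile = NULL, bands = bandDefinitions(),
                      fLow = 1, fHigh = 50, filterOrder = 4,
                      segmentS = NULL, segLenS = 1, overlap = 0.5,
                      classifier = classifierSpec(),
                      responderThreshold = 0.5, bothScores = TRUE,
                      alpha = 0.05, runClassification = TRUE,
                      maxSelectionSteps = NULL, nPerm = 1000,
                      outputDir = "eegresponse-run", seed = 1,
                      verbose = TRUE) {
  if (!is.null(inputDir) && is.null(clinicalFile))
    stop("clinicalFile is required when reading from inputDir")
  cfg <- list(synthetic = synthetic, inputDir = inputDir,
              clinicalFile = clinicalFile, bands = bands, fLow = fLow,
              fHigh = fHigh, filterOrder = filterOrder,
              segmentS = segmentS, segLenS = segLenS, overlap = overlap,
              classifier = classifier,
              responderThreshold = responderThreshold,
              bothScores = bothScores, alpha = alpha,
              runClassification = runClassification,
              maxSelectionSteps = maxSelectionSteps, nPerm = nPerm,
              outputDir = outputDir, seed = as.integer(seed),
              verbose = verbose)
  class(cfg) <- "RunConfig"
  cfg
}

#' Read a run configuration from YAML
#'
#' The document mirrors \code{\link{runConfig}} argument names (snake_case
#' accepted), with optional \code{synthetic:} and \code{classifier:}
#' sections mirroring \code{\link{syntheticConfig}} and
#' \code{\link{classifierSpec}} arguments. Unknown keys are an error.
#'
#' @param path YAML file path.
#' @return A \code{\link{runConfig}} list.
#' @export
runConfigFromYaml <- function(path) {
  y <- yaml::read_yaml(path)
  camel <- function(x) gsub("_(\\w)", "\\U\\1", x, perl = TRUE)
  callWith <- function(fn, args, what) {
    if (is.null(args)) args <- list()
    names(args) <- camel(names(args))
    bad <- setdiff(names(args), names(formals(fn)))
    if (length(bad))
      stop("unknown ", what, " key(s): ", paste(bad, collapse = ", "))
    do.call(fn, args)
  }
  names(y) <- camel(names(y))
  if (!is.null(y$bands)) y$bands <- do.call(rbind, lapply(y$bands, as.data.frame))
  if (!is.null(y$synthetic)) {
    s <- y$synthetic
    names(s) <- camel(names(s))
    if (is.list(s$baseBandPower)) s$baseBandPower <- unlist(s$baseBandPower)
    if (!is.null(s$effectMap) && !is.data.frame(s$effectMap))
      s$effectMap <- do.call(rbind, lapply(s$effectMap, as.data.frame))
    if (!is.null(s$bands) && !is.data.frame(s$bands))
      s$bands <- do.call(rbind, lapply(s$bands, as.data.frame))
    y$synthetic <- s
  }
  y$synthetic <- callWith(syntheticConfig, y$synthetic, "synthetic")
  if (!is.null(y$classifier))
    y$classifier <- lapply(y$classifier, function(v)
      if (is.list(v)) unlist(v) else v)
  y$classifier <- callWith(classifierSpec, y$classifier, "classifier")
  callWith(runConfig, y, "run config")
}

configAsList <- function(config) {
  sc <- config$synthetic
  list(
    input = if (is.null(config$inputDir)) "synthetic" else config$inputDir,
    clinical_file = config$clinicalFile,
    synthetic = if (is.null(sc)) NULL else list(
      n_responders = sc@nResponders, n_nonresponders = sc@nNonresponders,
      n_channels = length(sc@channelLabels), fs = sc@fs,
      duration_s = sc@durationS,
      base_band_power = as.list(sc@baseBandPower),
      pink_noise_level = sc@pinkNoiseLevel, subject_sd = sc@subjectSd,
      effect_map = sc@effectMap, seed = sc@seed),
    bands = config$bands,
    preprocess = list(f_low = config$fLow, f_high = config$fHigh,
                      order = config$filterOrder,
                      segment_s = config$segmentS),
    welch = list(seg_len_s = config$segLenS, overlap = config$overlap),
    classifier = list(kernel = "rbf", c_grid = config$classifier@cGrid,
                      gamma_grid = config$classifier@gammaGrid,
                      n_folds = config$classifier@nFolds,
                      inner_folds = config$classifier@innerFolds,
                      cv_seed = config$classifier@cvSeed),
    responder_threshold = config$responderThreshold,
    both_scores = config$bothScores, alpha = config$alpha,
    max_selection_steps = config$maxSelectionSteps, n_perm = config$nPerm,
    seed = config$seed)
}

sayIf <- function(verbose, ...) if (verbose) message(sprintf(...))

# band-power tables for a synthetic cohort, streamed so raw recordings are
# never all held in memory; returns list(tables, clinical)
syntheticBandPowers <- function(config) {
  sc <- config$synthetic
  plan <- cohortPlan(sc)
  nS <- nrow(plan)
  chans <- sc@channelLabels
  bands <- config$bands
  mk <- function() array(
    NA_real_, c(nS, length(chans), nrow(bands)),
    dimnames = list(subject = plan$subject_id, channel = chans,
                    band = bands$name))
  vals <- list(pre = mk(), post = mk())
  out <- generateCohort(sc, perRecording = function(rec) {
    rec <- preprocessRecording(rec, config$fLow, config$fHigh,
                               config$filterOrder, config$segmentS)
    est <- welchPsd(rec, segLenS = config$segLenS,
                    overlap = config$overlap)
    i <- match(rec@subjectId, plan$subject_id)
    vals[[rec@session]][i, , ] <<- bandPowerMatrix(est, bands)
  })
  list(tables = list(pre = bandPowerTable(vals$pre, "pre"),
                     post = bandPowerTable(vals$post, "post")),
       clinical = out$clinical)
}

#' Run the full analysis pipeline
#'
#' Executes both analysis paths on one cohort: (upper path) pre/post
#' band-power change rates compared between responders and non-responders
#' per channel with FDR correction; (lower path) responder prediction from
#' pre-treatment band powers with single-channel screening, greedy forward
#' channel selection and a label-permutation test of each band's best
#' model. All result tables plus a manifest echoing the configuration are
#' written under \code{config$outputDir}; rerunning with an identical
#' configuration reproduces identical outputs.
#'
#' @param config a \code{\link{runConfig}} list.
#' @return Invisibly, the manifest (also written as
#'   \code{manifest.json}).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  outDir <- config$outputDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  verbose <- isTRUE(config$verbose)
  bands <- validateBands(config$bands)

  if (is.null(config$inputDir)) {
    sayIf(verbose, "generating synthetic cohort (%d + %d subjects)",
          config$synthetic@nResponders, config$synthetic@nNonresponders)
    sim <- syntheticBandPowers(config)
    tables <- sim$tables
    clinical <- sim$clinical
  } else {
    sayIf(verbose, "reading recordings from %s", config$inputDir)
    recs <- readEEGDataset(config$inputDir)
    clinical <- readClinicalTable(config$clinicalFile)
    missing <- setdiff(unique(vapply(recs, subjectId, "")),
                       clinical$subject_id)
    if (length(missing))
      stop("clinical table is missing subject(s): ",
           paste(missing, collapse = ", "))
    recs <- lapply(recs, preprocessRecording, fLow = config$fLow,
                   fHigh = config$fHigh, order = config$filterOrder,
                   segmentS = config$segmentS)
    tables <- buildBandPowerTable(recs, bands, config$segLenS,
                                  config$overlap)
  }
  if (is.null(tables$pre) || is.null(tables$post))
    stop("both pre and post recordings are required")
  eegSubjects <- subjectIds(tables$pre)
  missing <- setdiff(eegSubjects, clinical$subject_id)
  if (length(missing))
    stop("clinical table is missing subject(s): ",
         paste(missing, collapse = ", "))

  labels <- labelResponders(clinical, config$responderThreshold,
                            config$bothScores)
  writeClinicalTable(clinical, file.path(outDir, "clinical.csv"))
  writeBandPowerTable(tables$pre, file.path(outDir, "band_power_pre.csv"))
  writeBandPowerTable(tables$post, file.path(outDir, "band_power_post.csv"))

  sayIf(verbose, "comparing change rates between groups")
  rates <- changeRate(tables$pre, tables$post)
  statRows <- lapply(bands$name, function(b) {
    res <- compareGroups(rates, labels, b, config$alpha)
    cbind(band = b, res)
  })
  stats <- do.call(rbind, statRows)
  utils::write.csv(stats, file.path(outDir, "group_stats.csv"),
                   row.names = FALSE)

  summary <- list(
    n_subjects = length(eegSubjects),
    n_responders = sum(labels[eegSubjects], na.rm = TRUE),
    n_nonresponders = sum(!labels[eegSubjects], na.rm = TRUE),
    significant_channels = lapply(split(stats, stats$band), function(s)
      s$channel[!is.na(s$p_adj) & s$p_adj < config$alpha]))

  files <- c("clinical.csv", "band_power_pre.csv", "band_power_post.csv",
             "group_stats.csv")

  if (isTRUE(config$runClassification)) {
    classification <- list()
    for (b in bands$name) {
      sayIf(verbose, "classification for band %s", b)
      screen <- singleChannelScreen(tables$pre, labels, b,
                                    config$classifier)
      screenFile <- sprintf("single_channel_%s.csv", b)
      utils::write.csv(screen, file.path(outDir, screenFile),
                       row.names = FALSE)
      trace <- forwardChannelSelection(tables$pre, labels, b,
                                       config$classifier,
                                       config$maxSelectionSteps)
      perm <- permutationTest(tables$pre, labels, b, bestSubset(trace),
                              config$classifier, config$nPerm,
                              seed = config$seed + match(b, bands$name))
      traceFile <- sprintf("selection_trace_%s.json", b)
      jsonlite::write_json(
        list(band = b, steps = selectionSteps(trace),
             best_subset = bestSubset(trace), best_auc = trace@bestAuc,
             permutation = list(observed_auc = perm@observedAuc,
                                p_value = perm@pValue,
                                n_perm = length(perm@nullAucs),
                                null_aucs = perm@nullAucs)),
        file.path(outDir, traceFile), auto_unbox = TRUE, digits = NA)
      files <- c(files, screenFile, traceFile)
      classification[[b]] <- list(
        best_single_channel = screen$channel[which.max(screen$auc)],
        best_single_auc = max(screen$auc),
        best_subset = bestSubset(trace), best_auc = trace@bestAuc,
        permutation_p = perm@pValue)
    }
    summary$classification <- classification
  }

  manifest <- list(package = "eegresponse",
                   config = configAsList(config), files = files,
                   summary = summary)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
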