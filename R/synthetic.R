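# Synthetic cohort generator: band-limited Gaussian noise with analytically
# calibrated Welch band powers, a 1/f background, lognormal between-subject
# variability, and CAPS-like clinical scores consistent with the >50%
# improvement responder rule.

#' SyntheticConfig: generator settings for a synthetic pre/post EEG cohort
#'
#' @slot nResponders,nNonresponders group sizes (defaults 17 and 31).
#' @slot channelLabels montage labels (default 62-channel extended 10-20).
#' @slot fs sampling rate in Hz (default 1000).
#' @slot durationS recording length in seconds (default 150).
#' @slot bands band definitions (see \code{\link{bandDefinitions}}).
#' @slot baseBandPower named per-band baseline mean PSD (microvolt^2/Hz,
#'   arbitrary units).
#' @slot effectMap data.frame (group, session, channel, band, factor) of
#'   multiplicative power effects; \code{"*"} is a wildcard and matching
#'   rows multiply.
#' @slot pinkNoiseLevel amplitude of the 1/f background (PSD = level/f).
#' @slot subjectSd log-scale SD of the lognormal subject-session power
#'   factor (mean fixed at 1).
#' @slot seed master seed; all subject substreams derive from it.
#' @export
setClass("SyntheticConfig",
  representation(nResponders = "integer", nNonresponders = "integer",
                 channelLabels = "character", fs = "numeric",
                 durationS = "numeric", bands = "data.frame",
                 baseBandPower = "numeric", effectMap = "data.frame",
                 pinkNoiseLevel = "numeric", subjectSd = "numeric",
                 seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (object@nResponders < 0L || object@nNonresponders < 0L ||
      object@nResponders + object@nNonresponders < 2L)
    msg <- c(msg, "need at least 2 subjects in total")
  if (anyDuplicated(object@channelLabels))
    msg <- c(msg, "channel labels must be unique")
  if (object@fs <= 2 * max(object@bands$f_high))
    msg <- c(msg, "fs must exceed twice the highest band edge")
  if (!all(object@bands$name %in% names(object@baseBandPower)))
    msg <- c(msg, "baseBandPower must name every band")
  if (any(object@baseBandPower <= 0))
    msg <- c(msg, "baseBandPower must be positive")
  if (nrow(object@effectMap) && any(object@effectMap$factor <= 0))
    msg <- c(msg, "all effect factors must be positive")
  if (object@pinkNoiseLevel < 0 || object@subjectSd < 0)
    msg <- c(msg, "pinkNoiseLevel and subjectSd must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Default group-by-session power effects
#'
#' Encodes the study conditions the generator emulates: responders' theta
#' and beta power decreases after treatment (factors 0.72 and 0.69) while
#' non-responders' increases (1.08 and 1.10) -- the beta factors match the
#' roughly 31\% decrease and 10\% increase seen at fronto-central sites in
#' treated cohorts -- and responders carry elevated delta power (factor
#' 1.35, both sessions, so change rates are unaffected) at five
#' centro-frontal/occipital channels, which is the pre-treatment signal the
#' classifier has to find.
#'
#' @return data.frame with columns group, session, channel, band, factor.
#' @export
defaultEffectMap <- function() {
  rbind(
    data.frame(group = "responder", session = "post", channel = "*",
               band = c("theta", "beta"), factor = c(0.72, 0.69)),
    data.frame(group = "nonresponder", session = "post", channel = "*",
               band = c("theta", "beta"), factor = c(1.08, 1.10)),
    data.frame(group = "responder", session = "*",
               channel = c("CZ", "O1", "FC2", "FC1", "F2"),
               band = "delta", factor = 1.35)
  )
}

#' Construct a SyntheticConfig
#'
#' Defaults reproduce the emulated study conditions: 17 responders and 31
#' non-responders, 62-channel extended 10-20 montage, 1000 Hz sampling,
#' 150 s eyes-closed segments, the five canonical bands, and the effect map
#' of \code{\link{defaultEffectMap}}.
#'
#' @param nResponders,nNonresponders group sizes.
#' @param channelLabels electrode labels.
#' @param fs sampling rate (Hz); must exceed twice the highest band edge.
#' @param durationS recording duration (seconds).
#' @param bands band definition data.frame.
#' @param baseBandPower named per-band baseline PSD level.
#' @param effectMap multiplicative (group, session, channel, band) effects.
#' @param pinkNoiseLevel 1/f background amplitude (PSD = level/f).
#' @param subjectSd log-scale between-subject power SD.
#' @param seed master seed.
#' @return A \linkS4class{SyntheticConfig}.
#' @export
syntheticConfig <- function(nResponders = 17, nNonresponders = 31,
                            channelLabels = defaultChannelLabels(),
                            fs = 1000, durationS = 150,
                            bands = bandDefinitions(),
                            baseBandPower = c(delta = 2.0, theta = 1.2,
                                              alpha_low = 1.0,
                                              alpha_high = 0.8, beta = 0.5),
                            effectMap = defaultEffectMap(),
                            pinkNoiseLevel = 0.1, subjectSd = 0.25,
                            seed = 1) {
  validateBands(bands)
  new("SyntheticConfig", nResponders = as.integer(nResponders),
      nNonresponders = as.integer(nNonresponders),
      channelLabels = as.character(channelLabels), fs = fs,
      durationS = durationS, bands = bands, baseBandPower = baseBandPower,
      effectMap = effectMap, pinkNoiseLevel = pinkNoiseLevel,
      subjectSd = subjectSd, seed = as.integer(seed))
}

# multiplicative effect factors for one (group, session): channels x bands
effectFactors <- function(map, group, session, channels, bandNames) {
  out <- matrix(1, length(channels), length(bandNames),
                dimnames = list(channels, bandNames))
  if (!nrow(map)) return(out)
  for (r in seq_len(nrow(map))) {
    if (!map$group[r] %in% c("*", group)) next
    if (!map$session[r] %in% c("*", session)) next
    ch <- if (map$channel[r] == "*") channels else map$channel[r]
    bd <- if (map$band[r] == "*") bandNames else map$band[r]
    ch <- intersect(ch, channels)
    bd <- intersect(bd, bandNames)
    out[ch, bd] <- out[ch, bd] * map$factor[r]
  }
  out
}

# ---------------------------------------------------------------------------
# Calibration: the Welch estimator smooths the spectrum with the squared
# window kernel, so a flat synthesized band does not measure back at its
# synthesis level (edge bins lose power into neighbouring bands). We solve
# a small linear system: A[i, j] = measured mean PSD in band i per unit
# synthesized PSD in band j, computed from the window's power transfer,
# and synthesize at levels A^{-1} %*% target.

hammingWindow <- function(n) 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))

.calibCache <- new.env(parent = emptyenv())

welchBandResponse <- function(N, fs, nperseg, bands) {
  key <- paste(N, fs, nperseg, paste(bands$f_low, bands$f_high, collapse = ","),
               sep = "|")
  if (!is.null(.calibCache[[key]])) return(.calibCache[[key]])
  w <- hammingWindow(nperseg)
  W <- stats::fft(c(w, numeric(N - nperseg)))
  K <- Mod(W)^2 / (fs * sum(w^2))       # power transfer kernel, circular
  dfsyn <- fs / N
  fan <- (0:(nperseg %/% 2)) * fs / nperseg
  fsynHalf <- (0:(N %/% 2)) * dfsyn
  nb <- nrow(bands)
  A <- matrix(0, nb, nb)
  for (bi in seq_len(nb)) {
    gbins <- which(fan >= bands$f_low[bi] & fan < bands$f_high[bi])
    for (bj in seq_len(nb)) {
      jbins <- which(fsynHalf >= bands$f_low[bj] &
                     fsynHalf < bands$f_high[bj]) - 1L
      resp <- 0
      for (g in fan[gbins]) {
        gi <- round(g / dfsyn)
        resp <- resp + sum(K[(gi - jbins) %% N + 1L]) +
          sum(K[(gi + jbins) %% N + 1L])
      }
      A[bi, bj] <- dfsyn * resp / length(gbins)
    }
  }
  .calibCache[[key]] <- A
  A
}

# one channel of band-limited noise + 1/f background, synthesized in the
# frequency domain (levels are one-sided PSD in microvolt^2/Hz)
synthesizeChannel <- function(N, fs, bands, levels, pinkLevel) {
  half <- N %/% 2
  freqs <- (0:half) * fs / N
  spec <- complex(length.out = N)
  addNoise <- function(sel, psdLevels) {
    m <- length(sel)
    if (!m) return()
    amp <- sqrt(psdLevels * fs * N / 2)
    co <- complex(real = stats::rnorm(m, sd = sqrt(0.5)),
                  imaginary = stats::rnorm(m, sd = sqrt(0.5))) * amp
    spec[sel] <<- spec[sel] + co
  }
  for (b in seq_len(nrow(bands))) {
    sel <- which(freqs >= bands$f_low[b] & freqs < bands$f_high[b])
    sel <- sel[sel > 1L & sel <= half]     # never touch DC / Nyquist
    addNoise(sel, rep(levels[b], length(sel)))
  }
  if (pinkLevel > 0) {
    fmax <- min(65, 0.95 * fs / 2)
    sel <- which(freqs >= 0.5 & freqs <= fmax)
    sel <- sel[sel > 1L & sel <= half]
    addNoise(sel, pinkLevel / freqs[sel])
  }
  idx <- 2:(half + if (N %% 2 == 0) 0L else 1L)
  spec[N - idx + 2L] <- Conj(spec[idx])
  Re(stats::fft(spec, inverse = TRUE)) / N
}

#' Generate one synthetic EEG recording
#'
#' Each channel is a sum of independent band-limited Gaussian noise
#' components (one per band) plus a 1/f background. Per-band amplitudes are
#' calibrated against the Welch estimator's band response (1 s Hamming
#' segments, 50\% overlap) so that the expected measured mean PSD in band b
#' equals \code{baseBandPower[b] * effect factor * subject factor}. The
#' subject factor is lognormal with mean 1 and log-SD \code{subjectSd},
#' drawn independently per band and per session.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @param subjectId subject identifier for the returned recording.
#' @param group \code{"responder"} or \code{"nonresponder"}.
#' @param session \code{"pre"} or \code{"post"}.
#' @param stream optional L'Ecuyer-CMRG state controlling all draws;
#'   defaults to the config master seed. Identical stream implies an
#'   identical recording.
#' @return An \linkS4class{EEGRecording}.
#' @export
generateRecording <- function(config, subjectId, group, session,
                              stream = NULL) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  if (!group %in% c("responder", "nonresponder"))
    stop("unknown group label: ", group)
  if (!session %in% c("pre", "post"))
    stop("unknown session label: ", session)
  if (is.null(stream)) stream <- streamAt(config@seed, 0L)
  withStream(stream, generateRecordingImpl(config, subjectId, group,
                                           session))$value
}

generateRecordingImpl <- function(config, subjectId, group, session) {
  bands <- config@bands
  nb <- nrow(bands)
  fs <- config@fs
  N <- round(config@durationS * fs)
  nperseg <- min(round(fs), N)
  A <- welchBandResponse(N, fs, nperseg, bands)
  eff <- effectFactors(config@effectMap, group, session,
                       config@channelLabels, bands$name)
  base <- config@baseBandPower[bands$name]
  subjFactor <- if (config@subjectSd > 0)
    exp(stats::rnorm(nb, -config@subjectSd^2 / 2, config@subjectSd))
  else rep(1, nb)
  data <- matrix(0, length(config@channelLabels), N)
  for (ch in seq_along(config@channelLabels)) {
    target <- base * eff[ch, ] * subjFactor
    levels <- solve(A, target)
    levels[levels < 0] <- 0
    data[ch, ] <- synthesizeChannel(N, fs, bands, levels,
                                    config@pinkNoiseLevel)
  }
  eegRecording(subjectId, session, data, config@channelLabels, fs,
               provenance = sprintf("synthetic(group=%s,seed=%d)",
                                    group, config@seed))
}

# ---------------------------------------------------------------------------
# Clinical scores

truncNorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- stats::rnorm(1, mean, sd)
      if (v >= lower && v <= upper) break
    }
    out[i] <- v
  }
  out
}

#' Generate CAPS-like clinical scores for one subject
#'
#' Pre-treatment severity (Sev) and symptom-count (Sx) totals are drawn on
#' the scale of published PTSD cohorts (Sev roughly 25-80, Sx 6-20); post
#' scores are \code{pre * (1 - improvement)} with improvement drawn around
#' \code{improvementResponder} (responders) or
#' \code{improvementNonresponder} (non-responders), rounded to integers and
#' clipped so that the resulting record always satisfies the strict >50\%
#' both-scores responder rule for its intended group.
#'
#' @param subjectId subject identifier.
#' @param group \code{"responder"} or \code{"nonresponder"}.
#' @param stream optional RNG stream (see \code{\link{generateRecording}}).
#' @param improvementResponder mean fractional improvement for responders
#'   (must exceed 0.5; default 0.77, the cohort-level mean improvement seen
#'   in treated responders).
#' @param improvementNonresponder mean fractional improvement for
#'   non-responders (must be below 0.5; default 0.19).
#' @param improvementSd SD of the per-score improvement draw.
#' @return One-row data.frame: subject_id, group, sev_pre, sev_post,
#'   sx_pre, sx_post, responder.
#' @export
generateClinical <- function(subjectId, group, stream = NULL,
                             improvementResponder = 0.77,
                             improvementNonresponder = 0.19,
                             improvementSd = 0.05) {
  if (!group %in% c("responder", "nonresponder"))
    stop("unknown group label: ", group)
  stopifnot(improvementResponder > 0.5, improvementResponder < 1,
            improvementNonresponder > 0, improvementNonresponder < 0.5)
  if (is.null(stream)) stream <- rootStream(1L)
  withStream(stream, generateClinicalImpl(subjectId, group,
                                          improvementResponder,
                                          improvementNonresponder,
                                          improvementSd))$value
}

generateClinicalImpl <- function(subjectId, group, improvementResponder,
                                 improvementNonresponder, improvementSd) {
  {
    resp <- group == "responder"
    sevPre <- round(truncNorm(1, if (resp) 42.8 else 37.4,
                              if (resp) 16.2 else 13.3, 25, 80))
    sxPre <- round(truncNorm(1, 12.5, 3.9, 6, 20))
    bounds <- if (resp) c(0.55, 0.95) else c(0.02, 0.45)
    centre <- if (resp) improvementResponder else improvementNonresponder
    imp <- truncNorm(2, centre, improvementSd, bounds[1], bounds[2])
    post <- pmax(0, round(c(sevPre, sxPre) * (1 - imp)))
    if (resp) {
      post <- pmin(post, floor((c(sevPre, sxPre) - 1) / 2))
      post <- pmax(post, 0)
    } else {
      post <- pmax(post, ceiling(c(sevPre, sxPre) / 2))
    }
    data.frame(subject_id = as.character(subjectId), group = group,
               sev_pre = sevPre, sev_post = post[1],
               sx_pre = sxPre, sx_post = post[2],
               responder = resp, stringsAsFactors = FALSE)
  }
}

# ---------------------------------------------------------------------------
# Cohort

cohortPlan <- function(config) {
  ids <- c(sprintf("resp%02d", seq_len(config@nResponders)),
           sprintf("nonr%02d", seq_len(config@nNonresponders)))
  groups <- c(rep("responder", config@nResponders),
              rep("nonresponder", config@nNonresponders))
  # responders and non-responders use disjoint stream counters so that
  # changing one group size never reshuffles the other group
  counters <- c(seq_len(config@nResponders),
                1000L + seq_len(config@nNonresponders))
  data.frame(subject_id = ids, group = groups, counter = counters,
             stringsAsFactors = FALSE)
}

#' Generate a full synthetic cohort
#'
#' Produces one pre and one post recording per subject plus a clinical
#' score table whose responder labels are consistent with the EEG effect
#' map group assignment. Fully reproducible from \code{config@seed}.
#'
#' For large configurations holding every recording in memory is costly
#' (the full default cohort is about 7 GB); \code{perRecording} allows
#' streamed processing: it is called as \code{perRecording(recording)} for
#' each recording in order and, when supplied, raw recordings are discarded
#' after the callback returns (the \code{recordings} element is then empty).
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @param perRecording optional callback for streamed processing.
#' @return list(recordings = list of \linkS4class{EEGRecording},
#'   clinical = data.frame).
#' @export
generateCohort <- function(config, perRecording = NULL) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  plan <- cohortPlan(config)
  clinical <- vector("list", nrow(plan))
  recs <- list()
  for (i in seq_len(nrow(plan))) {
    stream <- streamAt(config@seed, plan$counter[i])
    st <- withStream(stream,
                     generateClinicalImpl(plan$subject_id[i], plan$group[i],
                                          0.77, 0.19, 0.05))
    clinical[[i]] <- st$value
    for (session in c("pre", "post")) {
      st <- withStream(st$stream,
                       generateRecordingImpl(config, plan$subject_id[i],
                                             plan$group[i], session))
      if (is.null(perRecording)) {
        recs[[length(recs) + 1L]] <- st$value
      } else {
        perRecording(st$value)
      }
    }
  }
  list(recordings = recs, clinical = do.call(rbind, clinical))
}
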