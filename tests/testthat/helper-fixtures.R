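# Shared fixtures, all built in code at test time.

# small synthetic config for fast tests; defaults isolate the deterministic
# band calibration (no subject variability, no 1/f background)
smallConfig <- function(nResponders = 2, nNonresponders = 2,
                        channels = c("CZ", "O1", "F3"), fs = 250,
                        durationS = 20, subjectSd = 0, pink = 0,
                        effectMap = defaultEffectMap(), seed = 1, ...) {
  syntheticConfig(nResponders = nResponders,
                  nNonresponders = nNonresponders,
                  channelLabels = channels, fs = fs, durationS = durationS,
                  subjectSd = subjectSd, pinkNoiseLevel = pink,
                  effectMap = effectMap, seed = seed, ...)
}

targetBandPower <- function(cfg = smallConfig()) cfg@baseBandPower

makeRecording <- function(data, fs = 100, subject = "s1", session = "pre",
                          channels = NULL) {
  if (is.null(channels)) channels <- sprintf("ch%d", seq_len(nrow(data)))
  eegRecording(subject, session, data, channels, fs)
}

sineRecording <- function(freqs, fs = 1000, durS = 10, amp = 1, ...) {
  t <- seq(0, durS - 1 / fs, by = 1 / fs)
  data <- t(vapply(freqs, function(f) amp * sin(2 * pi * f * t), t))
  makeRecording(data, fs = fs, ...)
}

# band-power table with lognormal "subject" noise around per-band levels;
# optional per-channel multiplicative group effects for responders
makeBandTable <- function(n = 20, channels = c("A", "B", "C", "D"),
                          bands = c("delta", "beta"), sdLog = 0.25,
                          session = "pre") {
  vals <- array(exp(rnorm(n * length(channels) * length(bands),
                          sd = sdLog)),
                c(n, length(channels), length(bands)),
                dimnames = list(subject = sprintf("s%02d", seq_len(n)),
                                channel = channels, band = bands))
  bandPowerTable(vals, session)
}

evenLabels <- function(n) {
  lab <- rep(c(TRUE, FALSE), length.out = n)
  names(lab) <- sprintf("s%02d", seq_len(n))
  lab
}

# fast single-point classifier spec for simulation-heavy tests
pointSpec <- function(C = 1, gamma = 0.5, nFolds = 5, cvSeed = 1)
  classifierSpec(cGrid = C, gammaGrid = gamma, nFolds = nFolds,
                 cvSeed = cvSeed)

meanBandPowers <- function(cfg, group, session, nSeeds) {
  bands <- cfg@bands
  acc <- matrix(0, nSeeds, nrow(bands))
  for (k in seq_len(nSeeds)) {
    rec <- generateRecording(cfg, sprintf("s%d", k), group, session,
                             stream = eegresponse:::streamAt(cfg@seed, k))
    est <- welchPsd(rec)
    acc[k, ] <- colMeans(eegresponse:::bandPowerMatrix(est, bands))
  }
  colMeans(acc)
}
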