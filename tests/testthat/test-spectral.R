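bandDefs <- bandDefinitions()

test_that("Welch PSD of a sinusoid recovers its analytic power", {
  # a unit sine has power A^2/2 = 0.5 concentrated at its frequency
  est <- welchPsd(sineRecording(10, fs = 1000, durS = 30))
  df <- est@freqs[2] - est@freqs[1]
  expect_equal(sum(est@psd) * df, 0.5, tolerance = 0.01)
  near <- abs(est@freqs - 10) <= 2
  expect_gt(sum(est@psd[, near]) / sum(est@psd), 0.99)
})

test_that("integrated Welch PSD matches signal variance (Parseval)", {
  set.seed(7)
  err <- vapply(1:20, function(k) {
    x <- rnorm(30 * 500, sd = 2)
    est <- welchPsd(x, fs = 500)
    df <- est@freqs[2] - est@freqs[1]
    sum(est@psd) * df / 4 - 1
  }, 0)
  expect_lt(abs(mean(err)), 0.03)
})

test_that("PSD scales as the square of the signal amplitude", {
  set.seed(8)
  x <- rnorm(5000)
  a <- welchPsd(x, fs = 500)
  b <- welchPsd(3 * x, fs = 500)
  expect_equal(b@psd, 9 * a@psd)
})

test_that("degenerate and invalid Welch inputs are handled", {
  z <- welchPsd(numeric(1000), fs = 500)
  expect_true(all(z@psd == 0))
  expect_error(welchPsd(rnorm(100), fs = 500), "shorter than one")
})

test_that("segment bookkeeping follows the 50% overlap convention", {
  est <- welchPsd(rnorm(150 * 1000), fs = 1000)
  expect_identical(est@nSegments, 299L)   # 2 * 150 - 1
  expect_equal(est@freqs, 0:500)
})

test_that("band power averages the half-open [f_low, f_high) bins", {
  est <- welchPsd(rnorm(20 * 200), fs = 200)
  # constant psd -> band power equals that constant for every band
  flat <- est
  flat@psd[] <- 3.25
  for (b in seq_len(nrow(bandDefs)))
    expect_equal(unname(bandPower(flat, bandDefs$f_low[b],
                                  bandDefs$f_high[b])), 3.25)
  # manual oracle on the 1-Hz grid: theta averages bins {4,5,6,7}
  expect_equal(bandPower(est, 4, 8),
               rowMeans(est@psd[, est@freqs %in% 4:7, drop = FALSE]))
  # a 10 Hz tone lands in high alpha [10, 12), far above delta
  tone <- welchPsd(sineRecording(10, fs = 500, durS = 20))
  expect_gt(bandPower(tone, 10, 12)[[1]] / bandPower(tone, 1, 4)[[1]], 100)
  # an 8 Hz tone belongs to low alpha, not theta
  edge <- welchPsd(sineRecording(8, fs = 500, durS = 20))
  expect_gt(bandPower(edge, 8, 10)[[1]] / bandPower(edge, 4, 8)[[1]], 10)
  expect_error(bandPower(est, 0.01, 0.4), "no frequency bins")
})

test_that("integral mode returns total rather than mean in-band power", {
  est <- welchPsd(sineRecording(10, fs = 500, durS = 20))
  expect_equal(bandPower(est, 8, 12, mode = "integral")[[1]], 0.5,
               tolerance = 0.02)
})

test_that("band-power tables assemble per session with stable axes", {
  cfg <- smallConfig(nResponders = 2, nNonresponders = 2, fs = 250,
                     durationS = 4)
  co <- generateCohort(cfg)
  tabs <- buildBandPowerTable(co$recordings)
  expect_named(tabs, c("pre", "post"))
  expect_equal(dim(bandValues(tabs$pre)), c(4, 3, 5))
  expect_identical(subjectIds(tabs$pre), unique(co$clinical$subject_id))
  # composition: table entry equals direct welch + band power of that file
  rec <- co$recordings[[1]]
  est <- welchPsd(rec)
  expect_equal(bandValues(tabs$pre)[subjectId(rec), , "theta"],
               bandPower(est, 4, 8))
  # permuting input order permutes the subject axis identically
  tabs2 <- buildBandPowerTable(rev(co$recordings))
  ord <- subjectIds(tabs2$pre)
  expect_equal(bandValues(tabs2$pre),
               bandValues(tabs$pre)[ord, , , drop = FALSE])
  # heterogeneous channel sets are a data error naming the subject
  odd <- makeRecording(matrix(rnorm(500), 2), fs = 250, subject = "intruder",
                       channels = c("CZ", "PZ"))
  expect_error(buildBandPowerTable(c(co$recordings, odd)), "intruder")
})
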