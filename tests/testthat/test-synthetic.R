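test_that("recordings have the configured shape and are reproducible", {
  cfg <- smallConfig(fs = 250, durationS = 10)
  st <- eegresponse:::streamAt(cfg@seed, 1L)
  rec <- generateRecording(cfg, "s1", "responder", "pre", stream = st)
  expect_equal(ncol(signalMatrix(rec)), 250 * 10)
  expect_identical(channelLabels(rec), cfg@channelLabels)
  rec2 <- generateRecording(cfg, "s1", "responder", "pre", stream = st)
  expect_identical(signalMatrix(rec), signalMatrix(rec2))
  other <- generateRecording(cfg, "s1", "responder", "pre",
                             stream = eegresponse:::streamAt(cfg@seed, 2L))
  expect_false(identical(signalMatrix(rec), signalMatrix(other)))
})

test_that("invalid generator inputs are rejected", {
  expect_error(smallConfig(fs = 50), "twice the highest band edge")
  expect_error(smallConfig(channels = c("CZ", "CZ")), "unique")
  cfg <- smallConfig()
  expect_error(generateRecording(cfg, "s1", "patient", "pre"),
               "unknown group")
  expect_error(generateRecording(cfg, "s1", "responder", "mid"),
               "unknown session")
})

test_that("realized Welch band power matches the configured targets", {
  # no subject variability / background: isolates the calibration of the
  # band-limited components against the Welch band response
  cfg <- smallConfig(effectMap = data.frame(group = character(),
                                            session = character(),
                                            channel = character(),
                                            band = character(),
                                            factor = numeric()))
  got <- meanBandPowers(cfg, "responder", "pre", nSeeds = 20)
  expect_equal(got, unname(targetBandPower(cfg)[cfg@bands$name]),
               tolerance = 0.05)
})

test_that("effect-map factors scale measured band power multiplicatively", {
  em <- data.frame(group = "responder", session = "post", channel = "*",
                   band = "beta", factor = 0.5)
  cfg <- smallConfig(effectMap = em)
  pre <- meanBandPowers(cfg, "responder", "pre", nSeeds = 20)
  post <- meanBandPowers(cfg, "responder", "post", nSeeds = 20)
  beta <- which(cfg@bands$name == "beta")
  expect_equal(post[beta] / pre[beta], 0.5, tolerance = 0.1)
  # unaffected bands keep their ratio at 1
  expect_equal(post[-beta] / pre[-beta], rep(1, 4), tolerance = 0.1)
})

test_that("lognormal subject factors have mean one on the power scale", {
  cfg <- smallConfig(channels = c("CZ", "O1"), fs = 250, durationS = 10,
                     subjectSd = 0.4,
                     effectMap = defaultEffectMap()[0, ])
  got <- meanBandPowers(cfg, "nonresponder", "pre", nSeeds = 60)
  expect_equal(mean(got / targetBandPower(cfg)[cfg@bands$name]), 1,
               tolerance = 0.1)
})

test_that("clinical records always satisfy their group's responder rule", {
  for (group in c("responder", "nonresponder")) {
    recs <- lapply(1:500, function(k)
      generateClinical(sprintf("s%d", k), group,
                       stream = eegresponse:::streamAt(11L, k)))
    tab <- do.call(rbind, recs)
    lab <- labelResponders(tab)
    expect_true(all(lab == (group == "responder")))
    expect_true(all(tab$sev_post >= 0 & tab$sx_post >= 0))
    expect_true(all(tab$sev_pre > 0 & tab$sx_pre > 0))
  }
})

test_that("cohorts have two recordings per subject and are deterministic", {
  cfg <- smallConfig(nResponders = 3, nNonresponders = 4, fs = 250,
                     durationS = 2)
  co <- generateCohort(cfg)
  expect_length(co$recordings, 14)
  expect_equal(nrow(co$clinical), 7)
  expect_equal(sum(co$clinical$responder), 3)
  sessions <- vapply(co$recordings, sessionLabel, "")
  expect_equal(unname(table(sessions)[c("pre", "post")]), c(7L, 7L),
               ignore_attr = TRUE)
  co2 <- generateCohort(cfg)
  expect_identical(lapply(co$recordings, signalMatrix),
                   lapply(co2$recordings, signalMatrix))
  cfg2 <- smallConfig(nResponders = 3, nNonresponders = 4, fs = 250,
                      durationS = 2, seed = 99)
  co3 <- generateCohort(cfg2)
  expect_false(identical(signalMatrix(co$recordings[[1]]),
                         signalMatrix(co3$recordings[[1]])))
})

test_that("growing the cohort never reshuffles earlier subjects", {
  cfg <- smallConfig(nResponders = 2, nNonresponders = 2, fs = 250,
                     durationS = 2)
  cfgBig <- smallConfig(nResponders = 3, nNonresponders = 4, fs = 250,
                        durationS = 2)
  a <- generateCohort(cfg)
  b <- generateCohort(cfgBig)
  pick <- function(co, id) Filter(function(r) subjectId(r) == id,
                                  co$recordings)
  for (id in c("resp01", "resp02", "nonr01", "nonr02"))
    expect_identical(lapply(pick(a, id), signalMatrix),
                     lapply(pick(b, id), signalMatrix))
})
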