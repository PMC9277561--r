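clin <- function(sev, sx, id = "s1")
  data.frame(subject_id = id, sev_pre = sev[1], sev_post = sev[2],
             sx_pre = sx[1], sx_post = sx[2])

test_that("responder labeling applies the strict both-scores >50% rule", {
  expect_true(labelResponders(clin(c(40, 8), c(12, 2)))[[1]])
  expect_false(labelResponders(clin(c(40, 30), c(12, 8)))[[1]])
  # 75% on Sev but only 42% on Sx: both criteria required
  expect_false(labelResponders(clin(c(40, 10), c(12, 7)))[[1]])
  expect_true(labelResponders(clin(c(40, 10), c(12, 7)),
                              bothScores = FALSE)[[1]])
  # exactly 50% is not an improvement "by more than 50%"
  expect_false(labelResponders(clin(c(40, 20), c(12, 6)))[[1]])
  expect_warning(lab <- labelResponders(clin(c(0, 0), c(12, 2), id = "z1")),
                 "z1")
  expect_true(is.na(lab[["z1"]]))
})

test_that("change rate is (pre - post) / pre with invalid entries flagged", {
  mk <- function(x, session) bandPowerTable(
    array(x, c(1, 1, 1), dimnames = list("s1", "CZ", "beta")), session)
  expect_equal(bandValues(changeRate(mk(2, "pre"), mk(1, "post")))[1, 1, 1],
               0.5)
  expect_equal(bandValues(changeRate(mk(3, "pre"), mk(3, "post")))[1, 1, 1],
               0)
  # fronto-central beta example: 0.481 -> 0.331 is a ~31.2% decrease
  expect_equal(bandValues(changeRate(mk(0.481, "pre"),
                                     mk(0.331, "post")))[1, 1, 1],
               0.312, tolerance = 5e-4)
  expect_warning(cr <- changeRate(mk(0, "pre"), mk(1, "post")), "invalid")
  expect_true(is.na(bandValues(cr)[1, 1, 1]))
  bad <- bandPowerTable(array(1, c(1, 1, 1),
                              dimnames = list("s2", "CZ", "beta")), "post")
  expect_error(changeRate(mk(1, "pre"), bad), "share")
})

test_that("change rate is invariant to common rescaling of both tables", {
  set.seed(10)
  pre <- makeBandTable(n = 8, session = "pre")
  post <- makeBandTable(n = 8, session = "post")
  a <- changeRate(pre, post)
  pre@values <- pre@values * 7.3
  post@values <- post@values * 7.3
  b <- changeRate(pre, post)
  expect_equal(bandValues(a), bandValues(b))
})

test_that("BH adjustment matches the worked step-up example", {
  expect_equal(fdrAdjust(0.03), 0.03)
  expect_equal(fdrAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdrAdjust(rep(1, 5)), rep(1, 5))
  expect_error(fdrAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("test selection follows the normality and variance gates", {
  set.seed(11)
  n <- 40
  mkTable <- function(resp, nonresp) {
    vals <- array(NA_real_, c(2 * n, 1, 1),
                  dimnames = list(sprintf("s%02d", 1:(2 * n)), "CZ",
                                  "beta"))
    vals[1:n, 1, 1] <- resp
    vals[(n + 1):(2 * n), 1, 1] <- nonresp
    new("ChangeRateTable", values = vals)
  }
  lab <- rep(c(TRUE, FALSE), each = n)
  names(lab) <- sprintf("s%02d", 1:(2 * n))
  # normal, equal variance -> pooled t with df = n1 + n2 - 2
  res <- compareGroups(mkTable(rnorm(n), rnorm(n, 0.3)), lab, "beta")
  expect_equal(res$test_used, "pooled-t")
  expect_equal(res$df, 2 * n - 2)
  # normal, strongly unequal variance -> Welch with fractional df
  res <- compareGroups(mkTable(rnorm(n, sd = 0.05), rnorm(n, 1, sd = 2)),
                       lab, "beta")
  expect_equal(res$test_used, "welch-t")
  expect_lt(res$df, 2 * n - 2)
  # heavily skewed -> Mann-Whitney
  res <- compareGroups(mkTable(rexp(n)^3, rexp(n)^3 + 2), lab, "beta")
  expect_equal(res$test_used, "mann-whitney")
  expect_true(is.na(res$df))
  # identical constants in both groups: degenerate, excluded
  suppressMessages(
    res <- compareGroups(mkTable(rep(1, n), rep(1, n)), lab, "beta"))
  expect_equal(res$test_used, "excluded")
  expect_true(is.na(res$p_raw))
})

test_that("group comparisons are label-symmetric and order-invariant", {
  set.seed(12)
  vals <- array(rnorm(30 * 3 * 1), c(30, 3, 1),
                dimnames = list(sprintf("s%02d", 1:30),
                                c("CZ", "PZ", "F3"), "theta"))
  ct <- new("ChangeRateTable", values = vals)
  lab <- evenLabels(30)
  a <- compareGroups(ct, lab, "theta")
  # swapping group labels flips the t statistic, p unchanged
  b <- compareGroups(ct, !lab, "theta")
  flip <- ifelse(a$test_used %in% c("pooled-t", "welch-t"), -1, 1)
  expect_equal(a$p_raw, b$p_raw)
  expect_equal(a$statistic[flip == -1], -b$statistic[flip == -1])
  # permuting subject rows changes nothing
  perm <- sample(30)
  ct2 <- new("ChangeRateTable", values = vals[perm, , , drop = FALSE])
  c2 <- compareGroups(ct2, lab, "theta")
  expect_equal(a$p_raw, c2$p_raw)
  expect_equal(a$p_adj, c2$p_adj)
  # BH never decreases a p-value
  expect_true(all(a$p_adj >= a$p_raw))
})
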