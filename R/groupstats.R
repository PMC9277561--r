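# Responder labeling, band-power change rates, and per-channel group
# comparisons with normality/variance-gated test choice and
# Benjamini-Hochberg FDR control.

#' Label treatment responders from clinical scores
#'
#' A subject is a responder when BOTH the severity total and the symptom
#' count improved strictly more than \code{threshold} (default 50\%):
#' \code{(pre - post)/pre > threshold} for Sev and Sx. Subjects with a
#' non-positive pre score have an undefined improvement fraction and are
#' returned as NA with a warning.
#'
#' @param clinical data.frame with columns \code{subject_id},
#'   \code{sev_pre}, \code{sev_post}, \code{sx_pre}, \code{sx_post}.
#' @param threshold improvement fraction that must be exceeded (default 0.5).
#' @param bothScores require both Sev and Sx to improve (default TRUE);
#'   if FALSE only Sev is used.
#' @return Named logical vector (TRUE = responder), names =
#'   \code{subject_id}.
#' @examples
#' cl <- data.frame(subject_id = "s1", sev_pre = 40, sev_post = 8,
#'                  sx_pre = 12, sx_post = 2)
#' labelResponders(cl)
#' @export
labelResponders <- function(clinical, threshold = 0.5, bothScores = TRUE) {
  need <- c("subject_id", "sev_pre", "sev_post", "sx_pre", "sx_post")
  stopifnot(all(need %in% names(clinical)))
  bad <- !is.finite(clinical$sev_pre) | clinical$sev_pre <= 0 |
    (bothScores & (!is.finite(clinical$sx_pre) | clinical$sx_pre <= 0))
  if (any(bad))
    warning("excluding subject(s) with non-positive pre score: ",
            paste(clinical$subject_id[bad], collapse = ", "))
  sevImp <- (clinical$sev_pre - clinical$sev_post) / clinical$sev_pre
  sxImp <- (clinical$sx_pre - clinical$sx_post) / clinical$sx_pre
  out <- if (bothScores) sevImp > threshold & sxImp > threshold
  else sevImp > threshold
  out[bad] <- NA
  names(out) <- clinical$subject_id
  out
}

#' Band-power change rate
#'
#' Computes \code{(P_pre - P_post) / P_pre} elementwise; positive values
#' denote a power decrease after treatment. Both tables must share the
#' subject, channel and band axes. Entries with a non-positive
#' pre-treatment power are set to NA (invalid) with a warning.
#'
#' @param pre,post \linkS4class{BandPowerTable}s for the two sessions.
#' @return A \linkS4class{ChangeRateTable}.
#' @examples
#' # a pre power of 0.481 dropping to 0.331 is a change rate of ~0.312
#' (0.481 - 0.331) / 0.481
#' @export
changeRate <- function(pre, post) {
  stopifnot(is(pre, "BandPowerTable"), is(post, "BandPowerTable"))
  if (!identical(dimnames(pre@values), dimnames(post@values)))
    stop("pre and post tables must share subject/channel/band axes")
  vals <- (pre@values - post@values) / pre@values
  invalid <- !(pre@values > 0)
  if (any(invalid)) {
    warning(sum(invalid), " entries with non-positive pre power flagged invalid")
    vals[invalid] <- NA_real_
  }
  new("ChangeRateTable", values = vals)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values with monotonicity enforcement, clipped to 1.
#'
#' @param p numeric vector of raw p-values in [0, 1] (NAs pass through).
#' @return Adjusted p-values, same length and order as \code{p}.
#' @export
fdrAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# Levene's test (mean-centered), two groups
levenePvalue <- function(x, y) {
  g <- factor(rep(c("a", "b"), c(length(x), length(y))))
  res <- car::leveneTest(c(x, y) ~ g, center = mean)
  res[["Pr(>F)"]][1L]
}

# Lilliefors-corrected KS normality check; inapplicable (n < 5 or constant)
# counts as failed so the distribution-free test is used downstream
normalityOk <- function(x, alpha) {
  if (length(x) < 5L || stats::sd(x) == 0) return(FALSE)
  nortest::lillie.test(x)$p.value >= alpha
}

#' Per-channel group comparison of change rates
#'
#' For one band, compares responder and non-responder change rates channel
#' by channel. Each group is first checked for normality
#' (Kolmogorov-Smirnov with Lilliefors correction, alpha = 0.05); if either
#' group fails, a two-sided Mann-Whitney U test is used (normal
#' approximation with tie and continuity correction). Otherwise a
#' two-sample t-test is used: pooled when Levene's test (mean-centered)
#' accepts equal variances at alpha = 0.05, Welch (with Satterthwaite
#' fractional degrees of freedom) otherwise. The t statistic is oriented
#' responder minus non-responder. Raw p-values from all testable channels
#' of the band form one Benjamini-Hochberg adjustment family.
#'
#' Channels where the pooled values are constant (zero variance) are
#' degenerate: they are flagged with \code{test_used = "excluded"} and take
#' no part in the adjustment. Invalid (NA) change rates are dropped per
#' channel; a channel is also excluded when fewer than 2 valid subjects
#' remain in either group.
#'
#' @param changes a \linkS4class{ChangeRateTable}.
#' @param labels named logical vector from \code{\link{labelResponders}}
#'   (NA-labelled subjects are dropped).
#' @param band band name to test.
#' @param alpha gate level for the normality and variance checks.
#' @return data.frame with one row per channel: \code{channel},
#'   \code{n_resp}, \code{n_nonresp}, \code{normality_ok},
#'   \code{variance_equal}, \code{test_used} (\code{"pooled-t"},
#'   \code{"welch-t"}, \code{"mann-whitney"} or \code{"excluded"}),
#'   \code{statistic}, \code{df}, \code{p_raw}, \code{p_adj}; the band name
#'   is attached as attribute \code{"band"}.
#' @export
compareGroups <- function(changes, labels, band, alpha = 0.05) {
  stopifnot(is(changes, "ChangeRateTable"))
  if (!band %in% bandNames(changes))
    stop("unknown band: ", band)
  subjects <- subjectIds(changes)
  if (is.null(names(labels)) || !all(subjects %in% names(labels)))
    stop("labels must be named and cover every subject in the table")
  lab <- labels[subjects]
  keep <- !is.na(lab)
  arr <- changes@values[keep, , band, drop = FALSE]
  mat <- matrix(arr, nrow = dim(arr)[1L], dimnames = dimnames(arr)[1:2])
  lab <- lab[keep]
  if (sum(lab) < 2L || sum(!lab) < 2L)
    stop("need at least 2 subjects per group")
  channels <- channelLabels(changes)
  res <- lapply(channels, function(ch) {
    x <- mat[lab, ch]
    y <- mat[!lab, ch]
    x <- x[is.finite(x)]
    y <- y[is.finite(y)]
    row <- data.frame(channel = ch, n_resp = length(x),
                      n_nonresp = length(y), normality_ok = NA,
                      variance_equal = NA, test_used = "excluded",
                      statistic = NA_real_, df = NA_real_,
                      p_raw = NA_real_, stringsAsFactors = FALSE)
    if (length(x) < 2L || length(y) < 2L || stats::sd(c(x, y)) == 0)
      return(row)
    row$normality_ok <- normalityOk(x, alpha) && normalityOk(y, alpha)
    if (!row$normality_ok) {
      wt <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
      row$test_used <- "mann-whitney"
      row$statistic <- unname(wt$statistic)
      row$p_raw <- wt$p.value
    } else {
      row$variance_equal <- levenePvalue(x, y) >= alpha
      tt <- stats::t.test(x, y, var.equal = row$variance_equal)
      row$test_used <- if (row$variance_equal) "pooled-t" else "welch-t"
      row$statistic <- unname(tt$statistic)
      row$df <- unname(tt$parameter)
      row$p_raw <- tt$p.value
    }
    row
  })
  res <- do.call(rbind, res)
  res$p_adj <- NA_real_
  ok <- !is.na(res$p_raw)
  res$p_adj[ok] <- fdrAdjust(res$p_raw[ok])
  if (any(!ok))
    message("band ", band, ": ", sum(!ok), " degenerate channel(s) excluded")
  attr(res, "band") <- band
  res
}
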