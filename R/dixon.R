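# Two-sided critical values for Dixon's Q, n = 3..30, by significance level.
# Ratio variant follows the sample size: r10 (n<=7), r11 (8-10), r21 (11-13),
# r22 (n>=14). Values are 1-alpha quantiles of the null (iid normal)
# distribution of the two-sided statistic, computed once by Monte Carlo
# (2e6 replicates per n) and checked against the classical published r10
# tables at the 0.10/0.05/0.02 levels (agreement within 0.001).
DIXON_ALPHAS <- c(0.10, 0.05, 0.02, 0.01, 0.005, 0.002)
DIXON_CRIT <- matrix(c(
  0.9413, 0.9702, 0.9879, 0.9939, 0.9970, 0.9988,
  0.7656, 0.8296, 0.8891, 0.9204, 0.9432, 0.9635,
  0.6423, 0.7104, 0.7811, 0.8233, 0.8573, 0.8932,
  0.5622, 0.6275, 0.6982, 0.7427, 0.7809, 0.8233,
  0.5071, 0.5688, 0.6374, 0.6816, 0.7201, 0.7645,
  0.5438, 0.6082, 0.6764, 0.7186, 0.7551, 0.7959,
  0.5021, 0.5635, 0.6301, 0.6719, 0.7079, 0.7495,
  0.4707, 0.5299, 0.5940, 0.6350, 0.6704, 0.7115,
  0.5719, 0.6207, 0.6735, 0.7069, 0.7362, 0.7696,
  0.5428, 0.5907, 0.6425, 0.6758, 0.7053, 0.7390,
  0.5184, 0.5654, 0.6170, 0.6501, 0.6800, 0.7139,
  0.5385, 0.5864, 0.6380, 0.6701, 0.6988, 0.7324,
  0.5179, 0.5647, 0.6155, 0.6475, 0.6762, 0.7088,
  0.4996, 0.5457, 0.5953, 0.6275, 0.6558, 0.6884,
  0.4840, 0.5292, 0.5783, 0.6103, 0.6380, 0.6706,
  0.4697, 0.5141, 0.5626, 0.5935, 0.6214, 0.6539,
  0.4570, 0.5007, 0.5487, 0.5795, 0.6062, 0.6374,
  0.4457, 0.4888, 0.5359, 0.5665, 0.5939, 0.6253,
  0.4354, 0.4783, 0.5251, 0.5551, 0.5818, 0.6137,
  0.4259, 0.4680, 0.5144, 0.5442, 0.5711, 0.6020,
  0.4177, 0.4594, 0.5053, 0.5349, 0.5614, 0.5925,
  0.4097, 0.4509, 0.4962, 0.5257, 0.5517, 0.5829,
  0.4023, 0.4432, 0.4883, 0.5173, 0.5439, 0.5749,
  0.3955, 0.4359, 0.4807, 0.5098, 0.5357, 0.5660,
  0.3892, 0.4293, 0.4737, 0.5027, 0.5282, 0.5580,
  0.3833, 0.4228, 0.4668, 0.4952, 0.5208, 0.5511,
  0.3780, 0.4172, 0.4607, 0.4891, 0.5145, 0.5443,
  0.3729, 0.4117, 0.4554, 0.4836, 0.5091, 0.5384),
  nrow = 28, byrow = TRUE,
  dimnames = list(3:30, as.character(DIXON_ALPHAS)))

dixon_variant <- function(n) {
  if (n <= 7) "r10" else if (n <= 10) "r11" else if (n <= 13) "r21" else "r22"
}

# ratio of the suspect gap to the (variant-specific) range, for both tails
dixon_ratios <- function(x) {
  n <- length(x)
  s <- sort(x)
  v <- dixon_variant(n)
  ratio <- function(num, den) if (den > 0) num / den else 0
  switch(v,
    r10 = c(lo = ratio(s[2] - s[1], s[n] - s[1]),
            hi = ratio(s[n] - s[n - 1], s[n] - s[1])),
    r11 = c(lo = ratio(s[2] - s[1], s[n - 1] - s[1]),
            hi = ratio(s[n] - s[n - 1], s[n] - s[2])),
    r21 = c(lo = ratio(s[3] - s[1], s[n - 1] - s[1]),
            hi = ratio(s[n] - s[n - 2], s[n] - s[2])),
    r22 = c(lo = ratio(s[3] - s[1], s[n - 2] - s[1]),
            hi = ratio(s[n] - s[n - 2], s[n] - s[3])))
}

#' Dixon's Q test for a single small-sample outlier
#'
#' Two-sided Dixon test using the ratio variant appropriate to the sample
#' size (r10 for n <= 7, r11 for 8-10, r21 for 11-13, r22 for n >= 14). The
#' more extreme tail (larger ratio) is the suspect; it is flagged when its
#' Q exceeds the two-sided critical value at `alpha`. At most one value is
#' flagged per call.
#'
#' @param values Numeric vector, 3 <= length <= 30.
#' @param alpha Significance level; one of 0.10, 0.05, 0.02, 0.01, 0.005,
#'   0.002 (default 0.002).
#' @return A list of class `dixon_test`: `statistic` (Q), `critical`,
#'   `alpha`, `variant`, `n`, `flagged` (index into `values`, or `NA` if no
#'   outlier), `value` (the flagged value or `NA`), `side` (`"high"`/`"low"`).
#' @export
#' @examples
#' dixon_test(c(2.1, 2.2, 2.3, 2.4, 9.9), alpha = 0.05)
dixon_test <- function(values, alpha = 0.002) {
  n <- length(values)
  if (n < 3L) abort("Dixon's Q needs at least 3 values")
  if (n > 30L) abort("Dixon's Q is tabulated for n <= 30; use a different test")
  if (anyNA(values)) abort("values must not contain NA")
  a_col <- match(alpha, DIXON_ALPHAS)
  if (is.na(a_col)) {
    abort(paste0("alpha must be one of ", paste(DIXON_ALPHAS, collapse = ", ")))
  }
  crit <- DIXON_CRIT[as.character(n), a_col]
  r <- dixon_ratios(values)
  side <- if (r["hi"] >= r["lo"]) "high" else "low"
  q <- unname(max(r))
  flagged <- NA_integer_; value <- NA_real_
  if (q > crit && q > 0) {
    flagged <- if (side == "high") which.max(values) else which.min(values)
    value <- values[flagged]
  }
  structure(list(statistic = q, critical = unname(crit), alpha = alpha,
                 variant = dixon_variant(n), n = n, flagged = flagged,
                 value = value, side = side), class = "dixon_test")
}

#' @export
print.dixon_test <- function(x, ...) {
  cat(sprintf("Dixon's Q (%s, n=%d): Q=%.4f, critical=%.4f at alpha=%g\n",
              x$variant, x$n, x$statistic, x$critical, x$alpha))
  if (is.na(x$flagged)) cat("  no outlier flagged\n")
  else cat(sprintf("  flagged value %g (index %d, %s side)\n",
                   x$value, x$flagged, x$side))
  invisible(x)
}

#' Flag cycle-specific substitution-rate spikes
#'
#' Tests each sequencing cycle's substitution rate against the rates of the
#' surrounding window (default +/- 10 cycles) with Dixon's Q. A cycle is
#' flagged when it is the Dixon-flagged extreme of its own window. A second
#' pass re-tests every cycle with other flagged cycles removed from its
#' window, so adjacent spikes do not mask one another.
#'
#' @param profile A `bamqc_result` or its `per_cycle` tibble.
#' @param window Half-width of the context window in cycles (default 10).
#' @param alpha Dixon significance level (default 0.002).
#' @param stratum Stratum to analyse (default `"overall"`).
#' @return Integer vector of flagged cycles (possibly empty).
#' @export
detect_cycle_spikes <- function(profile, window = 10L, alpha = 0.002,
                                stratum = "overall") {
  pc <- if (inherits(profile, "bamqc_result")) profile$per_cycle else profile
  pc <- filter(pc, .data$stratum == !!stratum, is.finite(.data$subst_rate))
  rates <- setNames(pc$subst_rate, pc$cycle)
  cycles <- pc$cycle
  n_cyc <- length(cycles)
  if (n_cyc < 4L) {
    warn("too few cycles with defined rates; no spike detection possible")
    return(integer())
  }
  if (n_cyc < window + 1L) {
    window <- max(3L, n_cyc - 1L)
    warn(paste0("read shorter than the requested window; shrunk to ", window))
  }
  test_pass <- function(excluded) {
    flags <- integer()
    for (i in seq_len(n_cyc)) {
      foc <- cycles[i]
      win <- cycles[abs(cycles - foc) <= window]
      win <- setdiff(win, setdiff(excluded, foc))
      if (length(win) < 4L || length(win) > 30L) {
        win <- utils::head(win, 30L)
        if (length(win) < 4L) next
      }
      v <- rates[as.character(win)]
      dt <- dixon_test(unname(v), alpha = alpha)
      if (!is.na(dt$flagged) && win[dt$flagged] == foc) flags <- c(flags, foc)
    }
    flags
  }
  pass1 <- test_pass(integer())
  sort(unique(test_pass(pass1)))
}
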