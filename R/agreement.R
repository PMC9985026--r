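#' Paired percent-constriction events from two devices
#'
#' @param a,b Non-negative percent values from device A and device B,
#'   paired by event index, equal length.
#' @return A list of class `paired_events`.
#' @export
paired_events <- function(a, b) {
  if (length(a) != length(b)) {
    stop_arg("paired series must have equal length (%d vs %d)",
             length(a), length(b))
  }
  if (any(!is.finite(a)) || any(!is.finite(b)) || any(a < 0) || any(b < 0)) {
    stop_arg("paired percent values must be finite and non-negative")
  }
  structure(list(a = as.numeric(a), b = as.numeric(b), n = length(a)),
            class = "paired_events")
}

#' Pair two event series by nearest time
#'
#' Greedy nearest-in-time matching within a tolerance window; each event is
#' used at most once, closest gaps matched first. Unmatched events are
#' dropped and their count reported.
#'
#' @param times_a,percents_a Event nadir times (s) and percent values from
#'   device A.
#' @param times_b,percents_b Same for device B.
#' @param window_s Maximum time difference for a match (default 60 s).
#' @return A `paired_events` with attributes `unmatched_a`, `unmatched_b`.
#' @export
pair_events_by_time <- function(times_a, percents_a, times_b, percents_b,
                                window_s = 60) {
  stopifnot(length(times_a) == length(percents_a),
            length(times_b) == length(percents_b))
  if (!length(times_a) || !length(times_b)) {
    p <- paired_events(numeric(0), numeric(0))
    attr(p, "unmatched_a") <- length(times_a)
    attr(p, "unmatched_b") <- length(times_b)
    return(p)
  }
  d <- abs(outer(times_a, times_b, "-"))
  d[d > window_s] <- NA
  pairs <- matrix(numeric(0), ncol = 2)
  while (any(is.finite(d))) {
    k <- arrayInd(which.min(d), dim(d))
    pairs <- rbind(pairs, c(percents_a[k[1]], percents_b[k[2]]))
    d[k[1], ] <- NA
    d[, k[2]] <- NA
  }
  p <- paired_events(pairs[, 1], pairs[, 2])
  attr(p, "unmatched_a") <- length(times_a) - nrow(pairs)
  attr(p, "unmatched_b") <- length(times_b) - nrow(pairs)
  p
}

#' Binned confusion matrix and percent agreement
#'
#' Bins each device's percent value with [classify_event()]
#' (small/medium/large) and counts pairs in a 3x3 confusion matrix;
#' agreement is the diagonal share in percent.
#'
#' @param pairs A [paired_events].
#' @return List with `confusion` (3x3 table, rows device A) and
#'   `agreement_pct`.
#' @examples
#' p <- paired_events(c(10, 20, 40), c(12, 28, 33))
#' confusion_agreement(p)$agreement_pct  # 100
#' @export
confusion_agreement <- function(pairs) {
  stopifnot(inherits(pairs, "paired_events"))
  if (pairs$n < 1L) stop_arg("need at least one pair")
  ba <- classify_event(pairs$a)
  bb <- classify_event(pairs$b)
  confusion <- table(device_a = ba, device_b = bb)
  list(confusion = confusion,
       agreement_pct = 100 * sum(diag(confusion)) / pairs$n)
}

#' Bland-Altman bias and limits of agreement
#'
#' Differences `d = a - b`; bias is `mean(d)` and the limits of agreement
#' are `bias +/- 1.96 * SD(d)` with the sample (n-1) standard deviation.
#' Per-pair means are returned for plotting.
#'
#' @param pairs A [paired_events] with at least 2 pairs.
#' @return List with `bias`, `loa_low`, `loa_high`, `differences`, `means`.
#' @export
bland_altman <- function(pairs) {
  stopifnot(inherits(pairs, "paired_events"))
  if (pairs$n < 2L) stop_arg("need at least two pairs")
  d <- pairs$a - pairs$b
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       differences = d, means = (pairs$a + pairs$b) / 2)
}

#' Squared Pearson correlation of paired events
#'
#' @param pairs A [paired_events] with at least 3 pairs; both series need
#'   nonzero variance.
#' @return `r^2` in `[0, 1]`.
#' @export
correlation_r2 <- function(pairs) {
  stopifnot(inherits(pairs, "paired_events"))
  if (pairs$n < 3L) stop_arg("need at least three pairs")
  if (stats::sd(pairs$a) == 0 || stats::sd(pairs$b) == 0) {
    stop_arg("undefined correlation: a series has zero variance")
  }
  stats::cor(pairs$a, pairs$b)^2
}

#' Two-sample Z-test for a difference in location
#'
#' Unpaired, unequal-variance, two-tailed:
#' \deqn{z = \frac{\bar a - \bar b}{\sqrt{s_a^2/n_a + s_b^2/n_b}}}
#' with `p = 2 * (1 - Phi(|z|))` from the standard normal.
#'
#' @param mean_a,sd_a,n_a Summary statistics of group A (`n_a >= 2`).
#' @param mean_b,sd_b,n_b Summary statistics of group B.
#' @return List of class `z_test` with `z` and two-tailed `p`.
#' @examples
#' two_sample_z(1, 1, 100, 0, 1, 100)
#' @export
two_sample_z <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  if (n_a < 2 || n_b < 2) stop_arg("both groups need n >= 2")
  if (sd_a < 0 || sd_b < 0) stop_arg("standard deviations must be >= 0")
  se <- sqrt(sd_a^2 / n_a + sd_b^2 / n_b)
  if (se == 0) stop_arg("both group variances are zero")
  z <- (mean_a - mean_b) / se
  structure(list(z = z, p = 2 * stats::pnorm(-abs(z))), class = "z_test")
}

#' @export
print.z_test <- function(x, ...) {
  cat(sprintf("<z_test> z = %.3f, two-tailed p = %.4g\n", x$z, x$p))
  invisible(x)
}

#' Full method-agreement report for paired event series
#'
#' Bundles the binned confusion agreement, Bland-Altman bias and limits,
#' and correlation r-squared for two devices' paired percent-constriction
#' series.
#'
#' @param pairs A [paired_events] with at least 3 pairs.
#' @return An object of class `agreement_report`: list with `n`,
#'   `confusion`, `agreement_pct`, `bias`, `loa_low`, `loa_high`,
#'   `r_squared`.
#' @export
agreement_report <- function(pairs) {
  ca <- confusion_agreement(pairs)
  ba <- bland_altman(pairs)
  structure(list(n = pairs$n, confusion = ca$confusion,
                 agreement_pct = ca$agreement_pct, bias = ba$bias,
                 loa_low = ba$loa_low, loa_high = ba$loa_high,
                 r_squared = correlation_r2(pairs)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> n = %d\n", x$n))
  cat(sprintf("  agreement: %.1f%%  r^2: %.3f\n", x$agreement_pct,
              x$r_squared))
  cat(sprintf("  Bland-Altman bias %.2f, limits [%.2f, %.2f]\n",
              x$bias, x$loa_low, x$loa_high))
  print(x$confusion)
  invisible(x)
}
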