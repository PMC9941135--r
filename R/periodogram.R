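#' Chi-square periodogram (Sokolove-Bushell)
#'
#' Assesses free-running rhythmicity of an activity series recorded in
#' constant darkness. For each candidate period P (in bins) the series is
#' truncated to K = floor(N/P) complete cycles and folded into P columns;
#' the statistic is
#' \deqn{Q_P = K \sum_h (M_h - \bar M)^2 / \hat\sigma^2,}
#' with column means \eqn{M_h}, grand mean \eqn{\bar M} and
#' \eqn{\hat\sigma^2 = \sum_i (x_i - \bar M)^2 / N'} over the truncated
#' \eqn{N' = K P} points. Under no rhythm \eqn{Q_P} is approximately
#' chi-square with P-1 degrees of freedom; the significance line is the
#' 1-alpha chi-square quantile at each period.
#'
#' Rhythmicity follows the usual periodogram criteria: *power* is
#' Qp - significance line at the peak period, *width* is the contiguous span
#' of periods (in hours) around the peak where Qp exceeds the line, and a fly
#' is called rhythmic when power > 120 and width > 1.5 h. These power/width
#' conventions are reconstructions of common periodogram-software practice;
#' see the package vignette.
#'
#' @param counts Activity counts binned at `bin_h` hours (e.g. 30-min bins),
#'   or an `activity_trace` (its 1-min counts are re-binned to `bin_h`).
#' @param bin_h Hours per bin (default 0.5).
#' @param period_range_h Scanned period range in hours (default 16-32, in
#'   steps of one bin).
#' @param alpha Significance level of the chi-square line (default 0.05, no
#'   multiplicity correction).
#' @param power_min,width_min_h Rhythmicity thresholds (defaults 120 and
#'   1.5 h).
#' @param min_days Minimal data span required, in days (default 5).
#' @return A list of class `chi2_periodogram`: `periods_h`, `qp`, `sig_line`,
#'   `peak_period_h`, `peak_power`, `width_h`, `rhythmic`, plus the settings.
#' @examples
#' x <- rep(c(rep(10, 24), rep(0, 24)), 10)  # 24-h square wave, 30-min bins
#' p <- chi2_periodogram(x)
#' p$peak_period_h
#' @export
chi2_periodogram <- function(counts, bin_h = 0.5,
                             period_range_h = c(16, 32), alpha = 0.05,
                             power_min = 120, width_min_h = 1.5,
                             min_days = 5) {
  if (inherits(counts, "activity_trace")) {
    bin_minutes <- as.integer(round(bin_h * 60))
    counts <- bin_activity(counts$counts, bin_minutes)
  }
  stopifnot(is.numeric(counts), all(counts >= 0), bin_h > 0)
  N <- length(counts)
  if (N * bin_h < min_days * 24)
    stop(sprintf("need at least %g days of data, got %.2f", min_days,
                 N * bin_h / 24), call. = FALSE)
  p_bins <- seq.int(round(period_range_h[1L] / bin_h),
                    round(period_range_h[2L] / bin_h))
  periods_h <- p_bins * bin_h
  qp <- vapply(p_bins, function(P) {
    K <- N %/% P
    x <- counts[seq_len(K * P)]
    gm <- mean(x)
    ssq <- sum((x - gm)^2)
    if (ssq == 0) return(0)  # constant series carries no rhythm
    col_means <- rowMeans(matrix(x, nrow = P))
    K * sum((col_means - gm)^2) / (ssq / (K * P))
  }, numeric(1L))
  sig_line <- stats::qchisq(1 - alpha, df = p_bins - 1L)

  excess <- qp - sig_line
  peak <- which.max(excess)
  peak_power <- excess[peak]
  # contiguous run of periods above the line containing the peak
  above <- qp > sig_line
  width_h <- 0
  if (above[peak]) {
    lo <- peak
    while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
    hi <- peak
    while (hi < length(above) && above[hi + 1L]) hi <- hi + 1L
    width_h <- (hi - lo + 1L) * bin_h
  }
  structure(list(periods_h = periods_h, qp = qp, sig_line = sig_line,
                 peak_period_h = periods_h[peak], peak_power = peak_power,
                 width_h = width_h,
                 rhythmic = peak_power > power_min && width_h > width_min_h,
                 bin_h = bin_h, alpha = alpha),
            class = "chi2_periodogram")
}

#' @export
print.chi2_periodogram <- function(x, ...) {
  cat(sprintf(
    "<chi2_periodogram> peak %.2f h, power %.1f, width %.1f h -> %s\n",
    x$peak_period_h, x$peak_power, x$width_h,
    if (x$rhythmic) "rhythmic" else "arrhythmic"))
  invisible(x)
}

#' Re-bin a 1-min count series
#'
#' @param counts Integer 1-min counts.
#' @param bin_minutes Bin width; must divide the series length.
#' @return Numeric vector of per-bin sums.
#' @export
bin_activity <- function(counts, bin_minutes = 30L) {
  if (inherits(counts, "activity_trace")) counts <- counts$counts
  n <- length(counts) %/% bin_minutes
  colSums(matrix(counts[seq_len(n * bin_minutes)], nrow = bin_minutes))
}

#' Group summary of free-running period
#'
#' Averages the peak period over flies classified rhythmic, per genotype.
#'
#' @param results List of `chi2_periodogram` objects.
#' @param genotype Character vector, one label per result.
#' @return Data.frame `genotype, n_rhythmic, mean_period_h, sem_period_h`;
#'   zero rows (with a warning) if no fly is rhythmic.
#' @export
period_estimate <- function(results, genotype = rep("all", length(results))) {
  stopifnot(length(results) == length(genotype))
  rhythmic <- vapply(results, `[[`, logical(1L), "rhythmic")
  if (!any(rhythmic)) {
    warning("no rhythmic flies", call. = FALSE)
    return(data.frame(genotype = character(), n_rhythmic = integer(),
                      mean_period_h = numeric(), sem_period_h = numeric()))
  }
  per <- vapply(results, `[[`, numeric(1L), "peak_period_h")[rhythmic]
  gt <- genotype[rhythmic]
  out <- do.call(rbind, lapply(split(per, gt), function(p) {
    data.frame(n_rhythmic = length(p), mean_period_h = mean(p),
               sem_period_h = if (length(p) > 1L)
                 stats::sd(p) / sqrt(length(p)) else 0)
  }))
  data.frame(genotype = rownames(out), out, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Periodogram results as a table
#'
#' @param results List of `chi2_periodogram` objects.
#' @param fly_id Character vector of fly identifiers.
#' @return Summary data.frame `fly_id, peak_period_h, power, width_h,
#'   rhythmic`.
#' @export
periodogram_summary <- function(results, fly_id = seq_along(results)) {
  data.frame(fly_id = as.character(fly_id),
             peak_period_h = vapply(results, `[[`, numeric(1L), "peak_period_h"),
             power = vapply(results, `[[`, numeric(1L), "peak_power"),
             width_h = vapply(results, `[[`, numeric(1L), "width_h"),
             rhythmic = vapply(results, `[[`, logical(1L), "rhythmic"),
             stringsAsFactors = FALSE)
}
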