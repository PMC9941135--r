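#' Detect sleep bouts
#'
#' Fly sleep is scored behaviorally: a sleep bout is any maximal run of at
#' least 5 consecutive minutes with zero beam-break counts, and a sleep minute
#' is any minute inside such a run.
#'
#' @param counts Integer vector of 1-min activity counts (or an
#'   `activity_trace`, whose counts are used).
#' @param min_bout_min Minimal run length that counts as sleep (default 5,
#'   the standard definition).
#' @return A data.frame with one row per bout: `onset_min` (0-based minute
#'   index), `duration_min`.
#' @examples
#' detect_sleep_bouts(c(1, 0, 0, 0, 0, 0, 2, 0))
#' @export
detect_sleep_bouts <- function(counts, min_bout_min = 5L) {
  if (inherits(counts, "activity_trace")) counts <- counts$counts
  stopifnot(is.numeric(counts), length(counts) >= min_bout_min,
            all(counts >= 0))
  r <- rle(counts == 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_bout_min
  data.frame(onset_min = starts[keep] - 1L,
             duration_min = r$lengths[keep])
}

# logical per-minute sleep vector (minute inside a >=5-min zero run)
sleep_minutes <- function(counts, min_bout_min = 5L) {
  if (inherits(counts, "activity_trace")) counts <- counts$counts
  r <- rle(counts == 0)
  rep(r$values & r$lengths >= min_bout_min, r$lengths)
}

# maximal runs of TRUE within a logical vector -> onsets (1-based) & lengths
true_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  list(onset = (ends - r$lengths + 1L)[r$values],
       length = r$lengths[r$values])
}

#' Consolidation index of night sleep
#'
#' CI summarizes how consolidated sleep is: the sum of squared sleep-bout
#' lengths divided by the total amount of sleep,
#' \eqn{CI = \sum l_i^2 / \sum l_i} (minutes). A single uninterrupted night
#' bout gives CI equal to its own length; fragmentation drives CI toward the
#' mean bout length. CI is 0 when there is no sleep.
#'
#' @param bout_lengths Numeric vector of night sleep-bout lengths in minutes
#'   (clipped to the night window).
#' @return CI in minutes.
#' @examples
#' consolidation_index(c(10, 20, 30))  # 23.33
#' @export
consolidation_index <- function(bout_lengths) {
  if (length(bout_lengths) == 0L) return(0)
  if (any(bout_lengths < 0)) stop("negative bout length", call. = FALSE)
  tot <- sum(bout_lengths)
  if (tot == 0) return(0)
  sum(bout_lengths^2) / tot
}

#' Per-fly, per-day sleep metrics
#'
#' Computes, for each whole experimental day of each trace, the standard
#' sleep statistics: night sleep (ZT12-24) and day sleep (ZT0-12) in minutes,
#' night bout number and mean length, latency to sleep (minutes from
#' lights-off to the first night sleep episode; 0 if a bout is already ongoing
#' at ZT12; censored at 720 with a flag if the fly never sleeps at night),
#' WASO (awake minutes between first night sleep onset and ZT24; 0 and
#' flagged undefined when there is no night sleep), and the consolidation
#' index. Bouts straddling ZT12 or ZT24 are split at the boundary; minutes
#' count toward the phase they occur in, and the clipped night segment counts
#' as one night bout.
#'
#' @param traces A list of `activity_trace` objects (or a single one).
#' @param min_bout_min Sleep definition threshold in minutes (default 5).
#' @return A data.frame with one row per fly-day: `fly_id, genotype, day,
#'   night_sleep_min, day_sleep_min, n_bouts_night, mean_bout_len_night_min,
#'   latency_min, latency_censored, waso_min, waso_undefined, ci_min`.
#' @export
sleep_metrics <- function(traces, min_bout_min = 5L) {
  if (inherits(traces, "activity_trace")) traces <- list(traces)
  rows <- lapply(traces, function(tr) {
    asleep <- sleep_minutes(tr$counts, min_bout_min)
    do.call(rbind, lapply(seq_len(n_days(tr)), function(d) {
      day_idx <- (d - 1L) * 1440L + 1:720            # ZT0-12
      night_idx <- (d - 1L) * 1440L + 721:1440       # ZT12-24
      night <- asleep[night_idx]
      runs <- true_runs(night)
      night_sleep <- sum(night)
      first <- if (night_sleep > 0) which(night)[1L] else NA_integer_
      latency <- if (is.na(first)) 720L else first - 1L
      waso <- if (is.na(first)) 0L else 720L - latency - night_sleep
      data.frame(
        fly_id = tr$fly_id, genotype = tr$genotype, day = d,
        night_sleep_min = night_sleep,
        day_sleep_min = sum(asleep[day_idx]),
        n_bouts_night = length(runs$length),
        mean_bout_len_night_min =
          if (length(runs$length)) mean(runs$length) else 0,
        latency_min = latency,
        latency_censored = is.na(first),
        waso_min = waso,
        waso_undefined = is.na(first),
        ci_min = consolidation_index(runs$length),
        stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

#' Night/day sleep attribution for one day
#'
#' Attributes each sleep minute of one experimental day to the phase it falls
#' in: night is ZT \[12, 24), day is ZT \[0, 12).
#'
#' @param trace An `activity_trace`.
#' @param day 1-based experimental day.
#' @param min_bout_min Sleep definition threshold (default 5).
#' @return Named numeric: `night_sleep_min`, `day_sleep_min`.
#' @export
night_day_sleep <- function(trace, day = 1L, min_bout_min = 5L) {
  stopifnot(day >= 1L, day <= n_days(trace))
  asleep <- sleep_minutes(trace$counts, min_bout_min)
  off <- (day - 1L) * 1440L
  c(night_sleep_min = sum(asleep[off + 721:1440]),
    day_sleep_min = sum(asleep[off + 1:720]))
}

#' Latency to sleep and wake after sleep onset
#'
#' `sleep_latency()` is the time, in minutes, from lights-off (ZT12) to the
#' onset of the first night sleep episode; a bout already ongoing at ZT12
#' gives latency 0, and a night without sleep is censored at 720 min.
#' `sleep_waso()` counts awake minutes between the first night sleep onset
#' and ZT24 (0, flagged undefined, when there is no night sleep).
#'
#' @param trace An `activity_trace`.
#' @param day 1-based experimental day.
#' @param min_bout_min Sleep definition threshold (default 5).
#' @return `sleep_latency()`: list with `latency_min` and `censored`;
#'   `sleep_waso()`: list with `waso_min` and `undefined`.
#' @export
sleep_latency <- function(trace, day = 1L, min_bout_min = 5L) {
  m <- one_day_metrics(trace, day, min_bout_min)
  list(latency_min = m$latency_min, censored = m$latency_censored)
}

#' @rdname sleep_latency
#' @export
sleep_waso <- function(trace, day = 1L, min_bout_min = 5L) {
  m <- one_day_metrics(trace, day, min_bout_min)
  list(waso_min = m$waso_min, undefined = m$waso_undefined)
}

one_day_metrics <- function(trace, day, min_bout_min = 5L) {
  stopifnot(day >= 1L, day <= n_days(trace))
  m <- sleep_metrics(trace, min_bout_min)
  m[m$day == day, , drop = FALSE]
}

#' Per-fly averages over baseline days
#'
#' Averages the per-day metrics of [sleep_metrics()] within each fly, the
#' aggregation used for group comparisons. Latency censored nights and
#' undefined WASO nights are excluded from those two averages (their flags
#' are reported as counts).
#'
#' @param metrics Output of [sleep_metrics()].
#' @return One row per fly with averaged metrics and flag counts.
#' @export
average_metrics <- function(metrics) {
  sp <- split(metrics, metrics$fly_id)
  out <- do.call(rbind, lapply(sp, function(m) {
    lat <- m$latency_min[!m$latency_censored]
    was <- m$waso_min[!m$waso_undefined]
    data.frame(
      fly_id = m$fly_id[1L], genotype = m$genotype[1L],
      n_days = nrow(m),
      night_sleep_min = mean(m$night_sleep_min),
      day_sleep_min = mean(m$day_sleep_min),
      n_bouts_night = mean(m$n_bouts_night),
      mean_bout_len_night_min = mean(m$mean_bout_len_night_min),
      latency_min = if (length(lat)) mean(lat) else NA_real_,
      waso_min = if (length(was)) mean(was) else NA_real_,
      ci_min = mean(m$ci_min),
      n_nights_censored = sum(m$latency_censored),
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Population sleep profile
#'
#' The familiar sleep-profile plot: for each ZT bin, the fraction of time each
#' fly spends asleep (pooled over its recorded days), summarized across flies
#' as mean and SEM.
#'
#' @param traces List of `activity_trace` objects.
#' @param bin_minutes Profile bin width in minutes (default 30; 48 bins/day).
#' @param min_bout_min Sleep definition threshold (default 5).
#' @return A data.frame: `zt_bin_start_h, mean_frac, sem, n`.
#' @export
sleep_profile <- function(traces, bin_minutes = 30L, min_bout_min = 5L) {
  if (inherits(traces, "activity_trace")) traces <- list(traces)
  stopifnot(length(traces) >= 1L, 1440L %% bin_minutes == 0L)
  nbin <- 1440L %/% bin_minutes
  per_fly <- vapply(traces, function(tr) {
    asleep <- sleep_minutes(tr$counts, min_bout_min)
    bin <- ((seq_along(asleep) - 1L) %% 1440L) %/% bin_minutes
    as.numeric(tapply(asleep, factor(bin, levels = 0:(nbin - 1L)), mean))
  }, numeric(nbin))
  per_fly <- matrix(per_fly, nrow = nbin)
  n <- ncol(per_fly)
  sem <- if (n > 1L) apply(per_fly, 1L, stats::sd) / sqrt(n) else rep(0, nbin)
  data.frame(zt_bin_start_h = (0:(nbin - 1L)) * bin_minutes / 60,
             mean_frac = rowMeans(per_fly), sem = sem, n = n)
}
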