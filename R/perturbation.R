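#' Score sleep-deprivation rebound
#'
#' Mechanical sleep deprivation (SD) is applied either for the first half of
#' the night (`"sd6"`, ZT12-18) or the whole night (`"sd12"`, ZT12-24) of
#' `sd_day`. Rebound is quantified as delta sleep:
#' * `sd6`: sleep in ZT18-24 of the deprivation night (rebound) minus sleep
#'   in ZT18-24 of the baseline night.
#' * `sd12`: daytime sleep (ZT0-12) on the day following deprivation minus
#'   baseline daytime sleep.
#'
#' Sleep loss over the deprived window is `1 - sd_sleep/baseline_sleep`
#' (matched window of the baseline day). For `sd12` only flies with more than
#' 70% sleep loss throughout the night are included; flies with zero
#' baseline sleep in the deprived window are excluded with a flag.
#'
#' @param trace An `activity_trace` spanning both days.
#' @param protocol `"sd6"` or `"sd12"`.
#' @param baseline_day,sd_day 1-based experimental days.
#' @param min_loss_frac Inclusion threshold on sleep loss for `sd12`
#'   (default 0.70, strict inequality).
#' @param min_bout_min Sleep definition threshold (default 5).
#' @return A one-row data.frame: `fly_id, protocol, baseline_night_sleep_min,
#'   sd_night_sleep_min, sleep_loss_frac, delta_sleep_min, included,
#'   exclusion_reason`.
#' @export
delta_sleep <- function(trace, protocol = c("sd6", "sd12"),
                        baseline_day = 1L, sd_day = 2L,
                        min_loss_frac = 0.70, min_bout_min = 5L) {
  protocol <- match.arg(protocol)
  nd <- n_days(trace)
  need_day <- if (protocol == "sd12") sd_day + 1L else sd_day
  stopifnot(baseline_day >= 1L, sd_day >= 1L, need_day <= nd)
  asleep <- sleep_minutes(trace$counts, min_bout_min)
  win <- function(day, zt_from, zt_to)   # [zt_from, zt_to) of a given day
    sum(asleep[(day - 1L) * 1440L + (zt_from * 60 + 1):(zt_to * 60)])

  if (protocol == "sd6") {
    base_dep <- win(baseline_day, 12, 18)
    sd_dep <- win(sd_day, 12, 18)
    delta <- win(sd_day, 18, 24) - win(baseline_day, 18, 24)
  } else {
    base_dep <- win(baseline_day, 12, 24)
    sd_dep <- win(sd_day, 12, 24)
    delta <- win(sd_day + 1L, 0, 12) - win(baseline_day, 0, 12)
  }
  if (base_dep == 0) {
    loss <- NA_real_
    included <- FALSE
    reason <- "zero_baseline_sleep"
  } else {
    loss <- 1 - sd_dep / base_dep
    if (protocol == "sd12" && loss <= min_loss_frac) {
      included <- FALSE
      reason <- "sd_loss_filter"
    } else {
      included <- TRUE
      reason <- NA_character_
    }
  }
  data.frame(fly_id = trace$fly_id, protocol = protocol,
             baseline_night_sleep_min = base_dep,
             sd_night_sleep_min = sd_dep,
             sleep_loss_frac = loss, delta_sleep_min = delta,
             included = included, exclusion_reason = reason,
             stringsAsFactors = FALSE)
}

#' Classify the awakening response to a light pulse
#'
#' A 5-min light pulse is delivered during the night (typically ZT16, ZT18 or
#' ZT20). Flies with any activity in the 5 min preceding stimulus onset were
#' already awake and are excluded (`"awake_excluded"`); among flies inactive
#' before the pulse, those with activity in the 5 min following onset are
#' `"responding"`, the rest `"not_responding"`.
#'
#' @param trace An `activity_trace`.
#' @param stimulus_zt_h Stimulus onset in ZT hours (e.g. 16, 18, 20).
#' @param day 1-based experimental day of the stimulus night (default the
#'   last day of the trace).
#' @return One of `"responding"`, `"not_responding"`, `"awake_excluded"`.
#' @export
classify_awakening <- function(trace, stimulus_zt_h, day = n_days(trace)) {
  stopifnot(stimulus_zt_h >= 0, stimulus_zt_h < 24)
  onset <- (day - 1L) * 1440L + round(stimulus_zt_h * 60) + 1L  # 1-based bin
  if (onset - 5L < 1L || onset + 4L > length(trace$counts))
    stop("stimulus window exceeds trace", call. = FALSE)
  before <- trace$counts[(onset - 5L):(onset - 1L)]
  after <- trace$counts[onset:(onset + 4L)]
  if (any(before > 0)) "awake_excluded"
  else if (any(after > 0)) "responding"
  else "not_responding"
}

#' Sleep loss after a light-pulse arousal
#'
#' Quantifies how much night sleep is lost after a nocturnal light stimulus:
#' `sleep_loss_pct = 100 * (1 - sleep_after / sleep_baseline)`, where
#' `sleep_after` is sleep in the post-stimulus window \[stimulus ZT, ZT24) of
#' the stimulus night and `sleep_baseline` is the matched ZT window of the
#' preceding undisturbed night. Flies with at least 2% sleep loss are
#' included; zero baseline sleep makes the ratio undefined and excludes the
#' fly with a flag.
#'
#' @param trace An `activity_trace` covering both nights.
#' @param stimulus_zt_h Stimulus onset, ZT hours in \[12, 24).
#' @param stimulus_day 1-based day of the stimulus night (default last day).
#' @param baseline_day Matched undisturbed night (default the preceding day).
#' @param window_end_zt_h End of the accounting window (default 24).
#' @param min_loss_pct Inclusion threshold in percent (default 2).
#' @param min_bout_min Sleep definition threshold (default 5).
#' @return One-row data.frame: `fly_id, stimulus_zt_h, sleep_after_min,
#'   sleep_baseline_min, sleep_loss_pct, included, exclusion_reason`.
#' @export
arousal_sleep_loss <- function(trace, stimulus_zt_h,
                               stimulus_day = n_days(trace),
                               baseline_day = stimulus_day - 1L,
                               window_end_zt_h = 24,
                               min_loss_pct = 2, min_bout_min = 5L) {
  stopifnot(stimulus_zt_h >= 12, stimulus_zt_h < window_end_zt_h,
            window_end_zt_h <= 24, baseline_day >= 1L,
            stimulus_day <= n_days(trace))
  asleep <- sleep_minutes(trace$counts, min_bout_min)
  idx <- function(day)
    (day - 1L) * 1440L + (round(stimulus_zt_h * 60) + 1L):round(window_end_zt_h * 60)
  after <- sum(asleep[idx(stimulus_day)])
  base <- sum(asleep[idx(baseline_day)])
  if (base == 0) {
    loss <- NA_real_; included <- FALSE; reason <- "zero_baseline_sleep"
  } else {
    loss <- 100 * (1 - after / base)
    included <- loss >= min_loss_pct
    reason <- if (included) NA_character_ else "arousal_loss_filter"
  }
  data.frame(fly_id = trace$fly_id, stimulus_zt_h = stimulus_zt_h,
             sleep_after_min = after, sleep_baseline_min = base,
             sleep_loss_pct = loss, included = included,
             exclusion_reason = reason, stringsAsFactors = FALSE)
}
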