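#' Simulation configuration
#'
#' Defines the data-generating process for synthetic DAM experiments: each
#' fly is a minute-by-minute two-state (wake/sleep) Markov chain whose
#' transition probabilities depend on circadian phase. Awake minutes emit
#' zero-truncated Poisson counts with mean `activity_rate`; sleep minutes
#' emit 0 (plain Poisson emissions would let a fully awake fly produce
#' spurious 5-min zero runs, so the truncated form keeps the behavioral
#' sleep definition faithful to the hidden state). Bout lengths are
#' geometric, so the implied mean sleep-bout length in a phase is
#' `1/p_wake(phase)` minutes and the mean latency-like waking run is
#' `1/p_sleep(phase)`.
#'
#' On LD days phase is Zeitgeber time (night = ZT 12-24); on DD days phase
#' follows the configured internal `period_h`, so free-running period
#' recovery by the periodogram is testable.
#'
#' @param genotypes Named list; each element a list with `p_sleep` and
#'   `p_wake`, each a named numeric `c(day = , night = )` of per-minute
#'   transition probabilities. Defaults define a normal sleeper (`control`:
#'   consolidated ~600-min nights, ~60-min night bouts) and a short-sleeping,
#'   fragmented genotype (`short_sleeper`: ~20-min night bouts, doubled
#'   latency).
#' @param n_flies Flies per genotype (default 32, one monitor).
#' @param n_days Experimental days (default 3 baseline days).
#' @param period_h Internal free-running period in hours (default 24).
#' @param regime Per-day `"LD"`/`"DD"` labels (default all LD).
#' @param activity_rate Mean counts per awake minute (default 2).
#' @param light_pulse_wake_prob Probability a sleeping fly awakens at a light
#'   pulse (default 0.9).
#' @param deprivation_efficacy Probability an intended sleep minute is
#'   converted to wake during mechanical deprivation (default 1).
#' @param dead_fly_frac Fraction of flies that die partway through
#'   (default 0).
#' @param lights_on Clock time of ZT0 (default "08:00").
#' @param seed Master seed; fixes the full output stream.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genotypes = default_genotypes(),
                       n_flies = 32L, n_days = 3L, period_h = 24,
                       regime = rep("LD", n_days),
                       activity_rate = 2,
                       light_pulse_wake_prob = 0.9,
                       deprivation_efficacy = 1,
                       dead_fly_frac = 0,
                       lights_on = "08:00",
                       seed = 1L) {
  stopifnot(length(regime) == n_days, activity_rate > 0,
            dead_fly_frac >= 0, dead_fly_frac <= 1,
            light_pulse_wake_prob >= 0, light_pulse_wake_prob <= 1,
            deprivation_efficacy >= 0, deprivation_efficacy <= 1)
  for (g in genotypes) {
    stopifnot(all(c("day", "night") %in% names(g$p_sleep)),
              all(c("day", "night") %in% names(g$p_wake)),
              all(unlist(g[c("p_sleep", "p_wake")]) >= 0),
              all(unlist(g[c("p_sleep", "p_wake")]) <= 1))
  }
  structure(list(genotypes = genotypes, n_flies = as.integer(n_flies),
                 n_days = as.integer(n_days), period_h = period_h,
                 regime = toupper(regime), activity_rate = activity_rate,
                 light_pulse_wake_prob = light_pulse_wake_prob,
                 deprivation_efficacy = deprivation_efficacy,
                 dead_fly_frac = dead_fly_frac,
                 lights_on = lights_on, seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_genotypes <- function() {
  list(
    control = list(
      p_sleep = c(day = 0.05, night = 0.10),
      p_wake = c(day = 1 / 15, night = 1 / 60)),
    short_sleeper = list(
      p_sleep = c(day = 0.05, night = 0.05),
      p_wake = c(day = 1 / 15, night = 0.05)))
}

# zero-truncated Poisson with mean `rate` (>= 1 guaranteed)
rcounts <- function(n, rate) 1L + stats::rpois(n, max(rate - 1, 0))

#' Simulate one fly
#'
#' @param config A [sim_config()].
#' @param genotype Name of a genotype in the config.
#' @param fly_seed Integer seed for this fly's chain.
#' @param fly_id,channel,monitor_id Identity plumbing for the trace.
#' @return An `activity_trace`.
#' @export
simulate_fly <- function(config, genotype, fly_seed,
                         fly_id = paste0(genotype, "_", fly_seed),
                         channel = 1L, monitor_id = "SIM1") {
  stopifnot(inherits(config, "sim_config"),
            genotype %in% names(config$genotypes))
  g <- config$genotypes[[genotype]]
  n <- config$n_days * 1440L
  minute <- 0:(n - 1L)
  day_of <- minute %/% 1440L + 1L
  is_dd <- config$regime[day_of] == "DD"
  # circadian phase fraction: ZT/24 on LD days, internal clock in DD
  frac <- ifelse(is_dd,
                 (minute / 60) %% config$period_h / config$period_h,
                 (minute %% 1440L) / 1440)
  night <- frac >= 0.5
  ps <- ifelse(night, g$p_sleep[["night"]], g$p_sleep[["day"]])
  pw <- ifelse(night, g$p_wake[["night"]], g$p_wake[["day"]])

  set.seed(fly_seed)
  u <- stats::runif(n)
  state <- logical(n)  # TRUE = asleep
  s <- u[1L] < ps[1L] / (ps[1L] + pw[1L])  # stationary start at day phase
  state[1L] <- s
  for (i in 2:n) {
    s <- if (s) u[i] >= pw[i] else u[i] < ps[i]
    state[i] <- s
  }
  counts <- integer(n)
  counts[!state] <- rcounts(sum(!state), config$activity_rate)

  schedule <- light_schedule(config$lights_on, 12, config$regime)
  light <- unlist(lapply(seq_len(config$n_days),
                         function(d) day_light_flags(schedule, d)),
                  use.names = FALSE)
  t0 <- as.POSIXct(paste("2024-01-01", config$lights_on), tz = "UTC")
  new_activity_trace(fly_id = fly_id, genotype = genotype, channel = channel,
                     monitor_id = monitor_id, t0 = t0, counts = counts,
                     light = light, schedule = schedule)
}

#' Simulate a whole experiment
#'
#' Generates `n_flies` per genotype with per-fly seeds derived
#' deterministically from the master seed; a `dead_fly_frac` subset of flies
#' stops moving partway through the recording (all-zero counts to the end),
#' emulating deaths in the tubes.
#'
#' @param config A [sim_config()].
#' @return A list with `traces` (list of `activity_trace`), `channel_map`
#'   (data.frame), and `truth` (per-fly true parameters, as a data.frame).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  total <- config$n_flies * length(config$genotypes)
  fly_seeds <- sample.int(2147483646L, total)
  dead <- stats::runif(total) < config$dead_fly_frac
  death_frac <- stats::runif(total, 1 / 3, 2 / 3)

  traces <- vector("list", total)
  map <- truth <- vector("list", total)
  i <- 0L
  for (gt in names(config$genotypes)) {
    for (f in seq_len(config$n_flies)) {
      i <- i + 1L
      monitor <- sprintf("SIM%d", (i - 1L) %/% 32L + 1L)
      channel <- (i - 1L) %% 32L + 1L
      fly_id <- sprintf("%s_%02d", gt, f)
      tr <- simulate_fly(config, gt, fly_seeds[i], fly_id = fly_id,
                         channel = channel, monitor_id = monitor)
      if (dead[i]) {
        from <- floor(death_frac[i] * length(tr$counts)) + 1L
        tr$counts[from:length(tr$counts)] <- 0L
      }
      traces[[i]] <- tr
      g <- config$genotypes[[gt]]
      map[[i]] <- data.frame(monitor_id = monitor, channel = channel,
                             fly_id = fly_id, genotype = gt, include = TRUE,
                             stringsAsFactors = FALSE)
      truth[[i]] <- data.frame(
        fly_id = fly_id, genotype = gt, fly_seed = fly_seeds[i],
        dead = dead[i],
        p_sleep_day = g$p_sleep[["day"]], p_sleep_night = g$p_sleep[["night"]],
        p_wake_day = g$p_wake[["day"]], p_wake_night = g$p_wake[["night"]],
        mean_night_bout_min = 1 / g$p_wake[["night"]],
        stringsAsFactors = FALSE)
    }
  }
  list(traces = traces, channel_map = do.call(rbind, map),
       truth = do.call(rbind, truth))
}

#' Apply mechanical sleep deprivation to a trace
#'
#' Emulates the vortexer protocol (brief shaking every minute): within the
#' deprivation window, each minute that would be a sleep (zero-count) minute
#' is converted to an awake minute (count >= 1) with probability `efficacy`.
#'
#' @param trace An `activity_trace`.
#' @param day 1-based day of the deprivation night.
#' @param zt_from,zt_to ZT window deprived (default whole night, 12-24).
#' @param efficacy Per-minute wake-enforcement probability in \[0, 1\].
#' @param activity_rate Mean counts of an enforced awake minute (default 2).
#' @param seed Optional seed for reproducibility of the enforcement draws.
#' @return The modified trace.
#' @export
apply_deprivation <- function(trace, day, zt_from = 12, zt_to = 24,
                              efficacy = 1, activity_rate = 2, seed = NULL) {
  stopifnot(efficacy >= 0, efficacy <= 1, zt_from < zt_to)
  if (!is.null(seed)) set.seed(seed)
  idx <- (day - 1L) * 1440L + (round(zt_from * 60) + 1L):round(zt_to * 60)
  stopifnot(max(idx) <= length(trace$counts))
  zero <- idx[trace$counts[idx] == 0L]
  woken <- zero[stats::runif(length(zero)) < efficacy]
  trace$counts[woken] <- rcounts(length(woken), activity_rate)
  trace
}

#' Apply a 5-min light pulse to a trace
#'
#' Flies already active in the 5 min before the pulse are left unchanged
#' (they will be classified awake and excluded downstream). A sleeping fly
#' awakens at pulse onset with probability `wake_prob` and then stays awake
#' for `refractory_min` minutes.
#'
#' @param trace An `activity_trace`.
#' @param day 1-based day of the stimulus night.
#' @param zt_h Pulse onset, ZT hours.
#' @param wake_prob Awakening probability for a sleeping fly.
#' @param refractory_min Minutes of enforced wake after awakening
#'   (default 15).
#' @param activity_rate Mean counts per enforced awake minute (default 2).
#' @param seed Optional seed.
#' @return The modified trace.
#' @export
apply_light_pulse <- function(trace, day, zt_h, wake_prob = 0.9,
                              refractory_min = 15L, activity_rate = 2,
                              seed = NULL) {
  stopifnot(wake_prob >= 0, wake_prob <= 1)
  if (!is.null(seed)) set.seed(seed)
  onset <- (day - 1L) * 1440L + round(zt_h * 60) + 1L
  stopifnot(onset - 5L >= 1L, onset + refractory_min - 1L <= length(trace$counts))
  if (any(trace$counts[(onset - 5L):(onset - 1L)] > 0L)) return(trace)
  if (stats::runif(1L) < wake_prob) {
    idx <- onset:(onset + refractory_min - 1L)
    trace$counts[idx] <- rcounts(length(idx), activity_rate)
  }
  trace
}

#' Write traces to a DAM monitor file
#'
#' Emits the 42-column tab-delimited monitor format read by
#' [read_dam_file()]: reading index, date, time, status code 0 (valid), six
#' device fields (zeros), then 32 channel counts. All traces must share one
#' monitor and fit in 32 channels; unoccupied channels are written as 0.
#' Round-trips bit-exactly through [read_dam_file()]/[assemble_traces()].
#'
#' @param traces List of `activity_trace` objects with distinct channels on
#'   one monitor.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dam <- function(traces, path) {
  if (inherits(traces, "activity_trace")) traces <- list(traces)
  chans <- vapply(traces, `[[`, integer(1L), "channel")
  if (length(traces) > 32L || anyDuplicated(chans))
    stop("a DAM monitor holds at most 32 distinct channels; ",
         "split across monitor files", call. = FALSE)
  lens <- vapply(traces, function(tr) length(tr$counts), integer(1L))
  stopifnot(length(unique(lens)) == 1L)
  n <- lens[1L]
  t0 <- traces[[1L]]$t0
  tt <- t0 + (seq_len(n) - 1L) * 60
  cnt <- matrix(0L, nrow = n, ncol = 32L)
  for (tr in traces) cnt[, tr$channel] <- tr$counts
  lt <- as.POSIXlt(tt, tz = "UTC")
  rows <- paste(
    seq_len(n),
    format(tt, "%d %b %y", tz = "UTC"),
    format(tt, "%H:%M:%S", tz = "UTC"),
    0L,  # status: valid
    1L, 0L, 0L, 0L, 0L, 0L,  # device fields
    apply(cnt, 1L, paste, collapse = "\t"),
    sep = "\t")
  writeLines(rows, path)
  invisible(path)
}

#' Write a channel map CSV
#'
#' @param map Channel map data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_channel_map <- function(map, path) {
  utils::write.csv(map, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
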