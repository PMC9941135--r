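#' Read a Trikinetics DAM monitor file
#'
#' DAM monitor files are tab-delimited text with one row per reading:
#' reading index, date (`DD Mon YY`), time (`HH:MM:SS`), a status code, six
#' device fields, then 32 integer beam-break counts (columns 11-42), one per
#' channel. A status code of 0 marks a valid reading; rows with a nonzero
#' status are kept on the timeline but their counts are treated as missing for
#' all 32 channels. Readings at a cadence finer than `bin_minutes` are summed
#' into bins.
#'
#' @param path Path to the monitor file.
#' @param bin_minutes Width of the output bins in minutes (default 1, the
#'   cadence used for sleep scoring).
#' @param monitor_id Identifier for the monitor; defaults to the file name
#'   without extension.
#' @return A list of class `dam_raw` with elements `monitor_id`, `time`
#'   (POSIXct, one per bin), `valid` (logical per bin; FALSE when any reading
#'   in the bin had nonzero status), and `counts` (integer matrix, bins x 32;
#'   NA where invalid).
#' @export
read_dam_file <- function(path, bin_minutes = 1L, monitor_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(monitor_id))
    monitor_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty DAM file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 42L)
  if (length(bad))
    stop(sprintf("malformed DAM row: line %d has %d columns, expected 42",
                 bad[1L], nf[bad[1L]]), call. = FALSE)
  m <- matrix(unlist(fields), ncol = 42L, byrow = TRUE)
  tt <- as.POSIXct(paste(m[, 2L], m[, 3L]), format = "%d %b %y %H:%M:%S",
                   tz = "UTC")
  if (anyNA(tt)) {
    bad <- which(is.na(tt))[1L]
    stop(sprintf("malformed DAM row: unparsable date/time at line %d", bad),
         call. = FALSE)
  }
  if (is.unsorted(as.numeric(tt), strictly = TRUE))
    stop("non-monotone timestamps in DAM file: ", path, call. = FALSE)
  status <- suppressWarnings(as.integer(m[, 4L]))
  counts <- suppressWarnings(matrix(as.integer(m[, 11:42]), ncol = 32L))
  if (anyNA(counts[status == 0L, , drop = FALSE]))
    stop("malformed DAM row: non-integer channel count", call. = FALSE)
  valid <- status == 0L
  counts[!valid, ] <- NA_integer_

  # collapse sub-minute cadence into bins of bin_minutes
  bin_sec <- bin_minutes * 60
  bin_id <- floor(as.numeric(tt - tt[1L], units = "secs") / bin_sec)
  if (anyDuplicated(bin_id)) {
    grp <- factor(bin_id, levels = unique(bin_id))
    counts <- apply(counts, 2L, function(x) as.integer(tapply(x, grp, sum)))
    valid <- as.logical(tapply(valid, grp, all))
    tt <- tt[!duplicated(bin_id)]
    counts[!valid, ] <- NA_integer_
  }
  structure(list(monitor_id = monitor_id, time = tt, valid = valid,
                 counts = counts),
            class = "dam_raw")
}

#' Read a channel map
#'
#' The channel map links monitor channels to flies: a CSV with header
#' `monitor_id,channel,fly_id,genotype,include`.
#'
#' @param path CSV path.
#' @return A data.frame with those columns; `include` coerced to logical.
#' @export
read_channel_map <- function(path) {
  cm <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("monitor_id", "channel", "fly_id", "genotype", "include")
  if (!all(need %in% names(cm)))
    stop("channel map must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  cm$channel <- as.integer(cm$channel)
  cm$include <- as.logical(cm$include)
  if (anyDuplicated(cm[, c("monitor_id", "channel")]))
    stop("duplicate (monitor_id, channel) pairs in channel map", call. = FALSE)
  cm
}

#' Assemble Zeitgeber-aligned activity traces
#'
#' Crops each mapped channel to whole experimental days starting at a ZT0
#' boundary and attaches per-minute light flags derived from the schedule (the
#' configured photoperiod, not the device light sensor). Invalid or absent
#' minutes are imputed as 0 counts and recorded in a per-fly missingness
#' fraction; downstream filtering excludes flies with more than
#' `max_missing_frac` missing minutes.
#'
#' @param raw A `dam_raw` object from [read_dam_file()], or a list of them.
#' @param map Channel map data.frame (see [read_channel_map()]).
#' @param schedule A [light_schedule()].
#' @param days Optional integer vector of experimental days to keep (1-based,
#'   counted from the first ZT0 boundary in the recording); default all whole
#'   days.
#' @return A list of `activity_trace` objects, one per included channel.
#' @export
assemble_traces <- function(raw, map, schedule, days = NULL) {
  stopifnot(inherits(schedule, "light_schedule"))
  if (inherits(raw, "dam_raw")) raw <- list(raw)
  names(raw) <- vapply(raw, `[[`, "", "monitor_id")
  missing_mon <- setdiff(unique(map$monitor_id), names(raw))
  if (length(missing_mon))
    stop("channel map references monitors not supplied: ",
         paste(missing_mon, collapse = ", "), call. = FALSE)
  out <- list()
  for (mon in unique(map$monitor_id)) {
    r <- raw[[mon]]
    sub <- map[map$monitor_id == mon & map$include, , drop = FALSE]
    if (nrow(sub) == 0L) next
    bad <- sub$channel[sub$channel < 1L | sub$channel > 32L]
    if (length(bad))
      stop("channels out of range 1-32: ", paste(bad, collapse = ", "),
           call. = FALSE)

    # align to the first ZT0 minute
    zt0 <- which(zt_hours(r$time, schedule) == 0)[1L]
    if (is.na(zt0))
      stop("recording never crosses a ZT0 boundary; cannot align", call. = FALSE)
    # lay readings onto a contiguous minute grid from that point
    mins <- round(as.numeric(r$time - r$time[zt0], units = "mins"))
    keep <- mins >= 0
    n_days <- (max(mins[keep]) + 1L) %/% 1440L
    if (n_days < 1L)
      stop("less than one whole day after the first ZT0 boundary", call. = FALSE)
    if (is.null(days)) days_use <- seq_len(n_days)
    else {
      days_use <- as.integer(days)
      if (any(days_use < 1L | days_use > n_days))
        stop(sprintf("requested days outside recorded range 1-%d", n_days),
             call. = FALSE)
    }
    sel_min <- as.integer(outer(0:1439, (days_use - 1L) * 1440L, `+`))
    light <- unlist(lapply(days_use, function(d) day_light_flags(schedule, d)),
                    use.names = FALSE)
    idx <- match(sel_min, mins)  # NA where the minute is absent from the file
    present <- !is.na(idx)
    valid <- present
    valid[present] <- r$valid[idx[present]]

    for (j in seq_len(nrow(sub))) {
      ch <- sub$channel[j]
      cnt <- rep(NA_integer_, length(sel_min))
      cnt[present] <- r$counts[idx[present], ch]
      miss <- !valid | is.na(cnt)
      cnt[miss] <- 0L
      out[[length(out) + 1L]] <- new_activity_trace(
        fly_id = sub$fly_id[j], genotype = sub$genotype[j], channel = ch,
        monitor_id = mon, t0 = r$time[zt0] + (days_use[1L] - 1L) * 86400,
        counts = cnt, light = light, schedule = schedule,
        missing = miss)
    }
  }
  out
}

new_activity_trace <- function(fly_id, genotype, channel, monitor_id, t0,
                               counts, light, schedule,
                               missing = rep(FALSE, length(counts))) {
  stopifnot(length(counts) == length(light),
            length(counts) %% 1440L == 0L,
            all(counts >= 0L))
  structure(
    list(fly_id = fly_id, genotype = genotype, channel = as.integer(channel),
         monitor_id = monitor_id, t0 = t0,
         counts = as.integer(counts), light = light,
         schedule = schedule, missing = missing),
    class = "activity_trace")
}

#' @export
print.activity_trace <- function(x, ...) {
  cat(sprintf(
    "<activity_trace> %s (%s) monitor %s ch %d: %d min (%g days), %d counts, %.2f%% missing\n",
    x$fly_id, x$genotype, x$monitor_id, x$channel, length(x$counts),
    length(x$counts) / 1440, sum(x$counts), 100 * mean(x$missing)))
  invisible(x)
}

n_days <- function(trace) length(trace$counts) %/% 1440L

# ZT in hours of each minute bin (trace starts at ZT0 by construction)
trace_zt <- function(trace) (((seq_along(trace$counts) - 1L) %% 1440L) / 60)

missing_fraction <- function(trace) mean(trace$missing)

#' Survival filter
#'
#' A fly that stops registering beam breaks and never resumes has died in the
#' tube; only flies surviving through the entire experiment are analyzed.
#' A trace fails the filter when its terminal run of zero-count minutes is at
#' least `min_dead_hours` long (boundary inclusive).
#'
#' @param trace An `activity_trace`.
#' @param min_dead_hours Terminal all-zero span, in hours, that declares the
#'   fly dead (default 24).
#' @return `TRUE` if the fly is considered alive through the experiment.
#' @export
survival_filter <- function(trace, min_dead_hours = 24) {
  stopifnot(inherits(trace, "activity_trace"), length(trace$counts) > 0L)
  r <- rle(trace$counts == 0L)
  tail_zeros <- if (r$values[length(r$values)]) r$lengths[length(r$lengths)] else 0L
  tail_zeros < min_dead_hours * 60
}

#' Long-format trace table
#'
#' @param traces A list of `activity_trace` objects (or a single one).
#' @return A data.frame with columns `fly_id, genotype, minute_index,
#'   zt_hours, light, count` (minute_index is 0-based).
#' @export
trace_table <- function(traces) {
  if (inherits(traces, "activity_trace")) traces <- list(traces)
  do.call(rbind, lapply(traces, function(tr) {
    data.frame(fly_id = tr$fly_id, genotype = tr$genotype,
               minute_index = seq_along(tr$counts) - 1L,
               zt_hours = trace_zt(tr), light = tr$light, count = tr$counts,
               stringsAsFactors = FALSE)
  }))
}
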