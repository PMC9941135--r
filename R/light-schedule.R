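#' Define the light schedule of an experiment
#'
#' A light schedule anchors the Zeitgeber timeline: ZT0 is lights-on, and in a
#' 12:12 light:dark (LD) cycle lights go off at ZT12. Free-running days are
#' recorded in constant darkness (DD); the schedule carries one regime label
#' per experimental day so entrained and free-running days can be mixed in one
#' recording.
#'
#' @param lights_on Clock time of lights-on (ZT0), as `"HH:MM"`.
#' @param photoperiod_h Hours of light per 24 h on an LD day (12 for a 12:12
#'   cycle). Ignored on DD days.
#' @param regime Character vector of per-day regime labels, each `"LD"` or
#'   `"DD"`.
#' @return An object of class `light_schedule`.
#' @examples
#' light_schedule("08:00", 12, rep("LD", 3))
#' @export
light_schedule <- function(lights_on = "08:00", photoperiod_h = 12,
                           regime = rep("LD", 3L)) {
  if (!grepl("^[0-2]?[0-9]:[0-5][0-9]$", lights_on))
    stop("`lights_on` must be a clock time \"HH:MM\"", call. = FALSE)
  if (!is.numeric(photoperiod_h) || photoperiod_h < 0 || photoperiod_h > 24)
    stop("`photoperiod_h` must be in [0, 24]", call. = FALSE)
  regime <- toupper(as.character(regime))
  if (!all(regime %in% c("LD", "DD")))
    stop("`regime` labels must be \"LD\" or \"DD\"", call. = FALSE)
  hm <- as.integer(strsplit(lights_on, ":", fixed = TRUE)[[1L]])
  structure(
    list(lights_on = sprintf("%02d:%02d", hm[1L], hm[2L]),
         lights_on_min = hm[1L] * 60L + hm[2L],
         photoperiod_h = photoperiod_h,
         regime = regime),
    class = "light_schedule")
}

#' @export
print.light_schedule <- function(x, ...) {
  cat(sprintf("<light_schedule> lights on %s, photoperiod %g h, %d day(s): %s\n",
              x$lights_on, x$photoperiod_h, length(x$regime),
              paste(x$regime, collapse = " ")))
  invisible(x)
}

#' Zeitgeber time of clock timestamps
#'
#' ZT in hours is the elapsed time since the last lights-on, i.e.
#' `(clock - lights_on) mod 24 h`; ZT0 maps to lights-on.
#'
#' @param time A `POSIXct` vector, or minutes-past-midnight numeric.
#' @param schedule A [light_schedule()].
#' @return Numeric ZT in hours, in `[0, 24)`.
#' @export
zt_hours <- function(time, schedule) {
  stopifnot(inherits(schedule, "light_schedule"))
  if (inherits(time, "POSIXct")) {
    lt <- as.POSIXlt(time)
    mins <- lt$hour * 60 + lt$min + lt$sec / 60
  } else {
    mins <- as.numeric(time)
  }
  ((mins - schedule$lights_on_min) %% 1440) / 60
}

# Per-minute light flags for one experimental day (1440 values starting at ZT0).
day_light_flags <- function(schedule, day) {
  reg <- schedule$regime[[min(day, length(schedule$regime))]]
  if (reg == "DD") return(rep(FALSE, 1440L))
  zt_min <- seq_len(1440L) - 1L
  zt_min < schedule$photoperiod_h * 60
}
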