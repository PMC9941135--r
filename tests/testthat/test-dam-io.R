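# write small DAM fixture files in code and read them back

write_dam_lines <- function(path, rows) writeLines(rows, path)

dam_row <- function(idx, date, time, status, counts) {
  paste(c(idx, date, time, status, 1, 0, 0, 0, 0, 0, counts), collapse = "\t")
}

test_that("a valid DAM file reads back channel counts verbatim", {
  f <- withr::local_tempfile(fileext = ".txt")
  counts <- list(c(0, rep(0, 31)), c(2, rep(0, 31)), c(0, rep(0, 31)))
  rows <- vapply(1:3, function(i)
    dam_row(i, "01 Jan 24", sprintf("08:%02d:00", i - 1), 0, counts[[i]]),
    character(1))
  write_dam_lines(f, rows)
  raw <- read_dam_file(f)
  expect_equal(raw$counts[, 1], c(0L, 2L, 0L))
  expect_true(all(raw$valid))
})

test_that("nonzero status marks the minute missing for all 32 channels", {
  f <- withr::local_tempfile(fileext = ".txt")
  rows <- vapply(1:3, function(i)
    dam_row(i, "01 Jan 24", sprintf("08:%02d:00", i - 1),
            if (i == 2) 51 else 0, rep(i, 32)),
    character(1))
  write_dam_lines(f, rows)
  raw <- read_dam_file(f)
  expect_equal(raw$valid, c(TRUE, FALSE, TRUE))
  expect_true(all(is.na(raw$counts[2, ])))
  expect_true(all(raw$counts[c(1, 3), ] == c(1L, 3L)))
})

test_that("sub-minute cadence is summed into 1-min bins", {
  f <- withr::local_tempfile(fileext = ".txt")
  # 30-s cadence: pairs of readings should sum per minute
  times <- c("08:00:00", "08:00:30", "08:01:00", "08:01:30")
  vals <- c(1, 2, 3, 4)
  rows <- vapply(1:4, function(i)
    dam_row(i, "01 Jan 24", times[i], 0, rep(vals[i], 32)),
    character(1))
  write_dam_lines(f, rows)
  raw <- read_dam_file(f, bin_minutes = 1)
  expect_equal(raw$counts[, 1], c(3L, 7L))
  expect_equal(sum(raw$counts[, 1]), sum(vals))  # counts conserved
})

test_that("malformed rows and non-monotone timestamps raise parse errors", {
  f <- withr::local_tempfile(fileext = ".txt")
  write_dam_lines(f, c(dam_row(1, "01 Jan 24", "08:00:00", 0, rep(0, 32)),
                       "too\tfew\tcolumns"))
  expect_error(read_dam_file(f), "line 2")

  write_dam_lines(f, dam_row(1, "banana", "08:00:00", 0, rep(0, 32)))
  expect_error(read_dam_file(f), "date/time")

  write_dam_lines(f, c(dam_row(1, "01 Jan 24", "08:05:00", 0, rep(0, 32)),
                       dam_row(2, "01 Jan 24", "08:00:00", 0, rep(0, 32))))
  expect_error(read_dam_file(f), "monotone")
})

test_that("assemble_traces crops to whole ZT-aligned days with schedule-derived light", {
  cfg <- sim_config(n_flies = 2, n_days = 3, seed = 11,
                    genotypes = default_genotypes()["control"])
  sim <- simulate_experiment(cfg)
  f <- withr::local_tempfile(fileext = ".txt")
  write_dam(sim$traces, f)
  raw <- read_dam_file(f, monitor_id = "SIM1")
  sch <- sim$traces[[1]]$schedule

  tr <- assemble_traces(raw, sim$channel_map, sch, days = 2:3)
  expect_length(tr, 2)
  expect_length(tr[[1]]$counts, 2880)
  expect_equal(tr[[1]]$counts,
               sim$traces[[1]]$counts[1441:4320])
  # LD light flags: on for ZT < 12
  expect_true(all(tr[[1]]$light[1:720]))
  expect_false(any(tr[[1]]$light[721:1440]))

  # excluded channel yields no trace
  cm <- sim$channel_map
  cm$include[cm$channel == 2] <- FALSE
  tr <- assemble_traces(raw, cm, sch)
  expect_length(tr, 1)
  expect_equal(tr[[1]]$channel, 1L)

  # mapped channel from an absent monitor errors
  cm2 <- sim$channel_map
  cm2$monitor_id[2] <- "NOPE"
  expect_error(assemble_traces(raw, cm2, sch), "NOPE")
})

test_that("DD days get all-false light flags", {
  sch <- light_schedule("08:00", 12, c("LD", "DD"))
  cfg <- sim_config(n_flies = 1, n_days = 2, regime = c("LD", "DD"), seed = 3)
  tr <- simulate_fly(cfg, "control", 5)
  expect_true(any(tr$light[1:720]))
  expect_false(any(tr$light[1441:2880]))
})

test_that("survival filter flags terminal zero runs, boundary inclusive", {
  expect_false(survival_filter(make_trace(rep(0, 1440)), min_dead_hours = 24))
  alive <- day_counts()
  expect_true(survival_filter(make_trace(alive), min_dead_hours = 24))
  # exactly 24 h of terminal zeros is dead (inclusive boundary)
  x <- c(rep(1L, 1440), rep(0L, 1440))
  expect_false(survival_filter(make_trace(x), min_dead_hours = 24))
  x2 <- c(rep(1L, 1441), rep(0L, 1439))
  expect_true(survival_filter(make_trace(c(x2, rep(1, 0))), min_dead_hours = 24))
})

test_that("survival filter agrees with a brute-force terminal-zero scan", {
  set.seed(99)
  for (i in 1:50) {
    x <- rbinom(2880, 1, 0.3) * rpois(2880, 2)
    if (runif(1) < 0.5) x[(2880 - sample(0:2000, 1)):2880] <- 0
    tr <- make_trace(x)
    expect_equal(survival_filter(tr, min_dead_hours = 12),
                 oracle_terminal_zeros(x) < 12 * 60)
  }
})

test_that("missingness is imputed as zero and fraction recorded", {
  f <- withr::local_tempfile(fileext = ".txt")
  n <- 1440
  t0 <- as.POSIXct("2024-01-01 08:00:00", tz = "UTC")
  rows <- vapply(seq_len(n), function(i)
    dam_row(i, format(t0 + (i - 1) * 60, "%d %b %y", tz = "UTC"),
            format(t0 + (i - 1) * 60, "%H:%M:%S", tz = "UTC"),
            if (i %in% 100:120) 51 else 0, rep(1, 32)),
    character(1))
  write_dam_lines(f, rows)
  raw <- read_dam_file(f, monitor_id = "M1")
  map <- data.frame(monitor_id = "M1", channel = 1, fly_id = "f1",
                    genotype = "g", include = TRUE)
  tr <- assemble_traces(raw, map, light_schedule("08:00", 12, "LD"))[[1]]
  expect_equal(sum(tr$missing), 21)
  expect_equal(tr$counts[100:120], rep(0L, 21))
  expect_equal(damsleep:::missing_fraction(tr), 21 / 1440)
})
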