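test_that("bout detection matches the definitional examples", {
  expect_equal(nrow(detect_sleep_bouts(c(1, 0, 0, 0, 0, 1))), 0)
  b <- detect_sleep_bouts(rep(0, 720))
  expect_equal(b$onset_min, 0)
  expect_equal(b$duration_min, 720)
  b <- detect_sleep_bouts(c(0, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0))
  expect_equal(b$onset_min, c(0, 6))
  expect_equal(b$duration_min, c(5, 6))
})

test_that("bout detection agrees with a brute-force zero-run enumerator", {
  set.seed(42)
  for (i in 1:200) {
    x <- rbinom(1440, 1, runif(1, 0.05, 0.6)) * (1 + rpois(1440, 2))
    expect_identical(detect_sleep_bouts(x), oracle_zero_runs(x))
  }
})

test_that("consolidation index follows its formula", {
  expect_equal(consolidation_index(c(10, 20, 30)), (100 + 400 + 900) / 60)
  expect_equal(consolidation_index(720), 720)
  expect_equal(consolidation_index(numeric(0)), 0)
  expect_error(consolidation_index(c(10, -1)), "negative")
})

test_that("sleep minutes split at phase boundaries by the minute they occur in", {
  # one 60-min bout straddling lights-off: ZT11:30 - ZT12:30
  x <- day_counts(list(c(690, 750)))
  tr <- make_trace(x)
  nd <- night_day_sleep(tr, 1)
  expect_equal(unname(nd["day_sleep_min"]), 30)
  expect_equal(unname(nd["night_sleep_min"]), 30)

  # asleep all night, awake all day
  x <- day_counts(list(c(720, 1440)))
  nd <- night_day_sleep(make_trace(x), 1)
  expect_equal(unname(nd["night_sleep_min"]), 720)
  expect_equal(unname(nd["day_sleep_min"]), 0)

  # no sleep at all
  nd <- night_day_sleep(make_trace(day_counts()), 1)
  expect_equal(unname(nd), c(0, 0))
})

test_that("latency and WASO follow their definitions on constructed nights", {
  # sleep onset exactly at ZT13 -> latency 60
  tr <- make_trace(day_counts(list(c(780, 900))))
  expect_equal(sleep_latency(tr, 1)$latency_min, 60)
  # ongoing bout at ZT12 -> latency 0
  tr <- make_trace(day_counts(list(c(700, 900))))
  expect_equal(sleep_latency(tr, 1)$latency_min, 0)
  # no night sleep -> censored 720
  lat <- sleep_latency(make_trace(day_counts()), 1)
  expect_equal(lat$latency_min, 720)
  expect_true(lat$censored)

  # continuous ZT12-24 sleep -> WASO 0
  tr <- make_trace(day_counts(list(c(720, 1440))))
  expect_equal(sleep_waso(tr, 1)$waso_min, 0)
  # onset ZT12, 300 asleep, 60 awake, 360 asleep -> WASO 60
  tr <- make_trace(day_counts(list(c(720, 1020), c(1080, 1440))))
  expect_equal(sleep_waso(tr, 1)$waso_min, 60)
  # no night sleep -> 0 with undefined flag
  w <- sleep_waso(make_trace(day_counts()), 1)
  expect_equal(w$waso_min, 0)
  expect_true(w$undefined)
})

test_that("ten hand-constructed nights match hand arithmetic", {
  # each case: sleep windows (0-based day minutes), expected
  # (night_sleep, latency, waso, ci)
  cases <- list(
    list(w = list(c(720, 1440)), e = c(720, 0, 0, 720)),
    list(w = list(c(780, 900)), e = c(120, 60, 540, 120)),
    list(w = list(c(720, 1020), c(1080, 1440)), e = c(660, 0, 60,
         (300^2 + 360^2) / 660)),
    list(w = list(), e = c(0, 720, 0, 0)),
    list(w = list(c(730, 740), c(760, 780), c(800, 830)),
         e = c(60, 10, 650, (100 + 400 + 900) / 60)),
    list(w = list(c(690, 750)), e = c(30, 0, 690, 30)),
    list(w = list(c(1430, 1440)), e = c(10, 710, 0, 10)),
    list(w = list(c(720, 725), c(1435, 1440)), e = c(10, 0, 710,
         (25 + 25) / 10)),
    list(w = list(c(900, 1440)), e = c(540, 180, 0, 540)),
    list(w = list(c(750, 900), c(960, 1200), c(1260, 1440)),
         e = c(570, 30, 120, (150^2 + 240^2 + 180^2) / 570)))
  for (cs in cases) {
    m <- sleep_metrics(make_trace(day_counts(cs$w)))
    expect_equal(m$night_sleep_min, cs$e[1])
    expect_equal(m$latency_min, cs$e[2])
    expect_equal(m$waso_min, cs$e[3])
    expect_equal(m$ci_min, cs$e[4], tolerance = 1e-12)
  }
})

test_that("night accounting conserves 720 minutes and CI is bounded by bout lengths", {
  set.seed(7)
  for (i in 1:100) {
    x <- rbinom(1440, 1, runif(1, 0.1, 0.7)) * (1 + rpois(1440, 2))
    tr <- make_trace(x)
    m <- sleep_metrics(tr)
    night <- damsleep:::sleep_minutes(x)[721:1440]
    expect_equal(m$night_sleep_min + sum(!night), 720)
    if (!m$latency_censored)
      expect_equal(m$latency_min + m$night_sleep_min + m$waso_min, 720)
    if (m$n_bouts_night >= 1) {
      runs <- damsleep:::true_runs(night)
      expect_gte(m$ci_min + 1e-9, m$mean_bout_len_night_min)
      expect_lte(m$ci_min, max(runs$length) + 1e-9)
    }
  }
})

test_that("merging two adjacent night bouts never decreases CI or night sleep", {
  set.seed(13)
  for (i in 1:30) {
    a <- sample(60:300, 1); gap <- sample(6:60, 1); b <- sample(60:300, 1)
    start <- 720
    frag <- day_counts(list(c(start, start + a),
                            c(start + a + gap, start + a + gap + b)))
    merged <- day_counts(list(c(start, start + a + gap + b)))
    mf <- sleep_metrics(make_trace(frag))
    mm <- sleep_metrics(make_trace(merged))
    expect_gte(mm$ci_min, mf$ci_min)
    expect_gte(mm$night_sleep_min, mf$night_sleep_min)
  }
})

test_that("sleep profile averages fractions across flies", {
  all_sleep <- make_trace(rep(0L, 1440))
  never <- make_trace(day_counts())
  night_only <- make_trace(day_counts(list(c(720, 1440))))

  p <- sleep_profile(list(all_sleep, all_sleep))
  expect_equal(p$mean_frac, rep(1, 48))
  expect_equal(p$sem, rep(0, 48))

  p <- sleep_profile(list(night_only))
  expect_equal(p$mean_frac, rep(c(0, 1), each = 24))

  p <- sleep_profile(list(all_sleep, never))
  expect_equal(p$mean_frac, rep(0.5, 48))
  expect_equal(nrow(p), 48)
})

test_that("per-fly averaging pools days and excludes censored nights", {
  x2 <- c(day_counts(list(c(720, 1440))), day_counts())
  tr <- make_trace(x2)
  m <- sleep_metrics(tr)
  a <- average_metrics(m)
  expect_equal(a$night_sleep_min, 360)   # (720 + 0) / 2
  expect_equal(a$latency_min, 0)         # censored night excluded
  expect_equal(a$n_nights_censored, 1)
})
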