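# Independent brute-force oracles; deliberately naive implementations that
# share no code with the package internals.

# enumerate zero-runs >= min_len by linear scan
oracle_zero_runs <- function(counts, min_len = 5L) {
  onsets <- integer()
  durs <- integer()
  run <- 0L
  for (i in seq_along(counts)) {
    if (counts[i] == 0) run <- run + 1L
    else {
      if (run >= min_len) {
        onsets <- c(onsets, i - run - 1L)  # 0-based
        durs <- c(durs, run)
      }
      run <- 0L
    }
  }
  if (run >= min_len) {
    onsets <- c(onsets, length(counts) - run)
    durs <- c(durs, run)
  }
  data.frame(onset_min = onsets, duration_min = durs)
}

# longest suffix of zeros, by scanning backwards
oracle_terminal_zeros <- function(counts) {
  k <- 0L
  for (i in rev(seq_along(counts))) {
    if (counts[i] != 0) break
    k <- k + 1L
  }
  k
}

# chi-square periodogram statistic at one period, by explicit fold-and-sum
oracle_qp <- function(x, P) {
  K <- length(x) %/% P
  x <- x[seq_len(K * P)]
  gm <- sum(x) / length(x)
  col_means <- numeric(P)
  for (h in seq_len(P))
    col_means[h] <- mean(x[seq(h, by = P, length.out = K)])
  denom <- sum((x - gm)^2) / (K * P)
  if (denom == 0) return(0)
  K * sum((col_means - gm)^2) / denom
}

# upper-tail hypergeometric p by summing choose() terms
oracle_hyper_p <- function(N, n, K, k) {
  jmax <- min(n, K)
  sum(vapply(k:jmax, function(j)
    choose(K, j) * choose(N - K, n - j), numeric(1))) / choose(N, n)
}

# BH step-up by hand
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# build a minimal activity_trace from a counts vector (starts at ZT0)
make_trace <- function(counts, fly_id = "f1", genotype = "test",
                       regime = rep("LD", ceiling(length(counts) / 1440))) {
  stopifnot(length(counts) %% 1440 == 0)
  sch <- light_schedule("08:00", 12, regime)
  n_days <- length(counts) / 1440
  light <- unlist(lapply(seq_len(n_days),
                         function(d) damsleep:::day_light_flags(sch, d)))
  damsleep:::new_activity_trace(
    fly_id = fly_id, genotype = genotype, channel = 1L, monitor_id = "M1",
    t0 = as.POSIXct("2024-01-01 08:00:00", tz = "UTC"),
    counts = as.integer(counts), light = light, schedule = sch)
}

# counts for one day with sleep exactly in the given 0-based minute windows
day_counts <- function(sleep_windows = list()) {
  x <- rep(1L, 1440L)
  for (w in sleep_windows) x[(w[1] + 1):(w[2])] <- 0L  # [from, to) 0-based
  x
}
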