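# Independent reference implementations and small builders used across the
# suite. The naive scan is a deliberately plain one-pass loop, written
# without reference to the package's segmentation code.

# Build a trace from a bare temperature vector at a regular interval.
make_trace <- function(tb, interval_min = 90, id = "x",
                       t0 = as.POSIXct("2020-01-01", tz = "UTC")) {
  time_s <- (seq_along(tb) - 1) * interval_min * 60
  tb_trace(id, time_s, tb, t0 = t0, t1 = t0 + time_s[length(time_s)],
           sampling_interval_min = interval_min)
}

# One-pass reference scan: walk the samples, open a bout when Tb drops
# below the euthermia threshold, close it at the first recovered sample.
naive_scan <- function(tb, time_s, interval_s, euth = 30, deep_tb = 20,
                       deep_h = 24, include_recovery = TRUE) {
  bouts <- list()
  open <- FALSE
  for (i in seq_along(tb)) {
    if (!open && tb[i] < euth) {
      open <- TRUE
      i0 <- i
    } else if (open && tb[i] >= euth) {
      bouts[[length(bouts) + 1]] <- list(i0 = i0, i1 = i - 1, rec = i,
                                         truncated = FALSE)
      open <- FALSE
    }
  }
  if (open)
    bouts[[length(bouts) + 1]] <- list(i0 = i0, i1 = length(tb), rec = NA,
                                       truncated = TRUE)
  rows <- lapply(bouts, function(b) {
    end_s <- if (b$truncated) time_s[b$i1] + interval_s else time_s[b$rec]
    dur_h <- (end_s - time_s[b$i0]) / 3600
    mn <- min(tb[b$i0:b$i1])
    mean_idx <- if (!b$truncated && include_recovery) b$i0:b$rec
                else b$i0:b$i1
    type <- if (mn >= deep_tb) "SHORT_SHALLOW"
            else if (dur_h > deep_h) "DEEP" else "SHORT"
    data.frame(start_s = time_s[b$i0], end_s = end_s, duration_h = dur_h,
               min_tb = mn, mean_tb = mean(tb[mean_idx]),
               bout_type = type, truncated = b$truncated)
  })
  if (!length(rows))
    return(data.frame(start_s = numeric(), end_s = numeric(),
                      duration_h = numeric(), min_tb = numeric(),
                      mean_tb = numeric(), bout_type = character(),
                      truncated = logical()))
  do.call(rbind, rows)
}

# Reflected random walk spanning the torpor and euthermic ranges, so runs
# below 30 degC of many lengths occur.
random_walk_tb <- function(n, start = 36, step_sd = 3) {
  x <- numeric(n)
  x[1] <- start
  for (i in seq_len(n - 1)) {
    x[i + 1] <- x[i] + rnorm(1, 0, step_sd)
    if (x[i + 1] > 45) x[i + 1] <- 90 - x[i + 1]
    if (x[i + 1] < 2) x[i + 1] <- 4 - x[i + 1]
  }
  x
}

# Tiny cohort CSV writers for io tests.
write_cohort_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

replica_cohort <- function() {
  data.frame(
    individual_id = c(sprintf("C%02d", 1:11), sprintf("H%02d", 1:11)),
    group = rep(c("control", "HF"), each = 11),
    mass_pre_g = rep(317, 22), mass_post_g = rep(310, 22),
    pellets_provided_g = rep(c(2000, 1500), each = 11),
    seeds_provided_g = rep(c(0, 500), each = 11),
    pellets_remaining_g = rep(118, 22),
    seeds_remaining_g = rep(c(0, 200), each = 11),
    pufa_pre_pct = rep(35, 22), pufa_post_pct = rep(31, 22),
    stringsAsFactors = FALSE)
}
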