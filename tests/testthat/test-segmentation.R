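test_that("a fully euthermic trace yields no bouts", {
  tr <- make_trace(rep(37, 100))
  expect_identical(nrow(detect_bouts(tr)), 0L)
})

test_that("a constructed excursion gives the documented bout metrics", {
  # 90-min spacing: three sub-threshold samples, recovery at the sixth
  tr <- make_trace(c(37, 37, 25, 24, 25, 37))
  b <- detect_bouts(tr)
  expect_identical(nrow(b), 1L)
  expect_equal(b$duration_h, 4.5)           # start to recovery sample
  expect_equal(b$min_tb, 24)
  expect_equal(b$mean_tb, mean(c(25, 24, 25, 37)))  # recovery included
  expect_identical(b$bout_type, "SHORT_SHALLOW")    # never below 20 degC
  expect_false(b$truncated)

  b2 <- detect_bouts(tr, include_recovery_in_mean = FALSE)
  expect_equal(b2$mean_tb, mean(c(25, 24, 25)))
  expect_equal(b2$duration_h, 4.5)          # duration convention unchanged
})

test_that("a record ending in torpor yields a truncated bout", {
  tr <- make_trace(c(37, 25, 24, 23))
  b <- detect_bouts(tr)
  expect_identical(nrow(b), 1L)
  expect_true(b$truncated)
  expect_equal(b$end_s, 3 * 5400 + 5400)    # last sample + one interval
  expect_equal(b$duration_h, 4.5)
  expect_equal(b$mean_tb, mean(c(25, 24, 23)))  # no recovery sample exists
})

test_that("classification honors the strict threshold conventions", {
  p <- segmentation_params()
  expect_identical(classify_bout(10.1, 2.7 * 24, p), "DEEP")
  expect_identical(classify_bout(18.5, 12.9, p), "SHORT")
  expect_identical(classify_bout(27.3, 4.7, p), "SHORT_SHALLOW")
  # boundary conventions: exactly 24 h is not "longer than 24 h";
  # a minimum of exactly 20 degC is not "below 20 degC"
  expect_identical(classify_bout(19.9, 24, p), "SHORT")
  expect_identical(classify_bout(20, 100, p), "SHORT_SHALLOW")
  expect_identical(classify_bout(19.999999, 24.000001, p), "DEEP")
  expect_error(classify_bout(15, 0, p), "positive")
})

test_that("classification is exhaustive and mutually exclusive", {
  set.seed(402)
  min_tb <- c(runif(500, 0, 30), 20, 20, 19.9999, 29.9)
  dur <- c(runif(504, 0.1, 200))
  dur[501:504] <- c(24, 24.0001, 24, 5)
  cls <- classify_bout(min_tb, dur, segmentation_params())
  expect_true(all(cls %in% c("DEEP", "SHORT", "SHORT_SHALLOW")))
  # re-derive from first principles; exactly one rule fires per bout
  deep <- min_tb < 20 & dur > 24
  short <- min_tb < 20 & dur <= 24
  sstb <- min_tb >= 20
  expect_true(all(deep + short + sstb == 1))
  expect_identical(cls == "DEEP", deep)
  expect_identical(cls == "SHORT", short)
  expect_identical(cls == "SHORT_SHALLOW", sstb)
})

test_that("merge_shallow preserves counts, leaves deep alone, idempotent", {
  b <- data.frame(bout_type = c("SHORT", "SHORT", "SHORT_SHALLOW",
                                "SHORT_SHALLOW", "SHORT_SHALLOW", "DEEP"))
  m <- merge_shallow(b)
  expect_identical(sum(m$bout_type == "SHALLOW"), 5L)
  expect_identical(sum(m$bout_type == "DEEP"), 1L)
  expect_identical(nrow(m), nrow(b))
  expect_identical(merge_shallow(m), m)
  empty <- b[0, , drop = FALSE]
  expect_identical(nrow(merge_shallow(empty)), 0L)

  set.seed(7)
  for (i in 1:20) {
    r <- data.frame(bout_type = sample(c("DEEP", "SHORT", "SHORT_SHALLOW",
                                         "SHALLOW"), 30, replace = TRUE))
    expect_identical(merge_shallow(merge_shallow(r)), merge_shallow(r))
  }
})

test_that("detect_bouts agrees with the naive reference scan", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(20:2000, 1)
    tb <- random_walk_tb(n)
    tr <- make_trace(tb)
    got <- detect_bouts(tr)
    want <- naive_scan(tb, tr$time_s, 5400)
    expect_identical(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got$start_s, want$start_s)
      expect_equal(got$end_s, want$end_s)
      expect_equal(got$min_tb, want$min_tb)
      expect_equal(got$mean_tb, want$mean_tb)
      expect_identical(got$bout_type, want$bout_type)
      expect_identical(got$truncated, want$truncated)
    }
  }
})

test_that("bouts partition the sub-threshold samples", {
  set.seed(55)
  for (i in 1:10) {
    tb <- random_walk_tb(sample(100:1500, 1))
    tr <- make_trace(tb)
    b <- detect_bouts(tr)
    expect_identical(sum(b$n_samples), sum(tb < 30))
    if (nrow(b) > 1)  # disjoint and ordered
      expect_true(all(b$start_s[-1] >= b$end_s[-nrow(b)]))
    expect_true(sum(b$duration_h) * 3600 <=
                  tr$time_s[length(tb)] - tr$time_s[1] + 5400 + 1e-9)
  }
})

test_that("raising the euthermia threshold never shrinks time in torpor", {
  set.seed(89)
  for (i in 1:8) {
    tb <- random_walk_tb(800)
    tr <- make_trace(tb)
    tot <- vapply(c(22, 26, 30, 34), function(th) {
      b <- detect_bouts(tr, segmentation_params(euthermia_threshold = th))
      sum(b$duration_h)
    }, numeric(1))
    expect_true(all(diff(tot) >= -1e-9))
  }
})

test_that("gap policies bridge, split, and error behave as documented", {
  # bout 25,24,23,(missing),24,25 then recovery; gap of 2 intervals
  time_s <- c(0, 5400, 10800, 16200, 21600, 32400, 37800, 43200)
  tb <- c(37, 37, 25, 24, 23, 24, 25, 37)
  tr <- tb_trace("g", time_s, tb)
  expect_identical(nrow(tr$gaps), 1L)

  br <- detect_bouts(tr, gap_policy = "bridge")
  expect_identical(nrow(br), 1L)
  expect_equal(br$duration_h, (43200 - 10800) / 3600)  # clock time kept
  expect_identical(br$n_samples, 5L)                   # no sample invented
  expect_equal(br$mean_tb, mean(c(25, 24, 23, 24, 25, 37)))

  sp <- detect_bouts(tr, gap_policy = "split")
  expect_identical(nrow(sp), 2L)
  expect_true(sp$truncated[1])
  expect_equal(sp$end_s[1], 21600 + 5400)
  expect_equal(sp$start_s[2], 32400)
  expect_false(sp$truncated[2])

  expect_error(detect_bouts(tr, gap_policy = "error"), "gap")
})

test_that("degenerate traces are rejected", {
  tr <- make_trace(c(37, 36))
  t1 <- tb_trace("one", 0, 36, t1 = as.POSIXct("1970-01-02", tz = "UTC"))
  expect_error(detect_bouts(t1), "at least 2 samples")
  expect_error(segmentation_params(euthermia_threshold = 20,
                                   deep_tb_threshold = 25),
               "below euthermia")
})
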