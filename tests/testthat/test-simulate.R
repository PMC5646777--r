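test_that("identical configs give identical cohorts, truth, and traces", {
  cfg <- simulation_config(seed = 99, n_per_group = 3,
                           experiment_span_d = 50)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$ground_truth$individuals, s2$ground_truth$individuals)
  expect_identical(lapply(s1$traces, `[[`, "tb"),
                   lapply(s2$traces, `[[`, "tb"))
  # rendering does not perturb the cohort draws
  s3 <- simulate_cohort(cfg, traces = FALSE)
  expect_identical(s1$cohort, s3$cohort)
})

test_that("hibernator_fraction = 0 yields no deep bouts anywhere", {
  cfg <- simulation_config(seed = 4, hibernator_fraction = 0)
  sim <- simulate_cohort(cfg, traces = FALSE)
  types <- unlist(lapply(sim$ground_truth$schedules, `[[`, "type"))
  expect_false("DEEP" %in% types)
  expect_true(all(!sim$ground_truth$individuals$hibernator))
})

test_that("schedules are disjoint with euthermic gaps of one interval", {
  cfg <- simulation_config(seed = 17)
  sim <- simulate_cohort(cfg, traces = FALSE)
  interval_d <- cfg$sampling_interval_min / 60 / 24
  for (s in sim$ground_truth$schedules) {
    if (nrow(s) < 2) next
    ends <- s$onset_d + s$duration_d
    expect_true(all(s$onset_d[-1] - ends[-nrow(s)] >= interval_d - 1e-9))
    expect_true(all(ends <= cfg$experiment_span_d))
    expect_true(all(s$onset_d >= 0))
  }
})

test_that("deep days do not track seed intake when the effect is off", {
  cfg <- simulation_config(seed = 71, beta_seed_on_deep_days = 0)
  set.seed(cfg$seed)
  seeds <- runif(500, 154, 455)
  totals <- vapply(seeds, function(s) {
    sch <- simulate_schedule(cfg, seeds_intake_g = s, hibernator = TRUE)
    sum(sch$duration_d[sch$type == "DEEP"])
  }, numeric(1))
  fit <- lm(totals ~ seeds)
  ci <- confint(fit, "seeds", level = 0.99)
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("deep plateau draws are centred on the configured target", {
  cfg <- simulation_config(seed = 103)
  set.seed(cfg$seed)
  plats <- unlist(lapply(1:300, function(i) {
    sch <- simulate_schedule(cfg, hibernator = TRUE,
                             individual_offset =
                               rnorm(1, 0, cfg$individual_plateau_sd))
    sch$plateau_tb[sch$type == "DEEP"]
  }))
  se <- sd(plats) / sqrt(length(plats))
  expect_lt(abs(mean(plats) - cfg$bout_types$deep$plateau_mean), 2 * se + 0.05)
})

test_that("an empty schedule renders to a constant baseline at zero noise", {
  cfg <- noiseless(simulation_config(seed = 2, experiment_span_d = 10))
  empty <- data.frame(type = character(), onset_d = numeric(),
                      duration_d = numeric(), plateau_tb = numeric())
  tr <- render_trace(empty, cfg, baseline_tb = 36.5)
  expect_true(all(tr$tb == 36.5))
  expect_identical(length(tr$tb), as.integer(10 * 86400 / 5400) + 1L)
})

test_that("a single noiseless deep bout is recovered on segmentation", {
  cfg <- noiseless(simulation_config(seed = 6, experiment_span_d = 30))
  sch <- data.frame(type = "DEEP", onset_d = 10, duration_d = 2.7,
                    plateau_tb = 10.1)
  tr <- render_trace(sch, cfg)
  b <- detect_bouts(tr)
  expect_identical(nrow(b), 1L)
  expect_identical(b$bout_type, "DEEP")
  interval_d <- cfg$sampling_interval_min / 60 / 24
  expect_lte(abs(b$start_s / 86400 - 10), interval_d)
  expect_lte(abs(b$end_s / 86400 - 12.7), interval_d)
  expect_equal(b$min_tb, 10.1, tolerance = 0.05)
})

test_that("impossible bout loads are rejected as infeasible packing", {
  cfg <- simulation_config(seed = 9, experiment_span_d = 12,
                           deep_total_base_d = 40, deep_total_sd_d = 0)
  set.seed(1)
  expect_error(simulate_schedule(cfg, hibernator = TRUE),
               "infeasible packing")
})

test_that("null effect sizes and zero noise freeze the PUFA measurements", {
  cfg <- simulation_config(seed = 14, pufa_base_change = 0,
                           beta_deep_on_pufa = 0, beta_seed_on_pufa = 0,
                           pufa_resid_sd = 0)
  sim <- simulate_cohort(cfg, traces = FALSE)
  expect_identical(sim$cohort$pufa_post_pct, sim$cohort$pufa_pre_pct)
})

test_that("a written simulation reads back equal to the ground truth", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(seed = 44, n_per_group = 2,
                           experiment_span_d = 25)
  sim <- simulate_cohort(cfg)
  write_simulation(sim, dir)
  back <- read_traces(file.path(dir, "traces.csv"))
  for (id in names(sim$traces))
    expect_equal(back[[id]]$tb, sim$traces[[id]]$tb, tolerance = 1e-9)
  co <- suppressMessages(read_cohort(file.path(dir, "cohort.csv"),
                                     study_replica = FALSE))
  expect_equal(co$mass_pre_g, sim$cohort$mass_pre_g, tolerance = 1e-9)
  expect_identical(as.character(co$group), as.character(sim$cohort$group))
  pufa <- read.csv(file.path(dir, "pufa.csv"))
  expect_identical(nrow(pufa), 8L)
})
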