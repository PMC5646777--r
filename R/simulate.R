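# Simulator for overwintering experiments: per-individual ground-truth bout
# schedules, rendered body-temperature traces, and cohort covariate tables
# with configurable effect sizes. Defaults emulate the statistical structure
# of a two-group (control vs high-fat) hamster overwintering study: 11
# females per group over a ~137-day winter, euthermic baselines near 36.5
# degC, deep bouts near 10.1 degC lasting ~2.7 d clustered late in the
# season, short bouts near 18.5 degC (~13 h), short-shallow bouts near 27.3
# degC (~5 h), seed intake 154-455 g in the high-fat group, and a winter
# PUFA decline coupled to deep-torpor time and dampened by seed intake.

#' Simulation configuration
#'
#' All knobs of the trace/cohort simulator, with defaults emulating the
#' study conditions. Where the emulated quantities were published as mean
#' +/- SE, the between-individual sd defaults are back-converted with the
#' published n (e.g. body mass sd 33 g from SE 10 with n = 11).
#'
#' @param seed Integer RNG seed; identical configs give identical output.
#' @param n_per_group Individuals per group (default 11).
#' @param experiment_span_d Experiment window length in days (default 137,
#'   a 19 Dec - 5 May winter).
#' @param sampling_interval_min Logger sampling interval, minutes
#'   (default 90).
#' @param baseline_tb_mean,baseline_tb_sd Euthermic baseline Tb (degC):
#'   between-individual mean and sd (defaults 36.5, 0.3).
#' @param ar1_coef,ar1_sd Within-individual euthermic fluctuation: AR(1)
#'   coefficient at the sampling interval and stationary sd in degC
#'   (defaults 0.7, 0.3). Set `ar1_sd = 0` for a flat baseline.
#' @param measurement_sd Logger measurement noise sd, degC (default 0.2;
#'   the logger accuracy is +/-0.5 degC).
#' @param quantize_step Optional logger quantization step in degC (e.g.
#'   0.5); `0` (default) disables quantization.
#' @param bout_types Per bout type (`deep`, `short`, `shallow`), a list
#'   with `plateau_mean`, `plateau_sd` (degC) and `duration_mean_h`,
#'   `duration_sd_h`. Defaults: deep 10.1 degC / 64.8 h (2.7 d), short
#'   18.5 degC / 12.9 h, short-shallow 27.3 degC / 4.7 h.
#' @param cooling_tau_h,rewarm_tau_h Exponential time constants for bout
#'   entry and arousal (defaults 4 h and 2 h; rewarming is faster, as in
#'   heterotherm physiology). Shortened proportionally for bouts too brief
#'   to complete the relaxation.
#' @param individual_plateau_sd Per-individual random offset (degC) added
#'   to all of an individual's bout plateaus; exercises the random
#'   intercept of the bout-level mixed models (default 0.3).
#' @param hibernator_fraction Probability that an individual expresses deep
#'   torpor at all (default 0.5).
#' @param deep_total_base_d Expected total deep-torpor days for a
#'   hibernator with zero seed intake (default 13).
#' @param deep_total_sd_d Individual noise sd on that total (default 1.2).
#' @param beta_seed_on_deep_days Effect of seed intake on expected deep
#'   torpor, days per gram (default -0.02).
#' @param n_short_mean,n_shallow_mean Expected counts of short and
#'   short-shallow bouts per individual, Poisson (defaults 2.2 and 25).
#' @param posthib_mean_d,posthib_sd_d Post-hibernation period, days
#'   (defaults 13, 4): deep bouts are packed just before it, late in the
#'   season.
#' @param inter_deep_gap_d Range (2-vector, days) of euthermic gaps between
#'   consecutive deep bouts (default `c(0.5, 1)`).
#' @param mass_pre_mean,mass_pre_sd Pre-winter body mass, g (defaults 317,
#'   33).
#' @param mass_change_pct_mean Named vector `c(control = , HF = )`: mean
#'   percent body-mass change over winter (defaults -4.6, +1.9).
#' @param mass_change_pct_sd Its sd (default 10).
#' @param pellets_provided_g Named vector of pellets provided per group
#'   (defaults control 2000 g, HF 1500 g).
#' @param seeds_provided_g Seeds provided in the HF group (default 500 g;
#'   control gets none).
#' @param pellets_intake_pct_mean,pellets_intake_pct_sd Percent of provided
#'   pellets eaten (defaults 94.5, 5, clipped to `[50, 100]`).
#' @param seeds_intake_range Uniform range of seed intake in the HF group,
#'   grams (default `c(154, 455)`).
#' @param pufa_pre_mean,pufa_pre_sd Pre-winter WAT PUFA proportion, percent
#'   of total fatty acids (defaults 35, 3).
#' @param pufa_base_change Baseline winter change in PUFA percentage points
#'   common to all individuals (default -5, a decline).
#' @param beta_deep_on_pufa Effect of deep-torpor time on PUFA change,
#'   points per day (default -0.5).
#' @param beta_seed_on_pufa Effect of seed intake on PUFA change, points
#'   per gram (default +0.02).
#' @param pufa_resid_sd Residual sd of PUFA change, points (default 1.5).
#' @param n_missing_pufa_pre Number of HF individuals whose pre-winter PUFA
#'   sample is set missing (default 0; the emulated study had 1).
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_per_group = 11L,
                              experiment_span_d = 137,
                              sampling_interval_min = 90,
                              baseline_tb_mean = 36.5,
                              baseline_tb_sd = 0.3,
                              ar1_coef = 0.7,
                              ar1_sd = 0.3,
                              measurement_sd = 0.2,
                              quantize_step = 0,
                              bout_types = list(
                                deep = list(plateau_mean = 10.1,
                                            plateau_sd = 0.7,
                                            duration_mean_h = 64.8,
                                            duration_sd_h = 8.7),
                                short = list(plateau_mean = 18.5,
                                             plateau_sd = 0.6,
                                             duration_mean_h = 12.9,
                                             duration_sd_h = 1.2),
                                shallow = list(plateau_mean = 27.3,
                                               plateau_sd = 1.8,
                                               duration_mean_h = 4.7,
                                               duration_sd_h = 1.4)),
                              cooling_tau_h = 4,
                              rewarm_tau_h = 2,
                              individual_plateau_sd = 0.3,
                              hibernator_fraction = 0.5,
                              deep_total_base_d = 13,
                              deep_total_sd_d = 1.2,
                              beta_seed_on_deep_days = -0.02,
                              n_short_mean = 2.2,
                              n_shallow_mean = 25,
                              posthib_mean_d = 13,
                              posthib_sd_d = 4,
                              inter_deep_gap_d = c(0.5, 1),
                              mass_pre_mean = 317,
                              mass_pre_sd = 33,
                              mass_change_pct_mean = c(control = -4.6,
                                                       HF = 1.9),
                              mass_change_pct_sd = 10,
                              pellets_provided_g = c(control = 2000,
                                                     HF = 1500),
                              seeds_provided_g = 500,
                              pellets_intake_pct_mean = 94.5,
                              pellets_intake_pct_sd = 5,
                              seeds_intake_range = c(154, 455),
                              pufa_pre_mean = 35,
                              pufa_pre_sd = 3,
                              pufa_base_change = -5,
                              beta_deep_on_pufa = -0.5,
                              beta_seed_on_pufa = 0.02,
                              pufa_resid_sd = 1.5,
                              n_missing_pufa_pre = 0L) {
  cfg <- as.list(environment())
  sds <- c(baseline_tb_sd, ar1_sd, measurement_sd, individual_plateau_sd,
           deep_total_sd_d, posthib_sd_d, mass_pre_sd, mass_change_pct_sd,
           pellets_intake_pct_sd, pufa_pre_sd, pufa_resid_sd,
           vapply(bout_types, function(b)
             c(b$plateau_sd, b$duration_sd_h), numeric(2)))
  stopifnot(all(is.finite(sds)), all(sds >= 0),
            hibernator_fraction >= 0, hibernator_fraction <= 1,
            abs(ar1_coef) < 1, experiment_span_d > 0,
            sampling_interval_min > 0, n_per_group >= 1,
            length(seeds_intake_range) == 2,
            seeds_intake_range[1] <= seeds_intake_range[2],
            seeds_intake_range[2] <= seeds_provided_g,
            length(inter_deep_gap_d) == 2,
            inter_deep_gap_d[1] > 0)
  class(cfg) <- "simulation_config"
  cfg
}

#' Turn off all noise sources of a simulation config
#'
#' Convenience for exact round-trip tests: zero baseline fluctuation,
#' measurement noise and quantization (the between-individual draws for
#' schedules and covariates remain stochastic).
#'
#' @param config A [simulation_config()].
#' @return The config with `ar1_sd`, `measurement_sd`, `quantize_step` = 0.
#' @export
noiseless <- function(config) {
  config$ar1_sd <- 0
  config$measurement_sd <- 0
  config$quantize_step <- 0
  config
}

rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  for (i in bad) {              # resample; clamp after 50 tries
    for (tries in 1:50) {
      x[i] <- rnorm(1, mean, sd)
      if (x[i] >= lo && x[i] <= hi) break
    }
    x[i] <- min(max(x[i], lo), hi)
  }
  x
}

# Split a total of deep-torpor days into bout durations averaging
# `mean_d` days, each at least `min_d`, summing exactly to the total.
split_deep_total <- function(total_d, mean_d, sd_d, min_d = 1.1) {
  n <- max(1L, round(total_d / mean_d))
  if (total_d / n < min_d) n <- max(1L, floor(total_d / min_d))
  for (tries in 1:50) {
    w <- abs(rnorm(n, mean_d, sd_d))
    d <- total_d * w / sum(w)
    if (all(d >= min_d)) return(d)
  }
  rep(total_d / n, n)
}

#' Simulate one individual's ground-truth bout schedule
#'
#' Draws a non-overlapping schedule of torpor bouts over the experiment
#' window. Deep bouts (hibernators only) are packed late in the season,
#' separated by short euthermic gaps and followed by a post-hibernation
#' period; their expected total decreases linearly in seed intake by
#' `beta_seed_on_deep_days`. Short and short-shallow bouts are scattered
#' over the euthermic part of the season with inter-bout gaps of at least
#' one sampling interval.
#'
#' Uses the current RNG state; seed upstream (see [simulate_cohort()]).
#'
#' @param config A [simulation_config()].
#' @param seeds_intake_g Seed intake of this individual, grams.
#' @param hibernator Does this individual express deep torpor?
#' @param individual_offset Additive per-individual plateau offset, degC.
#' @return Data frame ordered by onset: `type` (`DEEP`, `SHORT`,
#'   `SHORT_SHALLOW`), `onset_d`, `duration_d`, `plateau_tb`.
#' @export
simulate_schedule <- function(config, seeds_intake_g = 0, hibernator = TRUE,
                              individual_offset = 0) {
  span <- config$experiment_span_d
  interval_d <- config$sampling_interval_min / 60 / 24
  sched <- list()

  hib_start <- span  # start of the deep-torpor block
  if (hibernator) {
    target <- config$deep_total_base_d +
      config$beta_seed_on_deep_days * seeds_intake_g +
      rnorm(1, 0, config$deep_total_sd_d)
    target <- max(1.1, target)
    bt <- config$bout_types$deep
    durs <- split_deep_total(target, bt$duration_mean_h / 24,
                             bt$duration_sd_h / 24)
    gaps <- runif(length(durs), config$inter_deep_gap_d[1],
                  config$inter_deep_gap_d[2])
    block <- sum(durs) + sum(gaps[-1])
    posthib <- max(1, rnorm(1, config$posthib_mean_d, config$posthib_sd_d))
    if (block + posthib + 2 > span)
      stop("infeasible packing: requested deep-torpor time exceeds the ",
           "experiment span", call. = FALSE)
    hib_start <- span - posthib - block
    onset <- hib_start
    for (i in seq_along(durs)) {
      plat <- rnorm_trunc(1, bt$plateau_mean + individual_offset,
                          bt$plateau_sd, lo = 2, hi = 19.5)
      sched[[length(sched) + 1L]] <- data.frame(
        type = "DEEP", onset_d = onset, duration_d = durs[i],
        plateau_tb = plat, stringsAsFactors = FALSE)
      onset <- onset + durs[i] + if (i < length(durs)) gaps[i + 1L] else 0
    }
  }

  # shallow torpor lives in the euthermic season before the deep block
  window_end <- min(hib_start, span) - 0.5
  window_start <- 1
  n_short <- rpois(1, config$n_short_mean)
  n_shallow <- rpois(1, config$n_shallow_mean)
  kinds <- c(rep("SHORT", n_short), rep("SHORT_SHALLOW", n_shallow))
  if (length(kinds) && window_end > window_start + 1) {
    starts <- sort(runif(length(kinds), window_start, window_end))
    kinds <- sample(kinds)                 # interleave the two kinds
    prev_end <- -Inf
    min_gap <- max(interval_d, 0.1)
    for (i in seq_along(kinds)) {
      bt <- config$bout_types[[if (kinds[i] == "SHORT") "short"
                               else "shallow"]]
      dur_h <- if (kinds[i] == "SHORT")
        rnorm_trunc(1, bt$duration_mean_h, bt$duration_sd_h, lo = 3,
                    hi = 22)
      else
        rnorm_trunc(1, bt$duration_mean_h, bt$duration_sd_h, lo = 2.5,
                    hi = 12)
      plat <- if (kinds[i] == "SHORT")
        rnorm_trunc(1, bt$plateau_mean + individual_offset, bt$plateau_sd,
                    lo = 12, hi = 19.5)
      else
        rnorm_trunc(1, bt$plateau_mean + individual_offset, bt$plateau_sd,
                    lo = 20.5, hi = 29)
      onset <- max(starts[i], prev_end + min_gap)
      end <- onset + dur_h / 24
      if (end > window_end) next           # does not fit; drop this bout
      sched[[length(sched) + 1L]] <- data.frame(
        type = kinds[i], onset_d = onset, duration_d = dur_h / 24,
        plateau_tb = plat, stringsAsFactors = FALSE)
      prev_end <- end
    }
  }

  if (!length(sched))
    return(data.frame(type = character(), onset_d = numeric(),
                      duration_d = numeric(), plateau_tb = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, sched)
  out <- out[order(out$onset_d), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Render a body-temperature trace from a bout schedule
#'
#' Builds the piecewise Tb process: an AR(1) euthermic baseline;
#' within each scheduled bout, exponential relaxation from just below the
#' euthermia threshold toward the bout plateau on entry and back on
#' arousal (time constants from the config, shortened for brief bouts);
#' then sampling at the configured interval, measurement noise, and
#' optional quantization. In-bout values are capped at 29.4 degC so a
#' noiseless rendering is recovered exactly by segmentation at the 30 degC
#' threshold.
#'
#' Uses the current RNG state.
#'
#' @param schedule Schedule from [simulate_schedule()].
#' @param config A [simulation_config()].
#' @param individual_id Id for the resulting trace.
#' @param baseline_tb This individual's euthermic baseline (degC).
#' @param t0 Experiment onset timestamp (POSIXct or string, UTC).
#' @return A [tb_trace()] spanning the experiment window.
#' @export
render_trace <- function(schedule, config, individual_id = "sim",
                         baseline_tb = config$baseline_tb_mean,
                         t0 = "2014-12-19 00:00:00") {
  interval_s <- config$sampling_interval_min * 60
  span_s <- config$experiment_span_d * 86400
  time_s <- seq(0, span_s, by = interval_s)
  n <- length(time_s)

  tb <- rep(baseline_tb, n)
  if (config$ar1_sd > 0) {
    innov <- rnorm(n, 0, config$ar1_sd * sqrt(1 - config$ar1_coef^2))
    tb <- tb + as.numeric(stats::filter(innov, config$ar1_coef,
                                        method = "recursive"))
  }

  entry_tb <- 29.4  # just below the euthermia threshold
  for (i in seq_len(nrow(schedule))) {
    onset_s <- schedule$onset_d[i] * 86400
    end_s <- onset_s + schedule$duration_d[i] * 86400
    idx <- which(time_s >= onset_s & time_s < end_s)
    if (!length(idx)) next
    dur_h <- schedule$duration_d[i] * 24
    tau_c <- min(config$cooling_tau_h, dur_h / 8) * 3600
    tau_r <- min(config$rewarm_tau_h, dur_h / 8) * 3600
    plat <- schedule$plateau_tb[i]
    t_from <- time_s[idx] - onset_s
    t_to <- end_s - time_s[idx]
    val <- plat + (entry_tb - plat) * (exp(-t_from / tau_c) +
                                         exp(-t_to / tau_r))
    tb[idx] <- pmin(val, entry_tb)
  }

  if (config$measurement_sd > 0)
    tb <- tb + rnorm(n, 0, config$measurement_sd)
  if (config$quantize_step > 0)
    tb <- round(tb / config$quantize_step) * config$quantize_step
  tb <- pmin(pmax(tb, -40), 85)

  t0 <- as.POSIXct(t0, tz = "UTC")
  tb_trace(individual_id, time_s, tb, t0 = t0, t1 = t0 + span_s,
           sampling_interval_min = config$sampling_interval_min)
}

#' Simulate a full cohort with ground truth
#'
#' Draws per-individual covariates, ground-truth bout schedules, optional
#' rendered traces, and the PUFA table. PUFA after winter is
#' `pufa_pre + base_change + beta_deep * deep_days + beta_seed * seeds_g +
#' noise`, clipped to `[0, 100]`; control individuals receive no seeds.
#' Identical configs (including seed) give identical output whether or not
#' traces are rendered.
#'
#' @param config A [simulation_config()].
#' @param traces Render Tb traces (default `TRUE`); `FALSE` skips rendering
#'   for cohort-level statistical experiments.
#' @param t0 Experiment onset timestamp (UTC).
#' @return A list of class `hib_simulation`:
#'   * `config` — the config used;
#'   * `cohort` — covariate table in the [read_cohort()] column layout;
#'   * `traces` — named list of [tb_trace()]s, or `NULL`;
#'   * `ground_truth` — list with `individuals` (data frame of true
#'     per-individual quantities: hibernator flag, bout counts, deep and
#'     shallow totals in days, seed intake, baseline Tb) and `schedules`
#'     (named list of schedule data frames).
#' @export
simulate_cohort <- function(config, traces = TRUE,
                            t0 = "2014-12-19 00:00:00") {
  set.seed(config$seed)
  n <- config$n_per_group
  ids <- c(sprintf("C%02d", seq_len(n)), sprintf("H%02d", seq_len(n)))
  group <- rep(c("control", "HF"), each = n)

  mass_pre <- rnorm_trunc(2 * n, config$mass_pre_mean, config$mass_pre_sd,
                          lo = 150)
  mass_change <- rnorm(2 * n, config$mass_change_pct_mean[group],
                       config$mass_change_pct_sd)
  mass_post <- pmax(100, mass_pre * (1 + mass_change / 100))

  hibernator <- rbinom(2 * n, 1, config$hibernator_fraction) == 1
  seeds_provided <- ifelse(group == "HF", config$seeds_provided_g, 0)
  seeds_intake <- ifelse(group == "HF",
                         runif(2 * n, config$seeds_intake_range[1],
                               config$seeds_intake_range[2]), 0)
  pellets_provided <- config$pellets_provided_g[group]
  pellets_pct <- rnorm_trunc(2 * n, config$pellets_intake_pct_mean,
                             config$pellets_intake_pct_sd, lo = 50, hi = 100)
  pellets_intake <- pellets_provided * pellets_pct / 100
  offsets <- rnorm(2 * n, 0, config$individual_plateau_sd)
  baselines <- rnorm(2 * n, config$baseline_tb_mean, config$baseline_tb_sd)

  schedules <- vector("list", 2 * n)
  names(schedules) <- ids
  for (i in seq_len(2 * n))
    schedules[[i]] <- simulate_schedule(config, seeds_intake[i],
                                        hibernator[i], offsets[i])

  truth <- do.call(rbind, lapply(seq_len(2 * n), function(i) {
    s <- schedules[[i]]
    deep <- s$type == "DEEP"
    data.frame(individual_id = ids[i], group = group[i],
               hibernator = any(deep),
               deep_n = sum(deep), deep_total_d = sum(s$duration_d[deep]),
               shallow_n = sum(!deep),
               shallow_total_d = sum(s$duration_d[!deep]),
               deep_min_tb = if (any(deep)) mean(s$plateau_tb[deep])
                             else NA_real_,
               shallow_min_tb = if (any(!deep)) mean(s$plateau_tb[!deep])
                                else NA_real_,
               seeds_intake_g = seeds_intake[i],
               baseline_tb = baselines[i],
               plateau_offset = offsets[i],
               stringsAsFactors = FALSE)
  }))
  truth$group <- factor(truth$group, levels = c("control", "HF"))

  pufa_pre <- rnorm_trunc(2 * n, config$pufa_pre_mean, config$pufa_pre_sd,
                          lo = 0, hi = 100)
  pufa_post <- pufa_pre + config$pufa_base_change +
    config$beta_deep_on_pufa * truth$deep_total_d +
    config$beta_seed_on_pufa * seeds_intake +
    rnorm(2 * n, 0, config$pufa_resid_sd)
  pufa_post <- pmin(pmax(pufa_post, 0), 100)
  if (config$n_missing_pufa_pre > 0) {
    hf_idx <- which(group == "HF")
    drop <- sample(hf_idx, min(config$n_missing_pufa_pre, length(hf_idx)))
    pufa_pre[drop] <- NA_real_
  }

  cohort <- data.frame(
    individual_id = ids,
    group = factor(group, levels = c("control", "HF")),
    mass_pre_g = mass_pre, mass_post_g = mass_post,
    pellets_provided_g = pellets_provided,
    seeds_provided_g = seeds_provided,
    pellets_remaining_g = pellets_provided - pellets_intake,
    seeds_remaining_g = seeds_provided - seeds_intake,
    pufa_pre_pct = pufa_pre, pufa_post_pct = pufa_post,
    stringsAsFactors = FALSE)

  trace_list <- NULL
  if (traces) {
    trace_list <- lapply(seq_len(2 * n), function(i)
      render_trace(schedules[[i]], config, ids[i], baselines[i], t0 = t0))
    names(trace_list) <- ids
  }

  structure(list(config = config, cohort = cohort, traces = trace_list,
                 ground_truth = list(individuals = truth,
                                     schedules = schedules)),
            class = "hib_simulation")
}

#' @export
print.hib_simulation <- function(x, ...) {
  cat(sprintf("<hib_simulation> %d individuals (%d per group), %g d span",
              nrow(x$cohort), x$config$n_per_group,
              x$config$experiment_span_d))
  cat(sprintf(", %d hibernators", sum(x$ground_truth$individuals$hibernator)))
  cat(if (is.null(x$traces)) ", traces not rendered\n" else
    sprintf(", %d traces\n", length(x$traces)))
  invisible(x)
}

#' Write a simulation to disk
#'
#' Writes `traces.csv` (if rendered), `cohort.csv`, `pufa.csv` (long
#' pre/post table) and `ground_truth.json` into a directory.
#'
#' @param sim A `hib_simulation` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!is.null(sim$traces))
    write_traces(sim$traces, file.path(dir, "traces.csv"))
  write.csv(sim$cohort, file.path(dir, "cohort.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(pufa_long(sim$cohort), file.path(dir, "pufa.csv"),
            row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(individuals = sim$ground_truth$individuals,
         schedules = sim$ground_truth$schedules),
    file.path(dir, "ground_truth.json"),
    dataframe = "rows", digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
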