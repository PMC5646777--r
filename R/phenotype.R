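# Per-individual hibernation phenotypes: bout counts, time in torpor, bout
# temperatures, hibernator status, and phenology. Durations are carried in
# hours internally and reported in days (hours / 24).

.PHENO_CATEGORIES <- c("deep", "shallow", "both")
.PHENO_METRICS <- c("n", "total_d", "mean_d", "min_tb", "mean_tb")

category_summary <- function(bouts) {
  n <- nrow(bouts)
  if (n == 0L)
    return(list(n = 0L, total_d = 0, mean_d = NA_real_,
                min_tb = NA_real_, mean_tb = NA_real_))
  total_h <- sum(bouts$duration_h)
  list(n = n,
       total_d = total_h / 24,
       mean_d = total_h / n / 24,
       min_tb = mean(bouts$min_tb),   # mean over bouts of per-bout minimum
       mean_tb = mean(bouts$mean_tb))
}

#' Summarize one individual's torpor bouts into a hibernation phenotype
#'
#' For each bout category (`deep`, `shallow` = short + short-shallow
#' pooled, and `both` combined) the phenotype records the number of bouts,
#' total and mean bout duration in days, the mean over bouts of the per-bout
#' minimum Tb, and the mean bout Tb. An individual is a hibernator if it
#' expressed at least one deep bout; only hibernators get phenology:
#' pre-hibernation period (experiment onset to onset of the first deep
#' bout), hibernation duration (first deep bout onset to termination of the
#' last deep bout), and post-hibernation period (last deep bout end to
#' experiment end), all in days. Shallow bouts play no role in phenology.
#'
#' Individuals without bouts of a category get `n = 0`, `total = 0` and
#' missing (`NA`) means; non-hibernators get missing phenology, not zeros.
#'
#' @param bouts Bout table from [detect_bouts()] for this individual
#'   (any mix of `DEEP`/`SHORT`/`SHORT_SHALLOW`/`SHALLOW` labels; short
#'   categories are pooled internally).
#' @param trace The individual's [tb_trace()]; supplies the experiment
#'   window.
#' @return A one-row data frame: `individual_id`, `deep_n`, `deep_total_d`,
#'   `deep_mean_d`, `deep_min_tb`, `deep_mean_tb`, the same five for
#'   `shallow_*` and `both_*`, then `is_hibernator`, `prehib_d`, `hib_d`,
#'   `posthib_d`, `span_d`.
#' @export
summarize_individual <- function(bouts, trace) {
  stopifnot(inherits(trace, "tb_trace"))
  span_s <- as.numeric(difftime(trace$t1, trace$t0, units = "secs"))
  if (nrow(bouts)) {
    if (!all(bouts$individual_id == trace$individual_id))
      stop("bouts belong to a different individual than the trace",
           call. = FALSE)
    # truncated terminal bouts may overhang t1 by one sampling interval
    slack <- trace$sampling_interval_min * 60 + 1e-6
    if (any(bouts$start_s < -1e-6) || any(bouts$end_s > span_s + slack))
      stop("bout outside the experiment window for individual ",
           trace$individual_id, call. = FALSE)
  }
  merged <- merge_shallow(bouts)
  deep <- merged[merged$bout_type == "DEEP", , drop = FALSE]
  shallow <- merged[merged$bout_type == "SHALLOW", , drop = FALSE]

  row <- data.frame(individual_id = trace$individual_id,
                    stringsAsFactors = FALSE)
  for (cat in .PHENO_CATEGORIES) {
    b <- switch(cat, deep = deep, shallow = shallow, both = merged)
    s <- category_summary(b)
    for (m in .PHENO_METRICS) row[[paste0(cat, "_", m)]] <- s[[m]]
  }
  row$is_hibernator <- nrow(deep) >= 1L
  if (row$is_hibernator) {
    first_on <- min(deep$start_s)
    last_off <- max(deep$end_s)
    row$prehib_d <- first_on / 86400
    row$hib_d <- (last_off - first_on) / 86400
    row$posthib_d <- (span_s - last_off) / 86400
  } else {
    row$prehib_d <- row$hib_d <- row$posthib_d <- NA_real_
  }
  row$span_d <- span_s / 86400
  row
}

#' Build the cohort phenotype table
#'
#' Joins per-individual phenotypes with the cohort covariate table on
#' `individual_id`. Every phenotype must match exactly one cohort row and
#' vice versa; unmatched ids on either side raise an error listing them.
#'
#' @param phenotypes Data frame of rows from [summarize_individual()]
#'   (rbind-ed), one per individual.
#' @param cohort Validated cohort table from [read_cohort()].
#' @return The joined data frame, one row per individual, in cohort order.
#' @export
summarize_cohort <- function(phenotypes, cohort) {
  miss_tr <- setdiff(cohort$individual_id, phenotypes$individual_id)
  if (length(miss_tr))
    stop("cohort row(s) without a trace/phenotype: ",
         paste(miss_tr, collapse = ", "), call. = FALSE)
  miss_co <- setdiff(phenotypes$individual_id, cohort$individual_id)
  if (length(miss_co))
    stop("phenotype(s) without a cohort row: ",
         paste(miss_co, collapse = ", "), call. = FALSE)
  out <- merge(cohort, phenotypes, by = "individual_id", sort = FALSE)
  out[match(cohort$individual_id, out$individual_id), , drop = FALSE]
}

#' Group means and standard errors of phenotype metrics
#'
#' Produces the report shape used for group comparisons: per group and
#' metric, the mean, standard error (sd / sqrt(n)) and n, where n counts
#' the individuals contributing a non-missing value — so bout-temperature
#' means are averaged over the individuals that expressed the respective
#' bout type, while counts and totals include all individuals.
#'
#' @param cohort_phenotypes Joined table from [summarize_cohort()].
#' @param metrics Character vector of numeric columns to summarize.
#'   Defaults to all phenotype metrics.
#' @return A data frame with columns `metric`, `group`, `mean`, `se`, `n`.
#' @export
phenotype_group_summary <- function(cohort_phenotypes,
                                    metrics = NULL) {
  if (is.null(metrics)) {
    metrics <- c(as.vector(outer(.PHENO_CATEGORIES, .PHENO_METRICS,
                                 paste, sep = "_")),
                 "prehib_d", "hib_d", "posthib_d")
    metrics <- intersect(metrics, names(cohort_phenotypes))
  }
  rows <- list()
  for (m in metrics) {
    for (g in levels(cohort_phenotypes$group)) {
      v <- cohort_phenotypes[[m]][cohort_phenotypes$group == g]
      v <- v[!is.na(v)]
      n <- length(v)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = m, group = g,
        mean = if (n) mean(v) else NA_real_,
        se = if (n > 1L) sd(v) / sqrt(n) else NA_real_,
        n = n, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
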