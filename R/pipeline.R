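# Glue between the pipeline stages: building phenotype tables from traces,
# reshaping PUFA measurements, and assembling the inputs of the PUFA-change
# models.

#' Segment and phenotype a set of traces
#'
#' Runs [detect_bouts()] and [summarize_individual()] over a list of traces.
#'
#' @param traces Named list of [tb_trace()] objects.
#' @param params A [segmentation_params()].
#' @param ... Passed to [detect_bouts()] (gap policy, mean convention).
#' @return List with `bouts` (all bouts, one table) and `phenotypes` (one
#'   row per individual).
#' @export
phenotype_traces <- function(traces, params = segmentation_params(), ...) {
  bouts <- lapply(traces, detect_bouts, params = params, ...)
  phenotypes <- do.call(rbind, Map(summarize_individual, bouts, traces))
  rownames(phenotypes) <- NULL
  list(bouts = do.call(rbind, c(bouts, list(make.row.names = FALSE))),
       phenotypes = phenotypes)
}

#' Reshape a cohort table into the long PUFA table
#'
#' @param cohort Cohort table with `pufa_pre_pct` / `pufa_post_pct`.
#' @return Long data frame with columns `individual_id`, `group`, `time`
#'   (`"pre"`/`"post"`), `pufa_pct` — the input of [fit_pufa_lme()].
#'   Missing measurements are kept as `NA` rows.
#' @export
pufa_long <- function(cohort) {
  long <- rbind(
    data.frame(individual_id = cohort$individual_id, group = cohort$group,
               time = "pre", pufa_pct = cohort$pufa_pre_pct,
               stringsAsFactors = FALSE),
    data.frame(individual_id = cohort$individual_id, group = cohort$group,
               time = "post", pufa_pct = cohort$pufa_post_pct,
               stringsAsFactors = FALSE))
  long$time <- factor(long$time, levels = c("pre", "post"))
  long[order(long$individual_id), , drop = FALSE]
}

#' Assemble the PUFA-change table
#'
#' One row per individual with the winter PUFA change (post minus pre, in
#' percentage points, so declines are negative) alongside the hibernation
#' predictors: total deep and shallow torpor (days), per-category mean of
#' per-bout minimum Tb (missing for individuals lacking the category), seed
#' intake, and group. Rows lacking either PUFA measurement get a missing
#' change and are dropped by the model fits.
#'
#' @param x Either a joined phenotype-covariate table from
#'   [summarize_cohort()], or a `hib_simulation` (then the ground-truth
#'   quantities are used — no segmentation involved).
#' @return Data frame with columns `individual_id`, `group`,
#'   `pufa_change_pct_points`, `deep_total_d`, `shallow_total_d`,
#'   `deep_min_tb`, `shallow_min_tb`, `seeds_intake_g`.
#' @export
pufa_change_table <- function(x) {
  if (inherits(x, "hib_simulation")) {
    truth <- x$ground_truth$individuals
    co <- x$cohort
    stopifnot(identical(truth$individual_id, co$individual_id))
    return(data.frame(
      individual_id = truth$individual_id, group = truth$group,
      pufa_change_pct_points = co$pufa_post_pct - co$pufa_pre_pct,
      deep_total_d = truth$deep_total_d,
      shallow_total_d = truth$shallow_total_d,
      deep_min_tb = truth$deep_min_tb,
      shallow_min_tb = truth$shallow_min_tb,
      seeds_intake_g = truth$seeds_intake_g,
      stringsAsFactors = FALSE))
  }
  data.frame(
    individual_id = x$individual_id, group = x$group,
    pufa_change_pct_points = x$pufa_post_pct - x$pufa_pre_pct,
    deep_total_d = x$deep_total_d,
    shallow_total_d = x$shallow_total_d,
    deep_min_tb = x$deep_min_tb,
    shallow_min_tb = x$shallow_min_tb,
    seeds_intake_g = x$seeds_provided_g - x$seeds_remaining_g,
    stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline on traces and a cohort table
#'
#' Segmentation, phenotyping, covariate join, food budgets, and the PUFA
#' tables — everything downstream model fits need.
#'
#' @param traces Named list of [tb_trace()]s.
#' @param cohort Validated cohort table ([read_cohort()]).
#' @param params A [segmentation_params()].
#' @param comps Food compositions ([read_compositions()]).
#' @param ... Passed to [detect_bouts()].
#' @return List: `bouts`, `phenotypes`, `cohort_phenotypes` (joined),
#'   `budget`, `group_summary`, `pufa_long`, `pufa_change`.
#' @export
run_pipeline <- function(traces, cohort, params = segmentation_params(),
                         comps = read_compositions(), ...) {
  ph <- phenotype_traces(traces, params, ...)
  joined <- summarize_cohort(ph$phenotypes, cohort)
  list(bouts = ph$bouts,
       phenotypes = ph$phenotypes,
       cohort_phenotypes = joined,
       budget = budget_table(cohort, comps),
       group_summary = phenotype_group_summary(joined),
       pufa_long = pufa_long(cohort),
       pufa_change = pufa_change_table(joined))
}
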