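# The statistical model suite: bout-level linear mixed models, individual-
# level linear models, the paired PUFA mixed model with post-hoc interaction
# contrasts, and AICc-reduced PUFA-change models. Type III tests are always
# computed under sum-to-zero factor coding, so results do not depend on
# factor level order. Mixed models are fitted by REML via nlme.

# control-first level order when the standard group labels are used;
# otherwise first appearance order is kept
as_group_factor <- function(x) {
  x <- droplevels(factor(x))
  if (setequal(levels(x), c("control", "HF")))
    x <- factor(x, levels = c("control", "HF"))
  x
}

# Type III is ill-defined under treatment coding; force sum-to-zero locally.
with_sum_contrasts <- function(expr) {
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  force(expr)
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = AIC + 2k(k+1)/(n - k - 1)` with `k` the number of estimated
#' parameters (including the residual variance) and `n` the number of
#' observations. Undefined when `n - k - 1 <= 0`.
#'
#' @param fit A fitted model with `logLik()` and `nobs()` methods.
#' @return The AICc value.
#' @export
aicc <- function(fit) {
  ll <- logLik(fit)
  k <- attr(ll, "df")
  n <- stats::nobs(fit)
  if (n - k - 1 <= 0)
    stop("AICc undefined: n - k - 1 <= 0 (n = ", n, ", k = ", k, ")",
         call. = FALSE)
  AIC(fit) + 2 * k * (k + 1) / (n - k - 1)
}

coef_table <- function(fit) {
  if (inherits(fit, "lme")) {
    tt <- summary(fit)$tTable
    data.frame(term = rownames(tt), estimate = tt[, "Value"],
               se = tt[, "Std.Error"], df = tt[, "DF"],
               t_value = tt[, "t-value"], p_value = tt[, "p-value"],
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    sm <- summary(fit)$coefficients
    data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
               df = fit$df.residual, t_value = sm[, 3], p_value = sm[, 4],
               row.names = NULL, stringsAsFactors = FALSE)
  }
}

anova3_table <- function(fit) {
  if (inherits(fit, "lme")) {
    # marginal (Type III) conditional F-tests with group-level
    # denominator df — well calibrated for between-individual factors
    a <- anova(fit, type = "marginal")
    data.frame(term = rownames(a), statistic = a[, "F-value"],
               stat_type = "F", df = a[, "numDF"], den_df = a[, "denDF"],
               p_value = a[, "p-value"], row.names = NULL,
               stringsAsFactors = FALSE)
  } else {
    a <- car::Anova(fit, type = 3)
    keep <- !rownames(a) %in% "Residuals"
    data.frame(term = rownames(a)[keep], statistic = a[keep, "F value"],
               stat_type = "F", df = a[keep, "Df"],
               den_df = fit$df.residual, p_value = a[keep, "Pr(>F)"],
               row.names = NULL, stringsAsFactors = FALSE)
  }
}

model_diagnostics <- function(fit, data, group_col = "group") {
  res <- residuals(fit)
  shapiro_p <- if (length(res) >= 3 && length(res) <= 5000 &&
                   sd(res) > 0) shapiro.test(res)$p.value else NA_real_
  levene_p <- NA_real_
  if (!is.null(group_col) && group_col %in% names(data)) {
    g <- droplevels(factor(data[[group_col]]))
    if (nlevels(g) >= 2 && length(res) == length(g) && sd(res) > 0) {
      lt <- car::leveneTest(res ~ g)
      levene_p <- lt[1, "Pr(>F)"]
    }
  }
  list(shapiro_p = shapiro_p, levene_p = levene_p)
}

new_model_result <- function(model_id, response, fit, data,
                             group_col = "group", singular = FALSE,
                             extra = list()) {
  n_groups <- if (inherits(fit, "lme"))
    length(unique(fit$groups[[1]])) else NA_integer_
  res <- list(model_id = model_id,
              response = response,
              fit = fit,
              coefficients = coef_table(fit),
              anova_type3 = anova3_table(fit),
              random = if (inherits(fit, "lme")) {
                vc <- nlme::VarCorr(fit)
                data.frame(term = rownames(vc),
                           variance = suppressWarnings(
                             as.numeric(vc[, "Variance"])),
                           sd = suppressWarnings(as.numeric(vc[, "StdDev"])),
                           stringsAsFactors = FALSE)
              } else NULL,
              n_obs = stats::nobs(fit),
              n_groups = n_groups,
              aicc = tryCatch(aicc(fit), error = function(e) NA_real_),
              diagnostics = model_diagnostics(fit, data, group_col),
              singular = singular)
  res <- c(res, extra)
  class(res) <- "hib_model_result"
  res
}

#' @export
print.hib_model_result <- function(x, ...) {
  cat(sprintf("<hib_model_result> %s: %s (n_obs = %d%s)\n", x$model_id,
              x$response, x$n_obs,
              if (!is.na(x$n_groups)) sprintf(", n_individuals = %d",
                                              x$n_groups) else ""))
  if (isTRUE(x$singular))
    cat("  ! singular fit: between-individual variance ~ 0\n")
  cat("  Type III tests:\n")
  a <- x$anova_type3
  for (i in seq_len(nrow(a)))
    cat(sprintf("    %-28s %s(%g%s) = %8.3f  p = %.4g\n", a$term[i],
                a$stat_type[i], a$df[i],
                if (!is.na(a$den_df[i])) sprintf(", %g", a$den_df[i]) else "",
                a$statistic[i], a$p_value[i]))
  if (!is.na(x$aicc)) cat(sprintf("  AICc = %.2f\n", x$aicc))
  invisible(x)
}

#' Bout-level linear mixed model for a group comparison
#'
#' Compares a per-bout response (bout duration, minimum Tb, or mean Tb)
#' between experimental groups with a random intercept per individual to
#' correct for repeated measurements. Fitted by REML; the group effect is
#' tested with a Type III (marginal) F-test under sum-to-zero coding.
#'
#' A fit whose between-individual standard deviation collapses to ~0 is
#' flagged `singular` in the result, not dropped.
#'
#' @param bouts Bout table (rows = bouts) carrying `individual_id`, a group
#'   factor column, and the response column. Typically [detect_bouts()]
#'   output joined with the cohort `group` and filtered to one bout
#'   category.
#' @param response Name of the response column (e.g. `"duration_h"`,
#'   `"min_tb"`, `"mean_tb"`).
#' @param group_col Name of the grouping factor column (default `"group"`).
#' @param covariates Optional character vector of additional fixed-effect
#'   columns (e.g. `"mass_pre_g"`).
#' @return A `hib_model_result`.
#' @export
fit_bout_level_lme <- function(bouts, response, group_col = "group",
                               covariates = character()) {
  data <- bouts[, c("individual_id", group_col, covariates, response)]
  data <- data[complete.cases(data), , drop = FALSE]
  data[[group_col]] <- as_group_factor(data[[group_col]])
  per_group <- tapply(data$individual_id, data[[group_col]],
                      function(id) length(unique(id)))
  if (any(is.na(per_group)) || any(per_group < 2))
    stop("need >= 2 individuals with bouts in every group", call. = FALSE)
  fml <- as.formula(paste(response, "~",
                          paste(c(group_col, covariates), collapse = " + ")))
  fit <- with_sum_contrasts(
    nlme::lme(fixed = fml, random = ~ 1 | individual_id, data = data,
              method = "REML"))
  vc <- nlme::VarCorr(fit)
  sd_ind <- suppressWarnings(as.numeric(vc["(Intercept)", "StdDev"]))
  sd_res <- suppressWarnings(as.numeric(vc["Residual", "StdDev"]))
  singular <- is.finite(sd_ind) && is.finite(sd_res) &&
    sd_ind < 1e-4 * max(sd_res, 1e-12)
  new_model_result(paste0("lme_bout_", response), response, fit, data,
                   group_col, singular = singular)
}

#' Individual-level linear model with Type III tests
#'
#' Ordinary linear model for per-individual responses (bout counts, total
#' durations, phenology, PUFA change, ...) on arbitrary predictors,
#' reported with coefficient t-values and a Type III ANOVA table under
#' sum-to-zero coding. This covers the group comparisons corrected for
#' pre-hibernation body mass as well as any single-predictor model.
#'
#' @param data One row per individual.
#' @param response Response column name.
#' @param predictors Character vector of predictor column names
#'   (default `c("group", "mass_pre_g")`).
#' @param model_id Optional identifier for the report.
#' @return A `hib_model_result`.
#' @export
fit_count_total_lm <- function(data, response,
                               predictors = c("group", "mass_pre_g"),
                               model_id = NULL) {
  df <- data[, c(response, predictors), drop = FALSE]
  df <- df[complete.cases(df), , drop = FALSE]
  for (p in predictors)
    if (is.character(df[[p]]) || is.factor(df[[p]]))
      df[[p]] <- as_group_factor(df[[p]])
  check_full_rank(df, predictors)
  fml <- as.formula(paste(response, "~", paste(predictors, collapse = " + ")))
  fit <- with_sum_contrasts(lm(fml, data = df))
  group_col <- predictors[vapply(predictors, function(p)
    is.factor(df[[p]]), logical(1))][1]
  if (is.na(group_col)) group_col <- NULL
  new_model_result(model_id %||% paste0("lm_", response), response, fit, df,
                   group_col)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_full_rank <- function(df, predictors) {
  for (p in predictors) {
    v <- df[[p]]
    if ((is.numeric(v) && var(v) == 0) ||
        (is.factor(v) && nlevels(v) < 2))
      stop("predictor '", p, "' is constant: design is rank-deficient",
           call. = FALSE)
  }
  X <- model.matrix(as.formula(paste("~", paste(predictors, collapse = "+"))),
                    df)
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient design: predictors are collinear", call. = FALSE)
  invisible(TRUE)
}

#' Food-intake linear model (per-group hibernation-performance regression)
#'
#' Regresses a hibernation parameter on food intake and pre-hibernation
#' body mass within one experimental group. For the high-fat group pass
#' both `pellets_intake_g` and `seeds_intake_g` as predictors; for the
#' control group omit the seeds term. Coefficient t-values are the report
#' quantity.
#'
#' @param data One row per individual of a single group, carrying the
#'   response, `mass_pre_g`, and the intake columns.
#' @param response Response column name.
#' @param predictors Predictor column names, default
#'   `c("mass_pre_g", "pellets_intake_g", "seeds_intake_g")`.
#' @return A `hib_model_result`.
#' @export
fit_intake_lm <- function(data, response,
                          predictors = c("mass_pre_g", "pellets_intake_g",
                                         "seeds_intake_g")) {
  fit_count_total_lm(data, response, predictors,
                     model_id = paste0("lm_intake_", response))
}

#' Paired PUFA mixed model with post-hoc interaction contrasts
#'
#' Models white-adipose-tissue PUFA proportions with sampling time
#' (pre/post experiment), group, and their interaction as fixed effects and
#' a random intercept per individual. Type III (marginal) F-tests are
#' reported; the interaction is dissected with four Wald chi-square
#' contrasts on the model's cell means:
#' group difference at pre, pre-to-post change within each group, and
#' group difference at post. Contrast p-values are raw by default
#' (`adjust = "none"`), matching common reporting practice; set `adjust`
#' to any [p.adjust()] method for a multiplicity correction.
#'
#' @param pufa_long Long table with two rows per individual: columns
#'   `individual_id`, `group`, `time` (`"pre"`/`"post"`), `pufa_pct`.
#' @param require_paired Drop individuals lacking either measurement
#'   (default `TRUE`).
#' @param adjust Multiplicity correction for the contrasts, a
#'   [stats::p.adjust()] method name; default `"none"`.
#' @return A `hib_model_result` with an extra `contrasts` data frame:
#'   `contrast`, `estimate`, `se`, `chisq`, `df`, `p_value`.
#' @export
fit_pufa_lme <- function(pufa_long, require_paired = TRUE,
                         adjust = "none") {
  df <- pufa_long[, c("individual_id", "group", "time", "pufa_pct")]
  df <- df[complete.cases(df), , drop = FALSE]
  df$group <- as_group_factor(df$group)
  df$time <- factor(df$time, levels = c("pre", "post"))
  if (require_paired) {
    counts <- table(df$individual_id)
    keep <- names(counts)[counts == 2L]
    df <- df[df$individual_id %in% keep, , drop = FALSE]
  }
  if (nlevels(df$group) < 2)
    stop("need both groups represented", call. = FALSE)
  fit <- with_sum_contrasts(
    nlme::lme(pufa_pct ~ time * group, random = ~ 1 | individual_id,
              data = df, method = "REML"))

  cells <- expand.grid(time = levels(df$time), group = levels(df$group),
                       KEEP.OUT.ATTRS = FALSE)
  X <- model.matrix(stats::delete.response(terms(fit)), cells,
                    contrasts.arg = fit$contrasts)
  # rows: pre-control, post-control, pre-HF, post-HF (grid order)
  cell_id <- paste(cells$group, cells$time, sep = ".")
  L <- rbind(
    "group_at_pre"  = (cell_id == paste0(levels(df$group)[1], ".pre")) -
                      (cell_id == paste0(levels(df$group)[2], ".pre")),
    "pre_post_in_g1" = (cell_id == paste0(levels(df$group)[1], ".pre")) -
                       (cell_id == paste0(levels(df$group)[1], ".post")),
    "pre_post_in_g2" = (cell_id == paste0(levels(df$group)[2], ".pre")) -
                       (cell_id == paste0(levels(df$group)[2], ".post")),
    "group_at_post" = (cell_id == paste0(levels(df$group)[1], ".post")) -
                      (cell_id == paste0(levels(df$group)[2], ".post")))
  rownames(L) <- c(
    sprintf("%s - %s | pre", levels(df$group)[1], levels(df$group)[2]),
    sprintf("pre - post | %s", levels(df$group)[1]),
    sprintf("pre - post | %s", levels(df$group)[2]),
    sprintf("%s - %s | post", levels(df$group)[1], levels(df$group)[2]))
  C <- L %*% X                      # contrasts in fixed-effect space
  beta <- nlme::fixef(fit)
  V <- vcov(fit)
  est <- as.numeric(C %*% beta)
  se <- sqrt(diag(C %*% V %*% t(C)))
  chisq <- (est / se)^2
  p <- pchisq(chisq, df = 1, lower.tail = FALSE)
  p <- stats::p.adjust(p, method = adjust)
  contrasts <- data.frame(contrast = rownames(L), estimate = est, se = se,
                          chisq = chisq, df = 1L, p_value = p,
                          row.names = NULL, stringsAsFactors = FALSE)
  new_model_result("lme_pufa", "pufa_pct", fit, df, "group",
                   extra = list(contrasts = contrasts))
}

#' Backward AICc reduction of a linear model
#'
#' Starting from the full predictor set, repeatedly removes the single
#' predictor whose removal most decreases AICc, until no removal decreases
#' it (predictors listed in `keep` are never removed). All candidate models
#' are fitted to the same rows.
#'
#' @param data One row per observation, complete for all predictors.
#' @param response Response column name.
#' @param predictors Full predictor set.
#' @param keep Predictors exempt from removal.
#' @return List with `predictors` (the selected set) and `trace`
#'   (data frame of steps: dropped term and AICc before/after).
#' @export
reduce_by_aicc <- function(data, response, predictors, keep = character()) {
  df <- data[, c(response, predictors), drop = FALSE]
  df <- df[complete.cases(df), , drop = FALSE]
  fit_set <- function(preds) {
    fml <- if (length(preds))
      paste(response, "~", paste(preds, collapse = " + "))
    else paste(response, "~ 1")
    with_sum_contrasts(lm(as.formula(fml), data = df))
  }
  # a model too rich for its sample (n - k - 1 <= 0) scores +Inf, so the
  # reduction is forced away from it
  aicc_or_inf <- function(fit)
    tryCatch(aicc(fit), error = function(e) Inf)
  current <- predictors
  trace <- list()
  repeat {
    base_aicc <- aicc_or_inf(fit_set(current))
    droppable <- setdiff(current, keep)
    if (!length(droppable)) break
    cand <- vapply(droppable, function(p)
      aicc_or_inf(fit_set(setdiff(current, p))), numeric(1))
    best <- which.min(cand)
    if (cand[best] >= base_aicc) break
    trace[[length(trace) + 1L]] <- data.frame(
      dropped = droppable[best], aicc_before = base_aicc,
      aicc_after = cand[best], stringsAsFactors = FALSE)
    current <- setdiff(current, droppable[best])
  }
  list(predictors = current,
       trace = if (length(trace)) do.call(rbind, trace)
               else data.frame(dropped = character(),
                               aicc_before = numeric(),
                               aicc_after = numeric()))
}

#' PUFA-change models on hibernation performance
#'
#' Two linear models for the winter change in WAT PUFA proportions
#' (post minus pre, percentage points, so declines are negative):
#'
#' * **all-individuals model** — predictors: total deep-torpor duration,
#'   total shallow-torpor duration, and group;
#' * **hibernators model** — adds minimum Tb during deep and shallow
#'   torpor (defined only for hibernators, which restricts the rows), then
#'   reduces the predictor set by backward AICc (group and the two
#'   durations are retained as design variables; the minimum-Tb terms are
#'   the reduction candidates).
#'
#' @param change_table One row per individual with columns
#'   `pufa_change_pct_points`, `deep_total_d`, `shallow_total_d`, `group`,
#'   and for hibernators `deep_min_tb` (and optionally `shallow_min_tb`).
#' @return List of class `pufa_change_models`: `model_all` and
#'   `model_hibernators` (`hib_model_result`s) and `selection` (the AICc
#'   reduction trace).
#' @export
fit_pufa_change_models <- function(change_table) {
  m_all <- fit_count_total_lm(
    change_table, "pufa_change_pct_points",
    predictors = c("deep_total_d", "shallow_total_d", "group"),
    model_id = "lm_pufa_change_all")

  hib <- change_table[!is.na(change_table$deep_min_tb), , drop = FALSE]
  full <- c("deep_total_d", "shallow_total_d", "deep_min_tb", "group")
  if ("shallow_min_tb" %in% names(change_table))
    full <- c("deep_total_d", "shallow_total_d", "deep_min_tb",
              "shallow_min_tb", "group")
  # the hibernators model needs enough deep-torpor animals, in both
  # groups, to carry its predictors; otherwise it is reported as absent
  fit_hib <- function() {
    sel <- reduce_by_aicc(hib, "pufa_change_pct_points", full,
                          keep = c("deep_total_d", "shallow_total_d",
                                   "deep_min_tb", "group"))
    m <- fit_count_total_lm(hib, "pufa_change_pct_points",
                            predictors = sel$predictors,
                            model_id = "lm_pufa_change_hibernators")
    list(model = m, selection = sel$trace, note = NA_character_)
  }
  hb <- tryCatch(fit_hib(), error = function(e)
    list(model = NULL,
         selection = data.frame(dropped = character(),
                                aicc_before = numeric(),
                                aicc_after = numeric()),
         note = paste("hibernators model not estimable:",
                      conditionMessage(e))))
  structure(list(model_all = m_all, model_hibernators = hb$model,
                 selection = hb$selection, note = hb$note),
            class = "pufa_change_models")
}

#' Classical two-sample tests and diagnostics
#'
#' Bundles the simple tests used around the model suite: equal-variance
#' Student's t (not Welch), Pearson correlation, per-sample Shapiro-Wilk
#' normality tests, and a Levene test for homoscedasticity between the two
#' samples.
#'
#' @param x,y Numeric samples with at least 3 observations each.
#' @param paired Paired t-test instead of two-sample (default `FALSE`).
#' @return List with elements `t` (htest), `pearson` (htest, only when
#'   `length(x) == length(y)`), `shapiro_x`, `shapiro_y`, `levene_p`.
#' @export
simple_tests <- function(x, y, paired = FALSE) {
  if (length(x) < 3 || length(y) < 3)
    stop("need at least 3 observations per sample", call. = FALSE)
  lev <- car::leveneTest(c(x, y) ~ factor(rep(c("x", "y"),
                                              c(length(x), length(y)))))
  list(t = t.test(x, y, var.equal = TRUE, paired = paired),
       pearson = if (length(x) == length(y)) cor.test(x, y) else NULL,
       shapiro_x = if (sd(x) > 0) shapiro.test(x) else NULL,
       shapiro_y = if (sd(y) > 0) shapiro.test(y) else NULL,
       levene_p = lev[1, "Pr(>F)"])
}

#' Write a model report as JSON and TSV
#'
#' Serializes a `hib_model_result` (terms, estimates, Type III statistics,
#' contrasts if present, AICc, diagnostics) to `<dir>/<model_id>.json`
#' (machine-readable) and `<dir>/<model_id>.tsv` (one row per coefficient).
#'
#' @param result A `hib_model_result`.
#' @param dir Output directory (created if needed).
#' @return Paths of the files written, invisibly.
#' @export
write_model_report <- function(result, dir) {
  stopifnot(inherits(result, "hib_model_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  payload <- list(model_id = result$model_id, response = result$response,
                  n_obs = result$n_obs, n_groups = result$n_groups,
                  aicc = result$aicc, singular = result$singular,
                  coefficients = result$coefficients,
                  anova_type3 = result$anova_type3,
                  random = result$random,
                  contrasts = result$contrasts,
                  diagnostics = result$diagnostics)
  json_path <- file.path(dir, paste0(result$model_id, ".json"))
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "rows")
  tsv_path <- file.path(dir, paste0(result$model_id, ".tsv"))
  write.table(result$coefficients, tsv_path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(c(json_path, tsv_path))
}
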