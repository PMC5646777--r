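test_that("AICc matches its defining formula and refuses tiny samples", {
  set.seed(1)
  d <- data.frame(y = rnorm(20), x = rnorm(20))
  fit <- lm(y ~ x, d)
  k <- attr(logLik(fit), "df")           # slope, intercept, sigma
  expect_equal(k, 3)
  expect_equal(aicc(fit), AIC(fit) + 2 * k * (k + 1) / (20 - k - 1))

  tiny <- lm(y ~ x, d[1:4, ])            # n - k - 1 = 0
  expect_error(aicc(tiny), "undefined")
})

test_that("linear model coefficients match hand-solved normal equations", {
  d <- data.frame(y = c(1, 3, 2, 5), x = c(0, 1, 2, 3))
  r <- fit_count_total_lm(d, "y", predictors = "x")
  X <- cbind(1, d$x)
  beta <- solve(t(X) %*% X, t(X) %*% d$y)
  expect_equal(unname(r$coefficients$estimate), as.vector(beta),
               tolerance = 1e-12)
})

test_that("a response linear in mass with no group signal splits cleanly", {
  set.seed(12)
  d <- data.frame(group = factor(rep(c("control", "HF"), each = 10)),
                  mass_pre_g = runif(20, 250, 400))
  d$y <- 2 + 0.05 * d$mass_pre_g + rnorm(20, 0, 1e-4)
  r <- fit_count_total_lm(d, "y")
  co <- r$coefficients
  expect_gt(abs(co$t_value[co$term == "mass_pre_g"]), 1e4)
  a <- r$anova_type3
  expect_gt(a$p_value[a$term == "group"], 0.05)
})

test_that("balanced bout-level mixed model reproduces group means", {
  set.seed(77)
  m <- 6
  ind <- sprintf("i%d", 1:8)
  mu_i <- rnorm(8, c(rep(10, 4), rep(14, 4)), 1)
  d <- data.frame(individual_id = rep(ind, each = m),
                  group = factor(rep(c("control", "HF"), each = 4 * m),
                                 levels = c("control", "HF")),
                  y = rnorm(8 * m, rep(mu_i, each = m), 0.5))
  r <- fit_bout_level_lme(d, "y")
  pred <- predict(r$fit, newdata = data.frame(group = c("control", "HF")),
                  level = 0)
  obs <- tapply(d$y, d$group, mean)   # balanced: raw means are cell means
  expect_equal(unname(as.vector(pred)),
               unname(as.vector(obs[c("control", "HF")])),
               tolerance = 1e-8)
  expect_false(r$singular)
  expect_identical(r$n_groups, 8L)
})

test_that("a constant response gives a null group effect, flagged singular", {
  d <- data.frame(individual_id = rep(sprintf("i%d", 1:6), each = 4),
                  group = factor(rep(c("control", "HF"), each = 12)),
                  y = 5)
  r <- fit_bout_level_lme(d, "y")
  expect_true(r$singular)
  a <- r$anova_type3
  expect_lt(a$statistic[a$term == "group"], 1e-8)
  co <- r$coefficients
  expect_lt(abs(co$estimate[grepl("group", co$term)]), 1e-10)
  # too few individuals per group is a contract violation
  expect_error(fit_bout_level_lme(d[d$individual_id %in%
                                      c("i1", "i2", "i4"), ], "y"),
               ">= 2 individuals")
})

test_that("Type III results are invariant to factor level order", {
  set.seed(41)
  d <- data.frame(group = factor(rep(c("control", "HF"), c(8, 12))),
                  mass_pre_g = runif(20, 250, 400))
  d$y <- 5 + 2 * (d$group == "HF") + 0.01 * d$mass_pre_g + rnorm(20)
  r1 <- fit_count_total_lm(d, "y")
  d2 <- d
  d2$group <- factor(d2$group, levels = c("HF", "control"))
  r2 <- fit_count_total_lm(d2, "y")
  expect_equal(r1$anova_type3$statistic, r2$anova_type3$statistic,
               tolerance = 1e-10)
  expect_equal(r1$anova_type3$p_value, r2$anova_type3$p_value,
               tolerance = 1e-10)
  # and deterministic across repeated fits
  r3 <- fit_count_total_lm(d, "y")
  expect_identical(r1$anova_type3$p_value, r3$anova_type3$p_value)
})

test_that("intake models recover known coefficients and reject rank loss", {
  set.seed(19)
  n <- 30
  d <- data.frame(mass_pre_g = rnorm(n, 317, 30),
                  pellets_intake_g = rnorm(n, 1400, 100),
                  seeds_intake_g = rnorm(n, 300, 80))
  d$y <- 1 + 0.02 * d$mass_pre_g - 0.005 * d$pellets_intake_g +
    0.03 * d$seeds_intake_g + rnorm(n, 0, 1e-4)
  r <- fit_intake_lm(d, "y")
  est <- setNames(r$coefficients$estimate, r$coefficients$term)
  expect_lt(abs(est["mass_pre_g"] - 0.02), 1e-6)
  expect_lt(abs(est["pellets_intake_g"] + 0.005), 1e-6)
  expect_lt(abs(est["seeds_intake_g"] - 0.03), 1e-6)

  d$seeds_intake_g <- 0
  expect_error(fit_intake_lm(d, "y"), "rank-deficient")
})

test_that("pufa interaction contrasts equal cell-mean differences", {
  set.seed(23)
  n <- 8
  ids <- sprintf("i%d", 1:(2 * n))
  grp <- rep(c("control", "HF"), each = n)
  cell <- c(pre_control = 35, post_control = 28, pre_HF = 34.5,
            post_HF = 33)
  d <- rbind(
    data.frame(individual_id = ids, group = grp, time = "pre",
               pufa_pct = cell[paste0("pre_", grp)] + rnorm(2 * n, 0, 0.8)),
    data.frame(individual_id = ids, group = grp, time = "post",
               pufa_pct = cell[paste0("post_", grp)] + rnorm(2 * n, 0, 0.8)))
  r <- fit_pufa_lme(d)
  obs <- tapply(d$pufa_pct, list(d$group, factor(d$time,
                                                 c("pre", "post"))), mean)
  ct <- setNames(r$contrasts$estimate, r$contrasts$contrast)
  # balanced design: fitted cell means equal observed cell means
  expect_equal(unname(ct["control - HF | pre"]),
               obs["control", "pre"] - obs["HF", "pre"], tolerance = 1e-8)
  expect_equal(unname(ct["pre - post | control"]),
               obs["control", "pre"] - obs["control", "post"],
               tolerance = 1e-8)
  expect_equal(unname(ct["pre - post | HF"]),
               obs["HF", "pre"] - obs["HF", "post"], tolerance = 1e-8)
  expect_equal(unname(ct["control - HF | post"]),
               obs["control", "post"] - obs["HF", "post"], tolerance = 1e-8)
  expect_true(all(r$contrasts$df == 1))
})

test_that("identical pre/post measurements give zero change contrasts", {
  set.seed(3)
  ids <- sprintf("i%d", 1:10)
  a <- rnorm(10, 35, 3)
  d <- rbind(
    data.frame(individual_id = ids,
               group = rep(c("control", "HF"), each = 5),
               time = "pre", pufa_pct = a),
    data.frame(individual_id = ids,
               group = rep(c("control", "HF"), each = 5),
               time = "post", pufa_pct = a))
  r <- fit_pufa_lme(d)
  ct <- setNames(r$contrasts$estimate, r$contrasts$contrast)
  expect_lt(abs(ct["pre - post | control"]), 1e-9)
  expect_lt(abs(ct["pre - post | HF"]), 1e-9)
  # with no change anywhere the group gap is the same at both times
  expect_equal(unname(ct["control - HF | pre"]),
               unname(ct["control - HF | post"]), tolerance = 1e-9)
})

test_that("individuals missing a pre measurement are excluded from pairing", {
  sim <- simulate_cohort(simulation_config(seed = 61,
                                           n_missing_pufa_pre = 1L),
                         traces = FALSE)
  pl <- pufa_long(sim$cohort)
  r <- fit_pufa_lme(pl)
  expect_identical(r$n_groups, 21L)
  expect_identical(r$n_obs, 42L)
})

test_that("AICc reduction drops a pure-noise predictor", {
  set.seed(47)
  dropped <- 0
  for (rep in 1:25) {
    n <- 40
    d <- data.frame(group = factor(rep(c("control", "HF"), each = n / 2)),
                    deep_total_d = c(abs(rnorm(n / 2, 10, 4)),
                                     abs(rnorm(n / 2, 12, 4))),
                    shallow_total_d = abs(rnorm(n, 5, 2)),
                    deep_min_tb = rnorm(n, 10, 0.7),
                    shallow_min_tb = rnorm(n, 27, 1.8))
    d$pufa_change_pct_points <- -5 - 0.5 * d$deep_total_d -
      0.3 * d$deep_min_tb + rnorm(n, 0, 1)
    sel <- reduce_by_aicc(d, "pufa_change_pct_points",
                          c("deep_total_d", "shallow_total_d",
                            "deep_min_tb", "shallow_min_tb", "group"),
                          keep = c("deep_total_d", "shallow_total_d",
                                   "deep_min_tb", "group"))
    if (!"shallow_min_tb" %in% sel$predictors) dropped <- dropped + 1
  }
  expect_gte(dropped, 20)
})

test_that("the two pufa-change models carry the designed predictor sets", {
  sim <- simulate_cohort(simulation_config(seed = 29), traces = FALSE)
  ct <- pufa_change_table(sim)
  m <- fit_pufa_change_models(ct)
  a_terms <- m$model_all$anova_type3$term
  expect_true(all(c("deep_total_d", "shallow_total_d", "group") %in%
                    a_terms))
  h_terms <- m$model_hibernators$anova_type3$term
  expect_true(all(c("deep_total_d", "shallow_total_d", "deep_min_tb",
                    "group") %in% h_terms))
  expect_false("shallow_min_tb" %in% h_terms ||
                 nrow(m$selection) == 0)  # candidate was considered
  # hibernators model only uses individuals with deep torpor
  expect_identical(m$model_hibernators$n_obs,
                   as.integer(sum(!is.na(ct$deep_min_tb) &
                                    !is.na(ct$pufa_change_pct_points))))
})

test_that("simple tests match their closed forms", {
  x <- c(3.2, 4.1, 5.0, 4.4, 3.9)
  st <- simple_tests(x, x)
  expect_equal(unname(st$t$statistic), 0)
  expect_equal(st$t$p.value, 1)
  expect_equal(unname(st$pearson$estimate), 1)

  lin <- simple_tests(c(1, 2, 3), c(2, 4, 6))
  expect_equal(unname(lin$pearson$estimate), 1)

  set.seed(8)
  a <- rnorm(5); b <- rnorm(5)
  st2 <- simple_tests(a, b)
  r_oracle <- sum((a - mean(a)) * (b - mean(b))) / ((5 - 1) * sd(a) * sd(b))
  expect_equal(unname(st2$pearson$estimate), r_oracle, tolerance = 1e-12)
  # equal-variance Student's t, not Welch
  expect_equal(unname(st2$t$parameter), 8)
  expect_error(simple_tests(1:2, 1:5), "at least 3")
})
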