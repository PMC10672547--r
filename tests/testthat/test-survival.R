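test_that("Kaplan-Meier matches the hand product-limit computation", {
  km <- km_fit(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(survival_at(km, 2), 0.5)
  # censoring example worked by hand: deaths at 6 (x2) and 10, censor at 7
  km2 <- km_fit(c(6, 6, 7, 10), c(1, 1, 0, 1))
  expect_equal(survival_at(km2, 6), 0.5)
  expect_equal(survival_at(km2, 10), 0)
  expect_equal(survival_at(km2, c(6, 10)),
               km_oracle(c(6, 6, 7, 10), c(1, 1, 0, 1), c(6, 10)))
})

test_that("without censoring the KM estimate equals the empirical survival function", {
  set.seed(21)
  time <- round(stats::rexp(40, 0.05), 1)
  km <- km_fit(time, rep(1, 40))
  at <- sort(unique(time))
  expect_equal(survival_at(km, at),
               vapply(at, function(t) mean(time > t), numeric(1)))
})

test_that("an all-censored cohort keeps survival at 1 with no events", {
  km <- km_fit(c(3, 8, 12), c(0, 0, 0))
  expect_equal(km$n_events, 0)
  expect_equal(survival_at(km, c(0, 5, 20)), c(1, 1, 1))
  expect_true(is.na(km$median))
  expect_error(km_fit(numeric(0), integer(0)), "no observations")
})

test_that("log-rank equals the brute-force risk-table computation on small instances", {
  set.seed(77)
  checked <- 0
  while (checked < 30) {
    n <- sample(6:12, 1)
    k <- sample(2:3, 1)
    time <- sample(1:8, n, replace = TRUE)
    event <- rbinom(n, 1, 0.7)
    group <- sample(letters[1:k], n, replace = TRUE)
    if (length(unique(group)) < k || sum(event) == 0) next
    oracle <- tryCatch(logrank_oracle(time, event, group),
                       error = function(e) NULL)
    if (is.null(oracle) || !is.finite(oracle$statistic)) next
    res <- logrank_test(time, event, group)
    expect_equal(res$statistic, oracle$statistic, tolerance = 1e-8)
    expect_equal(unname(res$observed), unname(oracle$observed))
    expect_equal(sum(res$expected), sum(res$observed), tolerance = 1e-8)
    expect_equal(res$df, k - 1)
    checked <- checked + 1
  }
})

test_that("log-rank is invariant to group relabeling and null for identical groups", {
  time <- c(1, 2, 3, 4, 5, 6, 7, 8)
  event <- c(1, 1, 0, 1, 1, 1, 0, 1)
  g <- rep(c("a", "b"), 4)
  r1 <- logrank_test(time, event, g)
  r2 <- logrank_test(time, event, ifelse(g == "a", "z", "y"))
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-12)
  # two identical groups: duplicate every subject into both arms
  r0 <- logrank_test(rep(time, 2), rep(event, 2),
                     rep(c("a", "b"), each = 8))
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p_value, 1, tolerance = 1e-12)
  expect_error(logrank_test(time, event, rep("a", 8)), "2 non-empty")
  expect_error(logrank_test(time, rep(0, 8), g), "at least one event")
})

test_that("Student's t-test matches the pooled-variance closed form", {
  a <- c(4.1, 5.2, 6.3, 5.8)
  b <- c(7.4, 8.1, 6.9)
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  res <- t_test_groups(a, b)
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$p_value,
               2 * stats::pt(-abs(t_hand), length(a) + length(b) - 2),
               tolerance = 1e-12)
  # identical groups and separated groups
  expect_equal(t_test_groups(a, a)$statistic, 0)
  expect_equal(t_test_groups(a, a)$p_value, 1, tolerance = 1e-12)
  shifted <- t_test_groups(c(1, 2, 3), c(11, 12, 13))
  expect_lt(shifted$p_value, 0.001)
  expect_equal(t_test_groups(c(2, 2), c(2, 2))$p_value, 1)
  expect_error(t_test_groups(1, c(1, 2)), "at least 2")
  welch <- t_test_groups(a, b, welch = TRUE)
  expect_false(isTRUE(all.equal(welch$df, res$df)))
})

test_that("Cox coefficient matches grid-search maximization of the hand-written partial likelihood", {
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 0, 1, 1, 0, 1)
  x <- c(1, 1, 0, 0, 1, 0)
  coh <- data.frame(x = x, time_to_recurrence = time,
                    recurrence_event = event,
                    time_to_death = time, death_event = event)
  fit <- cox_fit(coh, "x", outcome = "recurrence")
  beta_grid <- cox_grid_oracle(time, event, x)
  expect_lt(abs(fit$coefficients$coef - beta_grid), 1e-4)
  # fitted score (numerical gradient of the hand-written likelihood) ~ 0
  h <- 1e-5
  grad <- (cox_partial_loglik_oracle(fit$coefficients$coef + h, time, event, x) -
           cox_partial_loglik_oracle(fit$coefficients$coef - h, time, event, x)) / (2 * h)
  expect_lt(abs(grad), 1e-6)
  # log partial likelihood did not decrease from the null model
  expect_gte(fit$loglik[2], fit$loglik[1])
})

test_that("constant covariates report coefficient 0 and HR 1 with a flag", {
  coh <- generate_cohort(cohort_params(n = 60, seed = 31))
  coh$zero <- 0
  fit <- cox_fit(coh, c("zero", "Vt"), outcome = "recurrence")
  row <- fit$coefficients[fit$coefficients$term == "zero", ]
  expect_equal(row$coef, 0)
  expect_equal(row$hr, 1)
  expect_true(any(grepl("constant covariate", fit$flags)))
})

test_that("perfect separation is flagged rather than silently reported", {
  coh <- data.frame(
    x = c(1, 1, 1, 0, 0, 0),
    time_to_recurrence = c(1, 2, 3, 10, 11, 12),
    recurrence_event = c(1, 1, 1, 0, 0, 0),
    time_to_death = c(1, 2, 3, 10, 11, 12),
    death_event = c(1, 1, 1, 0, 0, 0))
  fit <- cox_fit(coh, "x", outcome = "recurrence")
  expect_false(fit$converged)
  expect_true(length(fit$flags) > 0)
})

test_that("two-group log-rank and univariate Cox agree in direction and order of p-value", {
  coh <- generate_cohort(cohort_params(
    n = 300, seed = 41,
    log_hazard = list(recurrence = c(n_positive = 0.8))))
  lr <- logrank_test(coh$time_to_recurrence, coh$recurrence_event,
                     coh$n_stage)
  cx <- cox_fit(coh, "n_stage", outcome = "recurrence")
  expect_gt(cx$coefficients$coef, 0) # N+ worse, matching the log-rank split
  expect_gt(lr$observed["N+"], lr$expected["N+"])
  ratio <- cx$coefficients$p / lr$p_value
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})

test_that("univariate screen ranks a strong PNI effect first in most replicates", {
  hits <- 0
  for (seed in 1:15) {
    coh <- generate_cohort(cohort_params(
      n = 300, seed = 500 + seed,
      log_hazard = list(recurrence = c(pni = 1.5),
                        death = c(pni = 1.5))))
    sc <- univariate_screen(coh, outcome = "recurrence")
    if (sc$parameter[which.min(sc$p)] == "pni") hits <- hits + 1
  }
  expect_gt(hits, 15 / 2)
  expect_error(univariate_screen(generate_cohort(cohort_params(n = 50)),
                                 parameters = character(0)),
               "no parameters")
})

test_that("multivariate selection keeps screened parameters and appends Vt and St", {
  coh <- generate_cohort(cohort_params(
    n = 400, seed = 61,
    log_hazard = list(recurrence = c(n_positive = 1.3, vt = 0, one_minus_st = 0))))
  fit <- multivariate_model(coh, outcome = "recurrence")
  expect_true(all(c("Vt", "St") %in% fit$coefficients$term))
  expect_true("n_stage" %in% fit$coefficients$term)
  ci <- fit$coefficients[fit$coefficients$term == "n_stage", ]
  expect_gt(ci$lcl, 1) # CI excludes 1 for the truly prognostic parameter
})

test_that("with no significant univariate parameter the model holds Vt and St only", {
  coh <- generate_cohort(cohort_params(
    n = 95, seed = 71,
    log_hazard = list(recurrence = c(vt = 0, one_minus_st = 0),
                      death = c(vt = 0, one_minus_st = 0))))
  sc <- univariate_screen(coh, outcome = "recurrence")
  expect_true(all(is.na(sc$p) | sc$p > 0.05)) # this null draw screens nothing
  expect_message(fit <- multivariate_model(coh, outcome = "recurrence",
                                           screen = sc),
                 "Vt and St only")
  expect_equal(sort(fit$coefficients$term), c("St", "Vt"))
})

test_that("fewer events than model terms triggers an events-per-variable warning", {
  # handcrafted 8-patient cohort with a single recurrence event
  coh <- data.frame(
    id = sprintf("P%02d", 1:8),
    sex = rep(c("male", "female"), 4),
    t_stage = rep(c("T1-T2", "T3-T4"), each = 4),
    n_stage = rep(c("N-", "N+"), 4),
    grading = rep(c("low", "moderate", "high", "moderate"), 2),
    pni = rep(0:1, 4), lvi = 0L, ecs = 0L, margins = 0L,
    Vt_cm3 = seq(2, 30, length.out = 8), St = seq(0.45, 0.8, length.out = 8),
    time_to_recurrence = c(5, 12, 20, 25, 30, 40, 50, 60),
    recurrence_event = c(1L, rep(0L, 7)),
    time_to_death = c(5, 12, 20, 25, 30, 40, 50, 60),
    death_event = c(1L, rep(0L, 7)))
  expect_warning(
    suppressMessages(multivariate_model(coh, outcome = "recurrence",
                                        parameters = c("t_stage", "n_stage",
                                                       "pni"))),
    "events per variable")
})

test_that("dichotomized morphometric coding enters the multivariate model", {
  coh <- generate_cohort(cohort_params(n = 150, seed = 91))
  cuts <- derive_cutoffs(coh)
  fit <- suppressMessages(multivariate_model(
    coh, outcome = "recurrence", morpho_coding = "dichotomized",
    cutoffs = list(Vt = cuts$cutoff[cuts$marker == "Vt_cm3"][1],
                   St = cuts$cutoff[cuts$marker == "St"][1])))
  expect_true(all(c("Vt_above_cutoff", "St_below_cutoff") %in%
                    fit$coefficients$term))
})
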