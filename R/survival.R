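#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator of the survival function from right-censored
#' follow-up times, with the at-risk and event counts at each event time,
#' the median survival time, and the restricted mean survival time (area
#' under the curve up to the largest observed time). Without censoring the
#' estimate equals the empirical survival function.
#'
#' @param time follow-up times in months (>= 0).
#' @param event event indicator (1 = event, 0 = censored).
#' @return An object of class `km_estimate`: data frame `table` with
#'   columns `time`, `n_risk`, `n_event`, `n_censor`, `surv`; `median`;
#'   `rmean` (restricted mean) and `rmean_horizon`; and the underlying
#'   `survival::survfit` object as `fit`.
#' @examples
#' km <- km_fit(c(1, 2, 3, 4), c(1, 1, 1, 1))
#' survival_at(km, 2) # 0.5
#' @export
km_fit <- function(time, event) {
  if (length(time) == 0L) stop("no observations")
  if (length(time) != length(event)) stop("time and event lengths differ")
  if (any(!is.finite(time)) || any(time < 0)) {
    stop("times must be finite and non-negative")
  }
  event <- as.integer(event)
  if (!all(event %in% c(0L, 1L))) stop("event must be binary (0/1)")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  horizon <- max(time)
  tab <- summary(fit, rmean = horizon)$table
  med <- unname(tab["median"])
  rmean <- unname(tab[grep("rmean$", names(tab))[1]])
  structure(list(
    table = data.frame(time = fit$time, n_risk = fit$n.risk,
                       n_event = fit$n.event, n_censor = fit$n.censor,
                       surv = fit$surv),
    median = med, rmean = rmean, rmean_horizon = horizon,
    n = length(time), n_events = sum(event), fit = fit
  ), class = "km_estimate")
}

#' @rdname km_fit
#' @param km a `km_estimate`.
#' @param t times at which to evaluate the step function.
#' @export
survival_at <- function(km, t) {
  stopifnot(inherits(km, "km_estimate"))
  tab <- km$table[km$table$n_event > 0, , drop = FALSE]
  vapply(t, function(tt) {
    below <- tab$time <= tt
    if (!any(below)) 1 else tab$surv[max(which(below))]
  }, numeric(1))
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("km_estimate: n = %d, events = %d, median = %s months, restricted mean = %.1f months (horizon %.1f)\n",
              x$n, x$n_events,
              if (is.na(x$median)) "not reached" else format(x$median),
              x$rmean, x$rmean_horizon))
  invisible(x)
}

#' Log-rank comparison of two or more survival curves
#'
#' Standard observed-minus-expected chi-square test with hypergeometric
#' variance, `df = groups - 1`. Supports any number of groups, e.g.
#' comparing the four TNM stages or the two sides of a marker cutoff.
#'
#' @param time follow-up times in months.
#' @param event event indicator (1 = event, 0 = censored).
#' @param group group labels (factor or coercible); every level must be
#'   non-empty.
#' @return An object of class `logrank_result`: `statistic`, `df`,
#'   `p_value`, and per-group `observed` / `expected` event counts.
#' @export
logrank_test <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2L) {
    stop("log-rank test needs at least 2 non-empty groups")
  }
  if (anyNA(group)) stop("group labels must not contain NA")
  event <- as.integer(event)
  if (sum(event) == 0L) stop("log-rank test needs at least one event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1L
  structure(list(statistic = unname(sd$chisq), df = df,
                 p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
                 observed = stats::setNames(as.vector(sd$obs),
                                            levels(group)),
                 expected = stats::setNames(as.vector(sd$exp),
                                            levels(group))),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("logrank_result: chi-square = %.3f on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Student's t-test between two groups
#'
#' Two-sided comparison of group means, pooled-variance (classical
#' Student) by default; set `welch = TRUE` for the unequal-variance Welch
#' form. When both groups are constant: equal means give `t = 0, p = 1`
#' by convention, unequal means give an infinite statistic with `p = 0`.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param welch use the Welch correction.
#' @return List with `statistic`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
t_test_groups <- function(a, b, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 observations")
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(statistic = if (eq) 0 else sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2L,
                p_value = if (eq) 1 else 0,
                mean_a = mean(a), mean_b = mean(b),
                method = if (welch) "welch" else "student"))
  }
  tt <- stats::t.test(a, b, var.equal = !welch)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_a = mean(a), mean_b = mean(b),
       method = if (welch) "welch" else "student")
}

# Map analysis term names to numeric columns of the cohort. Binary
# clinical covariates are 0/1; grading is coded ordinally (low 0,
# moderate 1, high 2) so it enters as a single trend coefficient.
cox_term_matrix <- function(cohort, terms, cutoffs = NULL) {
  build <- function(term) {
    switch(term,
      t_stage = as.numeric(cohort$t_stage == "T3-T4"),
      n_stage = as.numeric(cohort$n_stage == "N+"),
      grading = as.numeric(factor(cohort$grading,
                                  levels = c("low", "moderate",
                                             "high"))) - 1,
      pni = as.numeric(cohort$pni),
      lvi = as.numeric(cohort$lvi),
      ecs = as.numeric(cohort$ecs),
      margins = as.numeric(cohort$margins),
      sex = as.numeric(cohort$sex == "male"),
      Vt = cohort$Vt_cm3,
      St = cohort$St,
      one_minus_st = 1 - cohort$St,
      Vt_above_cutoff = {
        if (is.null(cutoffs$Vt)) stop("no Vt cutoff supplied")
        as.numeric(cohort$Vt_cm3 > cutoffs$Vt)
      },
      St_below_cutoff = {
        if (is.null(cutoffs$St)) stop("no St cutoff supplied")
        as.numeric(cohort$St <= cutoffs$St)
      },
      {
        if (!term %in% names(cohort)) stop("unknown covariate: ", term)
        v <- cohort[[term]]
        if (!is.numeric(v)) stop("covariate is not numeric: ", term)
        v
      })
  }
  x <- vapply(terms, build, numeric(nrow(cohort)))
  matrix(x, ncol = length(terms), dimnames = list(NULL, terms))
}

outcome_surv <- function(cohort, outcome = c("recurrence", "death")) {
  outcome <- match.arg(outcome)
  if (outcome == "recurrence") {
    survival::Surv(cohort$time_to_recurrence, cohort$recurrence_event)
  } else {
    survival::Surv(cohort$time_to_death, cohort$death_event)
  }
}

#' Cox proportional-hazards fit
#'
#' Fits a Cox model for one outcome of the cohort by partial-likelihood
#' maximisation (Breslow tie handling by default, Efron available),
#' reporting per-covariate coefficients, hazard ratios with Wald 95%
#' confidence intervals and p-values. Covariates with zero variance are
#' reported with coefficient 0 and hazard ratio 1 rather than dropped
#' silently; non-convergence or monotone-likelihood (perfect separation)
#' warnings from the optimiser are captured and flagged.
#'
#' @param cohort a cohort data frame (see [generate_cohort()]).
#' @param covariates character vector of model terms: `t_stage`,
#'   `n_stage`, `grading` (ordinal), `pni`, `lvi`, `ecs`, `margins`,
#'   `sex`, `Vt` (continuous, per cm^3), `St` (continuous),
#'   `one_minus_st`, `Vt_above_cutoff` / `St_below_cutoff` (dichotomized
#'   at `cutoffs`), or any numeric cohort column.
#' @param outcome `"recurrence"` or `"death"`.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param cutoffs named list (`Vt`, `St`) used by the dichotomized
#'   codings.
#' @return An object of class `cox_fit`: data frame `coefficients` with
#'   `term`, `coef`, `hr`, `se`, `lcl`, `ucl`, `z`, `p`; `loglik`
#'   (null and fitted log partial likelihoods); `n`, `n_events`;
#'   `converged`; `flags` (captured optimiser warnings); and the
#'   underlying `coxph` object as `fit`.
#' @export
cox_fit <- function(cohort, covariates, outcome = c("recurrence", "death"),
                    ties = c("breslow", "efron"), cutoffs = NULL) {
  outcome <- match.arg(outcome)
  ties <- match.arg(ties)
  if (length(covariates) == 0L) stop("no covariates supplied")
  y <- outcome_surv(cohort, outcome)
  if (sum(y[, "status"]) == 0) stop("no events for outcome '", outcome, "'")
  x <- cox_term_matrix(cohort, covariates, cutoffs)
  const <- apply(x, 2, function(col) stats::var(col) == 0)
  flags <- character(0)
  res <- data.frame(term = covariates, coef = 0, hr = 1, se = NA_real_,
                    lcl = NA_real_, ucl = NA_real_, z = NA_real_,
                    p = NA_real_, stringsAsFactors = FALSE)
  fit <- NULL
  loglik <- c(NA_real_, NA_real_)
  converged <- TRUE
  if (any(!const)) {
    xm <- x[, !const, drop = FALSE]
    dat <- data.frame(xm)
    names(dat) <- colnames(xm)
    form <- stats::as.formula(paste("y ~",
                                    paste(sprintf("`%s`", colnames(xm)),
                                          collapse = " + ")))
    dat$y <- y
    fit <- withCallingHandlers(
      survival::coxph(form, data = dat, ties = ties),
      warning = function(w) {
        flags <<- c(flags, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    s <- summary(fit)
    loglik <- fit$loglik
    converged <- !any(grepl("converge|infinite|beta may be infinite",
                            flags, ignore.case = TRUE))
    idx <- match(colnames(xm), res$term)
    res$coef[idx] <- unname(stats::coef(fit))
    res$se[idx] <- s$coefficients[, "se(coef)"]
    res$hr[idx] <- exp(res$coef[idx])
    res$lcl[idx] <- exp(res$coef[idx] - 1.96 * res$se[idx])
    res$ucl[idx] <- exp(res$coef[idx] + 1.96 * res$se[idx])
    res$z[idx] <- res$coef[idx] / res$se[idx]
    res$p[idx] <- 2 * stats::pnorm(-abs(res$z[idx]))
  }
  if (any(const)) {
    flags <- c(flags, paste0("constant covariate(s) reported with HR 1: ",
                             paste(covariates[const], collapse = ", ")))
  }
  structure(list(coefficients = res, loglik = loglik, n = nrow(cohort),
                 n_events = sum(y[, "status"]), outcome = outcome,
                 ties = ties, converged = converged, flags = flags,
                 fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("cox_fit (%s, %s ties): n = %d, events = %d%s\n",
              x$outcome, x$ties, x$n, x$n_events,
              if (x$converged) "" else " [NOT CONVERGED]"))
  df <- x$coefficients
  df$hr <- sprintf("%.2f", df$hr)
  df$ci95 <- sprintf("%.2f-%.2f", x$coefficients$lcl, x$coefficients$ucl)
  df$p <- sprintf("%.3g", x$coefficients$p)
  print(df[, c("term", "p", "hr", "ci95")], row.names = FALSE)
  invisible(x)
}

#' Univariate Cox screen of clinical prognostic parameters
#'
#' One single-covariate Cox fit per parameter, mirroring the familiar
#' univariate-analysis table (p-value, hazard ratio, 95% CI per row).
#'
#' @param cohort a cohort data frame.
#' @param parameters terms to screen (see [cox_fit()]).
#' @param outcome `"recurrence"` or `"death"`.
#' @param ties tie handling passed to [cox_fit()].
#' @return A data frame with one row per parameter: `parameter`, `p`,
#'   `hr`, `lcl`, `ucl`, `coef`, `se`.
#' @export
univariate_screen <- function(cohort,
                              parameters = c("t_stage", "n_stage", "pni",
                                             "grading", "lvi", "margins"),
                              outcome = c("recurrence", "death"),
                              ties = c("breslow", "efron")) {
  outcome <- match.arg(outcome)
  if (length(parameters) == 0L) stop("no parameters to screen")
  rows <- lapply(parameters, function(par) {
    f <- cox_fit(cohort, par, outcome = outcome, ties = ties)
    cf <- f$coefficients
    data.frame(parameter = par, p = cf$p, hr = cf$hr, lcl = cf$lcl,
               ucl = cf$ucl, coef = cf$coef, se = cf$se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "outcome") <- outcome
  out
}

#' Multivariate Cox model with univariate pre-selection
#'
#' Keeps the clinical parameters whose univariate p-value is at or below
#' `alpha`, appends tumor volume and tumor sphericity, and fits the joint
#' Cox model. The morphometric markers enter continuously by default
#' (`Vt` per cm^3, `St` per unit) or dichotomized at supplied cutoffs.
#' If no clinical parameter passes the screen the model contains the two
#' morphometric markers only (a message notes this). A warning with an
#' events-per-variable diagnostic is issued when events are fewer than
#' model terms.
#'
#' @param cohort a cohort data frame.
#' @param outcome `"recurrence"` or `"death"`.
#' @param parameters clinical parameters to screen.
#' @param alpha univariate selection threshold.
#' @param morpho_coding `"continuous"` or `"dichotomized"`.
#' @param cutoffs named list (`Vt`, `St`) of cutoffs, required for the
#'   dichotomized coding.
#' @param screen optional precomputed [univariate_screen()] table.
#' @param ties tie handling passed to [cox_fit()].
#' @return A [cox_fit()] object with attributes `selected` (parameters
#'   kept by the screen) and `screen` (the univariate table).
#' @export
multivariate_model <- function(cohort, outcome = c("recurrence", "death"),
                               parameters = c("t_stage", "n_stage", "pni",
                                              "grading", "lvi", "margins"),
                               alpha = 0.05,
                               morpho_coding = c("continuous",
                                                 "dichotomized"),
                               cutoffs = NULL, screen = NULL,
                               ties = c("breslow", "efron")) {
  outcome <- match.arg(outcome)
  morpho_coding <- match.arg(morpho_coding)
  ties <- match.arg(ties)
  if (is.null(screen)) {
    screen <- univariate_screen(cohort, parameters, outcome, ties)
  }
  selected <- screen$parameter[!is.na(screen$p) & screen$p <= alpha]
  if (length(selected) == 0L) {
    message("no clinical parameter passed the univariate screen (p <= ",
            alpha, "); multivariate model contains Vt and St only")
  }
  morpho <- if (morpho_coding == "continuous") c("Vt", "St")
            else c("Vt_above_cutoff", "St_below_cutoff")
  terms <- c(selected, morpho)
  n_events <- sum(cohort[[paste0(outcome, "_event")]])
  if (n_events < length(terms)) {
    warning(sprintf("fewer events (%d) than model terms (%d): events per variable = %.2f",
                    n_events, length(terms), n_events / length(terms)))
  }
  fit <- cox_fit(cohort, terms, outcome = outcome, ties = ties,
                 cutoffs = cutoffs)
  attr(fit, "selected") <- selected
  attr(fit, "screen") <- screen
  fit
}
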