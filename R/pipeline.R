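#' Configuration for the full prognosis-analysis pipeline
#'
#' Describes one analysis run end to end. Exactly one input mode is
#' active: `"synthetic"` (the built-in generator produces the cohort, and
#' optionally actual tumor meshes whose measured morphometrics feed the
#' outcome model) or `"files"` (a cohort table on disk, optionally joined
#' with per-patient STL meshes or NIfTI masks from a directory, matched by
#' file name = patient id).
#'
#' @param mode `"synthetic"` or `"files"`.
#' @param n synthetic cohort size.
#' @param seed RNG seed recorded in every output.
#' @param cohort_params named list of overrides passed to
#'   [cohort_params()] (synthetic mode).
#' @param with_meshes in synthetic mode, generate a perturbed-sphere mesh
#'   per patient and measure `Vt`/`St` from the meshes instead of drawing
#'   them from distributions.
#' @param mesh_subdivisions icosphere resolution for `with_meshes`.
#' @param cohort_table path to a cohort CSV (files mode; see
#'   [read_cohort()]).
#' @param mesh_dir directory of per-patient `.stl` files (files mode).
#' @param mask_dir directory of per-patient `.nii`/`.nii.gz` masks (files
#'   mode).
#' @param outcomes outcomes to analyse.
#' @param alpha univariate selection threshold for the multivariate model.
#' @param morpho_coding how `Vt`/`St` enter the multivariate model
#'   (`"continuous"` or `"dichotomized"` at the derived cutoffs).
#' @param welch use Welch instead of pooled-variance t-tests in the group
#'   summary.
#' @param ties Cox tie handling.
#' @param max_failure_fraction abort if more than this fraction of
#'   patients fail mesh morphometrics.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(mode = c("synthetic", "files"),
                            n = 95, seed = 1,
                            cohort_params = list(),
                            with_meshes = FALSE,
                            mesh_subdivisions = 3,
                            cohort_table = NULL,
                            mesh_dir = NULL, mask_dir = NULL,
                            outcomes = c("recurrence", "death"),
                            alpha = 0.05,
                            morpho_coding = c("continuous", "dichotomized"),
                            welch = FALSE,
                            ties = c("breslow", "efron"),
                            max_failure_fraction = 0.2) {
  mode <- match.arg(mode)
  morpho_coding <- match.arg(morpho_coding)
  ties <- match.arg(ties)
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  if (mode == "files") {
    if (is.null(cohort_table)) {
      stop("files mode requires a cohort_table path")
    }
    if (!file.exists(cohort_table)) {
      stop("cohort table not found: ", cohort_table)
    }
    if (!is.null(mesh_dir) && !is.null(mask_dir)) {
      stop("supply either mesh_dir or mask_dir, not both")
    }
    if (!is.null(mesh_dir) && !dir.exists(mesh_dir)) {
      stop("mesh directory not found: ", mesh_dir)
    }
    if (!is.null(mask_dir) && !dir.exists(mask_dir)) {
      stop("mask directory not found: ", mask_dir)
    }
  }
  structure(list(mode = mode, n = as.integer(n), seed = as.integer(seed),
                 cohort_params = cohort_params, with_meshes = with_meshes,
                 mesh_subdivisions = mesh_subdivisions,
                 cohort_table = cohort_table, mesh_dir = mesh_dir,
                 mask_dir = mask_dir, outcomes = outcomes, alpha = alpha,
                 morpho_coding = morpho_coding, welch = welch, ties = ties,
                 max_failure_fraction = max_failure_fraction),
            class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' @param path YAML file whose keys are [analysis_config()] arguments.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  # YAML 1.1 reads a bare `n` key as the boolean FALSE; map it back
  names(vals)[names(vals) %in% c("FALSE", "no")] <- "n"
  do.call(analysis_config, vals)
}

#' Group summary of the morphometric markers
#'
#' Means, SDs and ranges of `Vt` and `St` overall and by outcome status
#' (disease-free and alive, recurrence, tumor-related death), with
#' t-test comparisons of recurrence vs disease-free patients and deceased
#' vs alive patients. Comparisons involving a group with fewer than two
#' patients are suppressed with a note.
#'
#' @param cohort a cohort data frame with morphometrics and both event
#'   flags.
#' @param welch use Welch instead of pooled-variance t-tests.
#' @return List of class `group_summary` with data frames `groups` and
#'   `comparisons`.
#' @export
summarize_groups <- function(cohort, welch = FALSE) {
  sel <- list(
    total = rep(TRUE, nrow(cohort)),
    disease_free = cohort$recurrence_event == 0 & cohort$death_event == 0,
    recurrence = cohort$recurrence_event == 1,
    tumor_death = cohort$death_event == 1
  )
  stat_row <- function(name, idx) {
    vt <- cohort$Vt_cm3[idx]
    st <- cohort$St[idx]
    data.frame(group = name, n = sum(idx),
               mean_Vt = if (sum(idx)) mean(vt) else NA_real_,
               sd_Vt = if (sum(idx) > 1) stats::sd(vt) else NA_real_,
               min_Vt = if (sum(idx)) min(vt) else NA_real_,
               max_Vt = if (sum(idx)) max(vt) else NA_real_,
               mean_St = if (sum(idx)) mean(st) else NA_real_,
               sd_St = if (sum(idx) > 1) stats::sd(st) else NA_real_,
               min_St = if (sum(idx)) min(st) else NA_real_,
               max_St = if (sum(idx)) max(st) else NA_real_)
  }
  groups <- do.call(rbind, Map(stat_row, names(sel), sel))
  cmp_defs <- list(
    list(name = "recurrence_vs_disease_free", a = sel$recurrence,
         b = sel$disease_free),
    list(name = "death_vs_alive", a = cohort$death_event == 1,
         b = cohort$death_event == 0)
  )
  rows <- list()
  notes <- character(0)
  for (cd in cmp_defs) {
    for (mk in c("Vt_cm3", "St")) {
      a <- cohort[[mk]][cd$a]
      b <- cohort[[mk]][cd$b]
      if (length(a) < 2L || length(b) < 2L) {
        notes <- c(notes, sprintf("comparison %s suppressed for %s: a group has fewer than 2 patients",
                                  cd$name, mk))
        rows[[length(rows) + 1L]] <- data.frame(
          marker = mk, comparison = cd$name, mean_group = NA_real_,
          mean_reference = NA_real_, t = NA_real_, p = NA_real_)
      } else {
        tt <- t_test_groups(a, b, welch = welch)
        rows[[length(rows) + 1L]] <- data.frame(
          marker = mk, comparison = cd$name, mean_group = tt$mean_a,
          mean_reference = tt$mean_b, t = tt$statistic, p = tt$p_value)
      }
    }
  }
  structure(list(groups = groups, comparisons = do.call(rbind, rows),
                 notes = notes),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat("group_summary\n")
  print(x$groups, row.names = FALSE, digits = 4)
  cat("\ncomparisons (t-test)\n")
  print(x$comparisons, row.names = FALSE, digits = 4)
  if (length(x$notes)) cat("\nnotes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

# Synthetic-mode morphometrics: one perturbed-sphere mesh per patient,
# measured with the same operators applied to clinical meshes.
synthetic_mesh_morphometrics <- function(n, seed, subdivisions,
                                         vt_mean, vt_sd, vt_range) {
  sdlog <- sqrt(log(1 + (vt_sd / vt_mean)^2))
  meanlog <- log(vt_mean) - sdlog^2 / 2
  with_seed(seed + 1L, {
    targets <- stats::rlnorm(n, meanlog, sdlog)
    targets <- pmin(pmax(targets, vt_range[1]), vt_range[2])
    amps <- stats::runif(n, 0, 0.6)
    seeds <- sample.int(.Machine$integer.max, n)
    rows <- lapply(seq_len(n), function(i) {
      m <- generate_tumor_mesh(target_volume_cm3 = targets[i],
                               amplitude = amps[i], seed = seeds[i],
                               subdivisions = subdivisions)
      mm <- mesh_morphometrics(m)
      data.frame(Vt_cm3 = mm$Vt_cm3, St = mm$St)
    })
    do.call(rbind, rows)
  })
}

#' Run the full prognosis-analysis pipeline
#'
#' Executes every stage in order: cohort and morphometrics ingestion (or
#' synthesis), group summary with t-tests, ROC/Youden cutoff derivation
#' per marker and outcome, cutoff-stratified Kaplan-Meier estimation with
#' log-rank comparison, univariate Cox screening of the clinical
#' parameters, and the multivariate Cox model with tumor volume and
#' sphericity appended. The run is deterministic for a fixed configuration
#' and inputs.
#'
#' In files mode, patients whose meshes cannot be measured are excluded
#' with a logged reason; the pipeline aborts if more than
#' `max_failure_fraction` of patients fail morphometrics.
#'
#' @param config an [analysis_config()].
#' @return An object of class `analysis_report`; see [write_report()] for
#'   the serialised layout.
#' @examples
#' rep <- run_pipeline(analysis_config(mode = "synthetic", n = 60,
#'                                     seed = 11))
#' rep$cutoffs
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  failures <- data.frame(id = character(0), reason = character(0))
  if (config$mode == "synthetic") {
    params <- do.call(cohort_params,
                      utils::modifyList(list(n = config$n,
                                             seed = config$seed),
                                        config$cohort_params))
    morpho <- NULL
    if (isTRUE(config$with_meshes)) {
      morpho <- synthetic_mesh_morphometrics(
        params$n, params$seed, config$mesh_subdivisions,
        params$vt_mean, params$vt_sd, params$vt_range)
    }
    cohort <- generate_cohort(params, morphometrics = morpho)
  } else {
    cohort <- read_cohort(config$cohort_table)
    source_dir <- if (!is.null(config$mesh_dir)) config$mesh_dir
                  else config$mask_dir
    if (!is.null(source_dir)) {
      mm <- if (!is.null(config$mesh_dir)) {
        morphometrics_from_dir(config$mesh_dir)
      } else {
        morphometrics_from_masks(config$mask_dir)
      }
      failures <- attr(mm, "failures")
      n_total <- nrow(mm) + nrow(failures)
      if (nrow(failures) > config$max_failure_fraction * n_total) {
        stop(sprintf("morphometrics failed for %d of %d patients (> %.0f%%); aborting",
                     nrow(failures), n_total,
                     100 * config$max_failure_fraction))
      }
      idx <- match(cohort$id, mm$id)
      cohort$Vt_cm3 <- mm$Vt_cm3[idx]
      cohort$St <- mm$St[idx]
      dropped <- is.na(idx)
      unexplained <- dropped & !(cohort$id %in% failures$id)
      if (any(unexplained)) {
        failures <- rbind(failures,
                          data.frame(id = cohort$id[unexplained],
                                     reason = "no measurable mesh for patient"))
      }
      cohort <- cohort[!dropped, , drop = FALSE]
    }
  }

  summary_tab <- summarize_groups(cohort, welch = config$welch)
  cutoffs <- derive_cutoffs(cohort, markers = c("Vt_cm3", "St"),
                            outcomes = config$outcomes)

  strat <- list()
  km_curves <- list()
  for (i in seq_len(nrow(cutoffs))) {
    mk <- cutoffs$marker[i]
    oc <- cutoffs$outcome[i]
    cut <- cutoffs$cutoff[i]
    lab <- if (mk == "Vt_cm3") c("Vt_below_cutoff", "Vt_above_cutoff")
           else c("St_below_cutoff", "St_above_cutoff")
    grp <- dichotomize(cohort[[mk]], cut, labels = lab)
    time <- cohort[[paste0("time_to_", oc)]]
    event <- cohort[[paste0(oc, "_event")]]
    lr <- if (nlevels(droplevels(grp)) == 2L) {
      logrank_test(time, event, grp)
    } else NULL
    for (g in levels(grp)) {
      if (!any(grp == g)) next
      km <- km_fit(time[grp == g], event[grp == g])
      strat[[length(strat) + 1L]] <- data.frame(
        marker = mk, outcome = oc, group = g, cutoff = cut,
        n = km$n, events = km$n_events, median_months = km$median,
        rmean_months = km$rmean,
        logrank_chisq = if (is.null(lr)) NA_real_ else lr$statistic,
        logrank_p = if (is.null(lr)) NA_real_ else lr$p_value)
      km_curves[[length(km_curves) + 1L]] <- data.frame(
        marker = mk, outcome = oc, group = g,
        time = c(0, km$table$time), surv = c(1, km$table$surv))
    }
  }
  stratified <- do.call(rbind, strat)
  km_curves <- do.call(rbind, km_curves)

  cut_list <- list(
    Vt = cutoffs$cutoff[cutoffs$marker == "Vt_cm3"][1],
    St = cutoffs$cutoff[cutoffs$marker == "St"][1]
  )
  univariate <- list()
  multivariate <- list()
  for (oc in config$outcomes) {
    univariate[[oc]] <- univariate_screen(cohort, outcome = oc,
                                          ties = config$ties)
    multivariate[[oc]] <- multivariate_model(
      cohort, outcome = oc, alpha = config$alpha,
      morpho_coding = config$morpho_coding,
      cutoffs = cut_list, screen = univariate[[oc]], ties = config$ties)
  }

  structure(list(
    cohort = cohort,
    morphometrics = cohort[, c("id", "Vt_cm3", "St")],
    group_summary = summary_tab,
    cutoffs = cutoffs,
    stratified_survival = stratified,
    km_curves = km_curves,
    univariate = univariate,
    multivariate = multivariate,
    failures = failures,
    metadata = list(seed = config$seed, mode = config$mode,
                    n_patients = nrow(cohort),
                    package_version = as.character(utils::packageVersion("morphosurv")),
                    config = unclass(config))
  ), class = "analysis_report")
}

# Morphometrics for a directory of NIfTI masks (files mode counterpart of
# morphometrics_from_dir).
morphometrics_from_masks <- function(dir) {
  files <- list.files(dir, pattern = "\\.nii(\\.gz)?$", ignore.case = TRUE,
                      full.names = TRUE)
  if (length(files) == 0L) stop("no NIfTI masks found in ", dir)
  ids <- sub("\\.nii(\\.gz)?$", "", basename(files), ignore.case = TRUE)
  rows <- vector("list", length(files))
  fail <- character(0)
  fail_ids <- character(0)
  for (i in seq_along(files)) {
    res <- tryCatch({
      mm <- mesh_morphometrics(mesh_from_mask(read_nifti_mask(files[i])))
      data.frame(id = ids[i], Vt_cm3 = mm$Vt_cm3, area_cm2 = mm$area_cm2,
                 St = mm$St)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      fail <- c(fail, res)
      fail_ids <- c(fail_ids, ids[i])
    } else rows[[i]] <- res
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(id = character(0), Vt_cm3 = numeric(0),
                      area_cm2 = numeric(0), St = numeric(0))
  }
  attr(out, "failures") <- data.frame(id = fail_ids, reason = fail)
  out
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("analysis_report: %d patients (%s mode, seed %d)\n",
              nrow(x$cohort), x$metadata$mode, x$metadata$seed))
  cat("\ncutoffs:\n")
  print(x$cutoffs, row.names = FALSE, digits = 4)
  cat("\nstratified survival:\n")
  print(x$stratified_survival, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write an analysis report to delimited text files
#'
#' Serialises every table of the report as tab-delimited text plus a JSON
#' metadata file recording the seed and configuration. Identical reports
#' produce byte-identical tables.
#'
#' @param report an [run_pipeline()] report.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  write_cohort(report$cohort, file.path(dir, "cohort.csv"))
  wt(report$morphometrics, "morphometrics.tsv")
  wt(report$group_summary$groups, "group_summary.tsv")
  wt(report$group_summary$comparisons, "group_comparisons.tsv")
  wt(report$cutoffs, "cutoffs.tsv")
  wt(report$stratified_survival, "stratified_survival.tsv")
  wt(report$km_curves, "km_curves.tsv")
  for (oc in names(report$univariate)) {
    wt(report$univariate[[oc]], sprintf("univariate_%s.tsv", oc))
    wt(report$multivariate[[oc]]$coefficients,
       sprintf("multivariate_%s.tsv", oc))
  }
  if (nrow(report$failures)) wt(report$failures, "failures.tsv")
  meta <- report$metadata
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  invisible(dir)
}

#' Synthetic end-to-end demonstration run
#'
#' Runs the whole pipeline on a generated cohort with the default
#' (realistic-effect-size) outcome model, optionally writing the report
#' tables to disk.
#'
#' @param n cohort size.
#' @param seed RNG seed.
#' @param output_dir optional directory for [write_report()].
#' @param ... further arguments to [analysis_config()].
#' @return The [run_pipeline()] report, invisibly if written to disk.
#' @export
demo_analysis <- function(n = 95, seed = 1, output_dir = NULL, ...) {
  report <- run_pipeline(analysis_config(mode = "synthetic", n = n,
                                         seed = seed, ...))
  if (!is.null(output_dir)) {
    write_report(report, output_dir)
    return(invisible(report))
  }
  report
}
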