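#' Empirical ROC curve
#'
#' Computes the empirical receiver-operating-characteristic curve of a
#' continuous marker against a binary event, using the classification rule
#' "positive if marker > threshold". Candidate thresholds are the midpoints
#' between consecutive distinct marker values plus the two infinite
#' endpoints, so every achievable (sensitivity, specificity) pair appears
#' exactly once. The area under the curve is computed by the trapezoid
#' rule, which on this threshold grid equals the Mann-Whitney
#' pairwise-comparison statistic (ties counted 1/2).
#'
#' @param marker numeric marker values (e.g. tumor volume in cm^3).
#' @param event binary event indicator (0/1 or logical), status at last
#'   follow-up.
#' @return An object of class `roc_curve`: data frame `points` with
#'   `threshold`, `sensitivity`, `specificity`; `auc`; class counts.
#' @examples
#' r <- roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1))
#' r$auc # 1: perfect separation
#' @export
roc_curve <- function(marker, event) {
  if (anyNA(marker) || anyNA(event)) stop("marker and event must not contain NA")
  event <- as.integer(event)
  if (!all(event %in% c(0L, 1L))) stop("event must be binary (0/1)")
  if (length(marker) != length(event)) stop("marker and event lengths differ")
  n1 <- sum(event == 1L)
  n0 <- sum(event == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present to compute a ROC curve")
  }
  sv <- sort(unique(marker))
  thr <- c(-Inf, if (length(sv) > 1) (sv[-1] + sv[-length(sv)]) / 2, Inf)
  sens <- vapply(thr, function(t) sum(marker > t & event == 1L) / n1,
                 numeric(1))
  spec <- vapply(thr, function(t) sum(marker <= t & event == 0L) / n0,
                 numeric(1))
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(sens)]) / 2)
  structure(list(points = data.frame(threshold = thr, sensitivity = sens,
                                     specificity = spec),
                 auc = auc, n_event = n1, n_nonevent = n0),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: %d thresholds, AUC = %.4f (%d events / %d non-events)\n",
              nrow(x$points), x$auc, x$n_event, x$n_nonevent))
  invisible(x)
}

#' Youden-index optimal cutoff
#'
#' Selects the threshold maximising the Youden index
#' `J = sensitivity + specificity - 1`. The marker orientation is chosen so
#' that `J >= 0`: if the marker is protective (low values predict the
#' event), the reported orientation is `"low"` and sensitivities refer to
#' the rule "positive if marker <= cutoff". Ties in `J` are broken first
#' toward the threshold with the more balanced sensitivity/specificity
#' pair, then toward the smaller threshold; the rule is deterministic.
#'
#' @param roc a [roc_curve()].
#' @return An object of class `cutoff_result`: `cutoff`, `J`,
#'   `sensitivity`, `specificity`, `orientation` (`"high"` if high marker
#'   values predict the event), and the ROC `auc`.
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  p <- roc$points
  j_high <- p$sensitivity + p$specificity - 1
  orientation <- if (max(-j_high) > max(j_high)) "low" else "high"
  j <- if (orientation == "high") j_high else -j_high
  best <- max(j)
  cand <- which(j >= best - 1e-12)
  if (length(cand) > 1L) {
    bal <- abs(p$sensitivity[cand] - p$specificity[cand])
    cand <- cand[bal <= min(bal) + 1e-12]
    cand <- cand[which.min(p$threshold[cand])]
  }
  sens <- p$sensitivity[cand]
  spec <- p$specificity[cand]
  if (orientation == "low") {
    sens <- 1 - p$sensitivity[cand]
    spec <- 1 - p$specificity[cand]
  }
  structure(list(cutoff = p$threshold[cand], J = j[cand],
                 sensitivity = sens, specificity = spec,
                 orientation = orientation, auc = roc$auc),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("cutoff_result: cutoff = %.4g (%s marker predicts event), J = %.3f, sens = %.3f, spec = %.3f\n",
              x$cutoff, if (x$orientation == "high") "high" else "low",
              x$J, x$sensitivity, x$specificity))
  invisible(x)
}

#' Stratify patients at a cutoff
#'
#' Splits a continuous marker into two groups at a cutoff; values less
#' than or equal to the cutoff go to the lower group (so a patient sitting
#' exactly on the cutoff is "below or equal").
#'
#' @param x numeric marker values.
#' @param cutoff finite cutoff value.
#' @param labels labels for the two groups (below-or-equal, above).
#' @return A factor with the two group labels and attribute `sizes`.
#' @export
dichotomize <- function(x, cutoff, labels = c("low", "high")) {
  if (!is.finite(cutoff)) stop("cutoff must be finite")
  g <- factor(ifelse(x > cutoff, labels[2], labels[1]), levels = labels)
  sizes <- table(g)
  if (any(sizes == 0L)) {
    warning("dichotomize produced an empty group ('",
            names(sizes)[sizes == 0][1], "')")
  }
  attr(g, "sizes") <- as.integer(sizes)
  g
}

#' Derive Youden cutoffs for the morphometric markers
#'
#' Runs [roc_curve()] and [youden_cutoff()] for each marker against each
#' outcome's event status at last follow-up, mirroring a per-outcome
#' cutoff derivation (separate cutoffs for recurrence and tumor-related
#' death).
#'
#' @param cohort a cohort data frame (see [generate_cohort()]).
#' @param markers cohort column names of continuous markers.
#' @param outcomes outcomes to binarize against (`"recurrence"`,
#'   `"death"`).
#' @return A data frame with one row per marker x outcome: cutoff, Youden
#'   `J`, AUC, orientation, sensitivity, specificity.
#' @export
derive_cutoffs <- function(cohort, markers = c("Vt_cm3", "St"),
                           outcomes = c("recurrence", "death")) {
  rows <- list()
  for (oc in outcomes) {
    ev <- cohort[[paste0(oc, "_event")]]
    for (mk in markers) {
      cr <- youden_cutoff(roc_curve(cohort[[mk]], ev))
      rows[[length(rows) + 1L]] <- data.frame(
        marker = mk, outcome = oc, cutoff = cr$cutoff, J = cr$J,
        auc = cr$auc, orientation = cr$orientation,
        sensitivity = cr$sensitivity, specificity = cr$specificity)
    }
  }
  do.call(rbind, rows)
}
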