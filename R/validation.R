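# validation: ROC/AUC with DeLong SE and CI, PPV enrichment vs the observed
# response rate, Kaplan-Meier / log-rank stratification at the frozen threshold.

#' ROC AUC with DeLong standard error and one-sided MWW p-value
#'
#' AUC is the pairwise concordance fraction with ties counted 1/2. The standard
#' error and 95% CI use the DeLong placement method (CI clipped to `[0, 1]`);
#' the p-value is the one-sided Mann-Whitney-Wilcoxon test of AUC > 0.5
#' (normal approximation with tie correction).
#'
#' @param scores Numeric prediction scores (larger = predicted positive).
#' @param labels Binary labels (1 = responder); both classes required.
#' @return A list of class `"roc_result"`: `auc`, `se`, `ci95`, `p_value`,
#'   `n_pos`, `n_neg`, `sidedness`.
#' @export
roc_auc <- function(scores, labels) {
  scores <- as.numeric(scores)
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) .stopf("scores and labels differ in length")
  if (anyNA(scores) || anyNA(labels)) .stopf("missing scores or labels")
  if (!all(labels %in% c(0, 1))) .stopf("labels must be binary 0/1")
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  npos <- length(sp); nneg <- length(sn)
  if (npos < 1L || nneg < 1L) .stopf("labels must contain both classes")
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  auc <- mean(cmp)
  v10 <- rowMeans(cmp)                 # placements of positives
  v01 <- 1 - colMeans(cmp)             # placements of negatives (P(neg < pos))
  s10 <- if (npos > 1L) stats::var(v10) else 0
  s01 <- if (nneg > 1L) stats::var(1 - v01) else 0
  se <- sqrt(s10 / npos + s01 / nneg)
  ci <- pmin(1, pmax(0, auc + c(-1, 1) * stats::qnorm(0.975) * se))
  p <- suppressWarnings(
    stats::wilcox.test(sp, sn, alternative = "greater",
                       exact = FALSE, correct = FALSE)$p.value)
  structure(list(auc = auc, se = se, ci95 = c(lower = ci[1L], upper = ci[2L]),
                 p_value = p, n_pos = npos, n_neg = nneg,
                 sidedness = "one-sided (AUC > 0.5)"),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (SE %.3f, 95%% CI %.3f-%.3f), MWW p = %.3g [%s], %d pos / %d neg\n",
              x$auc, x$se, x$ci95[1L], x$ci95[2L], x$p_value, x$sidedness,
              x$n_pos, x$n_neg))
  invisible(x)
}

#' Stratify patients at a fixed percentile threshold
#'
#' Predicted positive (responsive) if and only if the percentile score is at
#' or above the threshold (inclusive). Either class may be empty; downstream
#' statistics guard for that.
#'
#' @param scores A `"patient_scores"` data frame or a numeric percentile vector.
#' @param threshold Threshold on the percentile scale, strictly inside (0, 1).
#' @return Factor with levels `negative`, `positive`, named by sample where ids
#'   are available.
#' @export
stratify <- function(scores, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold) || threshold <= 0 || threshold >= 1)
    .stopf("threshold must lie strictly inside (0, 1) on the percentile scale")
  perc <- if (inherits(scores, "patient_scores")) scores$percentile else as.numeric(scores)
  cls <- factor(ifelse(perc >= threshold, "positive", "negative"),
                levels = c("negative", "positive"))
  if (inherits(scores, "patient_scores")) names(cls) <- scores$sample_id
  cls
}

#' Exact one-sided binomial test of PPV enrichment
#'
#' Given the responses of the predicted-positive patients, tests whether the
#' positive predictive value exceeds the cohort's unselected response rate
#' (`H1: p > baseline_rate`) by the exact binomial upper tail.
#'
#' @param predicted_pos_responses Binary responses of predicted positives.
#' @param baseline_rate Observed unselected response rate, in (0, 1).
#' @return A list of class `"ppv_result"`.
#' @export
ppv_test <- function(predicted_pos_responses, baseline_rate) {
  r <- as.numeric(predicted_pos_responses)
  if (!length(r)) .stopf("no predicted responders")
  if (anyNA(r) || !all(r %in% c(0, 1))) .stopf("responses must be binary 0/1")
  if (!(baseline_rate > 0 && baseline_rate < 1))
    .stopf("baseline_rate must lie in (0, 1)")
  n <- length(r); x <- sum(r)
  p <- stats::binom.test(x, n, p = baseline_rate, alternative = "greater")$p.value
  structure(list(n_predicted_positive = n, n_true_positive_within_predicted = x,
                 ppv = x / n, baseline_rate = baseline_rate, p_value = p,
                 sidedness = "one-sided (PPV > baseline)"),
            class = "ppv_result")
}

#' @export
print.ppv_result <- function(x, ...) {
  cat(sprintf("<ppv_result> PPV %.1f%% (%d/%d) vs baseline %.1f%%, exact binomial p = %.3g [%s]\n",
              100 * x$ppv, x$n_true_positive_within_predicted,
              x$n_predicted_positive, 100 * x$baseline_rate, x$p_value,
              x$sidedness))
  invisible(x)
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit survival estimates per predicted group and the unstratified
#' two-group log-rank chi-square (1 df) with standard hypergeometric tie
#' handling.
#'
#' @param times Nonnegative survival times.
#' @param events Binary event indicators (1 = event observed).
#' @param groups Two-level grouping (e.g. predicted positive/negative); both
#'   groups non-empty.
#' @return A list of class `"survival_comparison"`: per-group `curves`
#'   (time, survival, at-risk counts), `chisq`, `p_value`.
#' @export
km_logrank <- function(times, events, groups) {
  times <- as.numeric(times); events <- as.numeric(events)
  g <- factor(groups)
  if (nlevels(g) != 2L) .stopf("need exactly two groups, got %d", nlevels(g))
  if (any(table(g) == 0L)) .stopf("a group is empty")
  if (anyNA(times) || any(times < 0)) .stopf("times must be nonnegative and complete")
  if (!all(events %in% c(0, 1))) .stopf("events must be binary 0/1")
  if (sum(events) < 1) .stopf("no events observed")
  sf <- survival::survfit(survival::Surv(times, events) ~ g)
  strata_names <- sub("^g=", "", names(sf$strata))
  curves <- data.frame(
    group = rep(strata_names, sf$strata),
    time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
    survival = sf$surv, stringsAsFactors = FALSE)
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  chisq <- unname(sd$chisq)
  structure(list(groups = levels(g), curves = curves, chisq = chisq,
                 p_value = stats::pchisq(chisq, df = 1L, lower.tail = FALSE)),
            class = "survival_comparison")
}

#' @export
print.survival_comparison <- function(x, ...) {
  cat(sprintf("<survival_comparison> log-rank chi-square %.3f (1 df), p = %.3g [groups: %s]\n",
              x$chisq, x$p_value, paste(x$groups, collapse = " vs ")))
  invisible(x)
}

#' Prospective validation of a frozen model on one cohort
#'
#' Re-checks cohort suitability (COXEN distribution of the final model genes
#' between the original-cancer reference and this cohort, gated against the
#' within-cancer wCOXEN sets), scores the cohort, stratifies at the frozen
#' training threshold, and computes every statistic the phenotype supports:
#' ROC/AUC when a two-class response is present, PPV enrichment when there are
#' predicted positives, Kaplan-Meier/log-rank when survival columns exist. A
#' cohort failing the suitability gate is still scored and reported, flagged as
#' unsuitable (threshold-based stratification is not expected to transfer).
#' The model and threshold are never modified.
#'
#' @param model A `"pcr_model"` with a threshold (or pass `threshold`).
#' @param cohort_expr Cohort [expression_matrix()].
#' @param phenotype The cohort's [phenotype_table()].
#' @param reference_wcoxen List of within-original-cancer
#'   `"coxen_coefficients"` computed on the model genes.
#' @param reference_expr Original-cancer reference [expression_matrix()] used
#'   to compute this cohort's bCOXEN.
#' @param threshold Percentile threshold; defaults to `model$threshold`.
#' @param gate_alpha One-sided gate level (default 0.025).
#' @param cohort_label Report label.
#' @return A list of class `"validation_report"`.
#' @export
validate_cohort <- function(model, cohort_expr, phenotype, reference_wcoxen,
                            reference_expr, threshold = model$threshold,
                            gate_alpha = 0.025,
                            cohort_label = cohort_expr$system_label) {
  stopifnot(inherits(model, "pcr_model"), inherits(cohort_expr, "expression_matrix"),
            inherits(phenotype, "phenotype_table"))
  if (is.null(threshold)) .stopf("model carries no threshold; select one first")
  idx <- match(sample_ids(cohort_expr), phenotype$sample_id)
  if (anyNA(idx)) .stopf("phenotype missing for cohort sample(s)")
  resp <- phenotype$response[idx]
  time <- phenotype$time[idx]
  event <- phenotype$event[idx]
  has_response <- any(!is.na(resp))
  has_survival <- any(!is.na(time) & !is.na(event))
  if (!has_response && !has_survival)
    .stopf("phenotype has neither response nor survival columns")

  bcox <- coxen_distribution(model$gene_ids, reference_expr, cohort_expr)
  gate <- gate_cancer_types(reference_wcoxen,
                            stats::setNames(list(bcox), cohort_label),
                            alpha = gate_alpha)
  suitable <- gate$suitable[1L]

  scores <- score_cohort(model, cohort_expr)
  classes <- stratify(scores, threshold)
  notes <- character()
  if (!suitable)
    notes <- c(notes, "unsuitable - threshold-based stratification not expected to transfer")

  roc <- NULL; ppv <- NULL; surv <- NULL
  if (has_response) {
    ok <- !is.na(resp)
    if (length(unique(resp[ok])) == 2L) {
      roc <- roc_auc(scores$percentile[ok], resp[ok])
    } else notes <- c(notes, "response has a single class; AUC skipped")
    pos <- classes == "positive" & ok
    if (any(pos)) {
      base <- mean(resp[ok])
      if (base > 0 && base < 1) ppv <- ppv_test(resp[pos], base)
      else notes <- c(notes, "degenerate baseline response rate; PPV test skipped")
    } else notes <- c(notes, "no predicted responders; PPV test skipped")
  }
  if (has_survival) {
    ok <- !is.na(time) & !is.na(event)
    if (all(table(classes[ok]) > 0L) && sum(event[ok]) >= 1) {
      surv <- km_logrank(time[ok], event[ok], classes[ok])
    } else notes <- c(notes, "empty stratum or no events; log-rank skipped")
  }
  structure(list(cohort_label = cohort_label, suitable = suitable, gate = gate,
                 scores = scores, classes = classes, roc = roc, ppv = ppv,
                 survival = surv, threshold = threshold, notes = notes,
                 n = length(idx)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %s (n = %d): %s, threshold %.3f\n",
              x$cohort_label, x$n,
              if (x$suitable) "suitable" else "UNSUITABLE", x$threshold))
  if (!is.null(x$roc)) print(x$roc)
  if (!is.null(x$ppv)) print(x$ppv)
  if (!is.null(x$survival)) print(x$survival)
  for (nt in x$notes) cat("  note:", nt, "\n")
  invisible(x)
}
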