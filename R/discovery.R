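# discovery: screen a cell-line panel for genes whose expression associates
# with in vitro drug activity; pick the most informative panel.

#' Split cell lines into sensitive / intermediate / resistant classes
#'
#' Lines with activity at or above the `upper_frac` empirical quantile are
#' "sensitive", at or below the `lower_frac` quantile "resistant", the rest
#' "intermediate". Ties straddling a cut are assigned to the extreme class.
#' Defaults are tertiles, which keep both extreme classes populated for any
#' activity distribution.
#'
#' @param act A [drug_activity()].
#' @param lower_frac,upper_frac Cut fractions, `0 < lower_frac <= upper_frac < 1`.
#' @return An object of class `"sensitivity_classing"` with a per-line `class`.
#' @export
classify_sensitivity <- function(act, lower_frac = 1 / 3, upper_frac = 2 / 3) {
  stopifnot(inherits(act, "drug_activity"))
  a <- act$activity
  if (length(a) < 3L) .stopf("need at least 3 cell lines")
  if (!(lower_frac > 0 && lower_frac <= upper_frac && upper_frac < 1))
    .stopf("cut fractions must satisfy 0 < lower_frac <= upper_frac < 1")
  if (all(a == a[1L])) .stopf("all activity values tied; cannot form classes")
  ql <- stats::quantile(a, lower_frac, names = FALSE, type = 7)
  qu <- stats::quantile(a, upper_frac, names = FALSE, type = 7)
  cls <- rep("intermediate", length(a))
  cls[a <= ql] <- "resistant"
  cls[a >= qu] <- "sensitive"   # applied last: a value on both cuts counts sensitive
  names(cls) <- act$cell_line_ids
  if (!any(cls == "sensitive") || !any(cls == "resistant"))
    .stopf("empty extreme class after cuts (%g, %g)", lower_frac, upper_frac)
  structure(list(cell_line_ids = act$cell_line_ids, class = cls,
                 lower_frac = lower_frac, upper_frac = upper_frac,
                 cuts = c(lower = ql, upper = qu)),
            class = "sensitivity_classing")
}

# Vectorized Welch two-sample t over matrix rows (group1 minus group2).
# Genes constant within BOTH groups get statistic 0, p 1 and flagged = TRUE.
.row_welch <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1L)
  se2 <- v1 / n1 + v2 / n2
  flagged <- se2 <= 0
  stat <- ifelse(flagged, 0, (m1 - m2) / sqrt(se2))
  df <- ifelse(flagged, 1,
               se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L)))
  p <- ifelse(flagged, 1, 2 * stats::pt(-abs(stat), df))
  list(statistic = stat, df = df, p_value = p, flagged = flagged)
}

.biomarker_set <- function(full, fdr, panel_label, drug_name, method) {
  sig <- full[full$q_value < fdr, , drop = FALSE]
  ord <- order(-abs(sig$statistic), sig$gene_id)
  records <- sig[ord, , drop = FALSE]
  rownames(records) <- NULL
  structure(list(records = records, full = full, fdr = fdr,
                 panel_label = panel_label, drug_name = drug_name,
                 method = method),
            class = "biomarker_set")
}

#' @export
print.biomarker_set <- function(x, ...) {
  cat(sprintf("<biomarker_set> %s / %s (%s): %d of %d genes significant at FDR < %g\n",
              x$panel_label, x$drug_name, x$method,
              nrow(x$records), nrow(x$full), x$fdr))
  invisible(x)
}

#' Discover drug-sensitivity biomarkers by Welch t-test
#'
#' Per gene, Welch two-sample t statistic (sensitive minus resistant), two-sided
#' p, and Benjamini-Hochberg q over all genes tested. The returned set contains
#' the genes with `q < fdr`, sorted by |t| descending (ties broken
#' lexicographically). Genes constant within both classes are assigned p = 1 and
#' flagged rather than dropped, so gene indexing stays stable across steps.
#'
#' @param expr Cell-panel [expression_matrix()].
#' @param classing A [classify_sensitivity()] result.
#' @param fdr FDR level (default 0.05).
#' @param drug_name Drug label.
#' @return A `"biomarker_set"` with `$records` (significant genes) and `$full`
#'   (all genes tested, input order).
#' @export
discover_ttest <- function(expr, classing, fdr = 0.05,
                           drug_name = "drug") {
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(classing, "sensitivity_classing"))
  sens <- intersect(names(classing$class)[classing$class == "sensitive"],
                    sample_ids(expr))
  res <- intersect(names(classing$class)[classing$class == "resistant"],
                   sample_ids(expr))
  if (length(sens) < 2L || length(res) < 2L)
    .stopf("need >= 2 cell lines per extreme class in the expression matrix")
  w <- .row_welch(expr$values[, sens, drop = FALSE],
                  expr$values[, res, drop = FALSE])
  full <- data.frame(gene_id = gene_ids(expr), statistic = w$statistic,
                     p_value = w$p_value, q_value = bh_fdr(w$p_value),
                     direction = sign(w$statistic), flagged = w$flagged,
                     stringsAsFactors = FALSE)
  .biomarker_set(full, fdr, expr$system_label, drug_name, "ttest")
}

#' Discover drug-sensitivity biomarkers by correlation with activity
#'
#' Per gene, Pearson correlation with the drug-activity vector, two-sided
#' t-distributed test p, BH q. The set holds genes with `q < fdr` sorted by |r|
#' descending. Constant genes get p = 1 and are flagged.
#'
#' @param expr Cell-panel [expression_matrix()]; samples must equal the
#'   activity's cell-line set.
#' @param act A [drug_activity()].
#' @param fdr FDR level (default 0.05).
#' @param method `"pearson"` (default, matches the downstream linear modeling)
#'   or `"spearman"`.
#' @return A `"biomarker_set"`; `statistic` is the correlation coefficient.
#' @export
discover_correlation <- function(expr, act, fdr = 0.05,
                                 method = c("pearson", "spearman")) {
  stopifnot(inherits(expr, "expression_matrix"), inherits(act, "drug_activity"))
  method <- match.arg(method)
  if (!setequal(sample_ids(expr), act$cell_line_ids))
    .stopf("expression samples and activity cell lines differ")
  v <- expr$values[, act$cell_line_ids, drop = FALSE]
  y <- act$activity
  if (method == "spearman") {
    v <- t(apply(v, 1L, rank))
    y <- rank(y)
  }
  n <- length(y)
  xc <- v - rowMeans(v)
  yc <- y - mean(y)
  sxx <- rowSums(xc^2); syy <- sum(yc^2)
  flagged <- sxx <= 0
  r <- as.vector(xc %*% yc) / sqrt(pmax(sxx, .Machine$double.xmin) * syy)
  r <- pmin(pmax(r, -1), 1)
  r[flagged] <- 0
  tstat <- r * sqrt((n - 2L) / pmax(1 - r^2, 0))   # Inf at |r| = 1
  p <- ifelse(flagged, 1, 2 * stats::pt(-abs(tstat), n - 2L))
  full <- data.frame(gene_id = gene_ids(expr), statistic = r,
                     p_value = p, q_value = bh_fdr(p),
                     direction = sign(r), flagged = flagged,
                     stringsAsFactors = FALSE)
  .biomarker_set(full, fdr, expr$system_label, act$drug_name,
                 paste0("correlation_", method))
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q_(i) = min_(j >= i) (p_(j) * m / j)`, capped at 1; input order preserved.
#'
#' @param p_values Vector of p-values in `[0, 1]`.
#' @return Vector of q-values in the same order.
#' @export
bh_fdr <- function(p_values) {
  p <- as.numeric(p_values)
  if (anyNA(p) || any(p < 0 | p > 1))
    .stopf("p-values must lie in [0, 1] with no missing values")
  stats::p.adjust(p, method = "BH")
}

#' Choose the most informative cell-line panel
#'
#' Returns the candidate biomarker set with the largest number of significant
#' records; ties are broken by lexicographic `panel_label` order.
#'
#' @param candidate_sets List of `"biomarker_set"` objects.
#' @return The chosen `"biomarker_set"`.
#' @export
select_panel <- function(candidate_sets) {
  if (length(candidate_sets) < 1L) .stopf("need at least one candidate panel")
  stopifnot(all(vapply(candidate_sets, inherits, logical(1L), "biomarker_set")))
  counts <- vapply(candidate_sets, function(s) nrow(s$records), integer(1L))
  if (all(counts == 0L)) .stopf("no informative panel: all candidates empty")
  labels <- vapply(candidate_sets, function(s) s$panel_label, character(1L))
  candidate_sets[[order(-counts, labels)[1L]]]
}
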