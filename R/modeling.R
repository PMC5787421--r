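# modeling: principal-component regression on cell-line data over a grid of
# biomarker-set sizes, patient percentile scoring, model selection on the
# largest original-cancer cohort, Youden-J decision threshold.

#' Fit a principal-component regression drug-response model
#'
#' Genes are standardized by their training means/SDs, principal components are
#' computed on the standardized samples-by-genes matrix, the smallest number of
#' components whose cumulative explained variance reaches `variance_frac` is
#' retained (at least 1, at most `training samples - 2`), and drug activity is
#' regressed on the component scores by ordinary least squares. The model
#' stores everything needed to score new samples without the training data.
#'
#' @param cell_expr Training [expression_matrix()].
#' @param act [drug_activity()] whose cell lines equal the training samples.
#' @param genes Gene ids to model (at least 2, all present, none constant).
#' @param variance_frac Cumulative explained-variance target (default 0.8).
#' @return An object of class `"pcr_model"`.
#' @export
fit_pcr <- function(cell_expr, act, genes, variance_frac = 0.8) {
  stopifnot(inherits(cell_expr, "expression_matrix"), inherits(act, "drug_activity"))
  genes <- as.character(genes)
  if (length(genes) < 2L) .stopf("need at least 2 model genes")
  missing <- setdiff(genes, gene_ids(cell_expr))
  if (length(missing))
    .stopf("model gene(s) absent from training panel: %s",
           paste(utils::head(missing, 5L), collapse = ", "))
  if (!setequal(sample_ids(cell_expr), act$cell_line_ids))
    .stopf("training samples and activity cell lines differ")
  v <- cell_expr$values[genes, act$cell_line_ids, drop = FALSE]
  n <- ncol(v)
  if (n < 4L) .stopf("need at least 4 training samples")
  mu <- rowMeans(v)
  sds <- sqrt(rowSums((v - mu)^2) / (n - 1L))
  const <- sds <= 1e-12 * pmax(abs(mu), 1)
  if (any(const))
    .stopf("constant training gene(s): %s",
           paste(utils::head(genes[const], 5L), collapse = ", "))
  x <- t((v - mu) / sds)                      # samples x genes, standardized
  sv <- svd(x)
  var_share <- sv$d^2 / sum(sv$d^2)
  k <- which(cumsum(var_share) >= variance_frac)[1L]
  if (is.na(k)) k <- length(var_share)
  k <- max(1L, k)
  kmax <- min(length(genes), n - 2L, sum(sv$d > 1e-8 * sv$d[1L]))
  if (k > kmax) {
    .warnf("retained components clamped from %d to %d", k, kmax)
    k <- kmax
  }
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  dimnames(loadings) <- list(genes, paste0("PC", seq_len(k)))
  scores <- x %*% loadings
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, scores), act$activity)
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0
  fitted <- drop(cbind(1, scores) %*% coefs)
  names(fitted) <- act$cell_line_ids
  structure(list(gene_ids = genes, train_gene_means = mu, train_gene_sds = sds,
                 pc_loadings = loadings, coefficients = coefs, k = k,
                 variance_share = var_share[seq_len(k)],
                 n_train = n, drug_name = act$drug_name,
                 fitted = fitted, threshold = NULL),
            class = "pcr_model")
}

#' @export
print.pcr_model <- function(x, ...) {
  cat(sprintf("<pcr_model> %s: %d genes, %d PCs (%.0f%% variance), %d training samples%s\n",
              x$drug_name, length(x$gene_ids), x$k,
              100 * sum(x$variance_share), x$n_train,
              if (is.null(x$threshold)) "" else
                sprintf(", threshold %.3f", x$threshold)))
  invisible(x)
}

#' Score a patient cohort with a fitted model
#'
#' Cohort genes are z-scored within the cohort (the package's cross-platform
#' harmonization), projected on the stored PC loadings, and passed through the
#' regression; larger raw scores mean predicted more sensitive. Raw scores are
#' converted to percentile scores within this cohort only (average-rank ties,
#' 1 = most sensitive). Cohorts with fewer than 3 samples fall back to the
#' training standardization constants, with a warning.
#'
#' @param model A `"pcr_model"`.
#' @param cohort_expr [expression_matrix()] containing every model gene.
#' @return A `data.frame` of class `"patient_scores"` with `sample_id`,
#'   `raw_score`, `percentile`.
#' @export
score_cohort <- function(model, cohort_expr) {
  stopifnot(inherits(model, "pcr_model"), inherits(cohort_expr, "expression_matrix"))
  missing <- setdiff(model$gene_ids, gene_ids(cohort_expr))
  if (length(missing))
    .stopf("model gene(s) missing from cohort: %s",
           paste(missing, collapse = ", "))
  v <- cohort_expr$values[model$gene_ids, , drop = FALSE]
  n <- ncol(v)
  z <- if (n >= 3L) {
    .zscore_rows(v)
  } else {
    .warnf("cohort has %d sample(s); using training standardization", n)
    (v - model$train_gene_means) / model$train_gene_sds
  }
  scores <- t(z) %*% model$pc_loadings
  raw <- drop(cbind(1, scores) %*% model$coefficients)
  if (n == 1L) .warnf("single-patient cohort: percentile fixed at 1")
  out <- data.frame(sample_id = colnames(v), raw_score = unname(raw),
                    percentile = unname(.percentile_ranks(raw)),
                    stringsAsFactors = FALSE)
  class(out) <- c("patient_scores", "data.frame")
  out
}

#' Nested candidate gene subsets over a size grid
#'
#' Concordant biomarkers are ranked by the absolute value of their initial
#' discovery statistic (ties broken lexicographically) and truncated at sizes
#' `grid_step, 2*grid_step, ...`, always including the full concordant set.
#' Subsets are strictly nested.
#'
#' @param concord `"concord_biomarkers"` or gene-id character vector.
#' @param initial_ranking The discovery `"biomarker_set"` (its `$full` table
#'   must cover every concordant gene).
#' @param grid_step Size increment (default 4).
#' @param sizes Optional explicit size vector overriding the default grid.
#' @return Named list of gene-id vectors (`size_<m>`), sizes ascending.
#' @export
candidate_grid <- function(concord, initial_ranking, grid_step = 4L, sizes = NULL) {
  genes <- if (inherits(concord, "concord_biomarkers"))
    concord$gene_ids else as.character(concord)
  if (!length(genes)) .stopf("no concordant biomarkers to grid")
  stopifnot(inherits(initial_ranking, "biomarker_set"))
  tbl <- initial_ranking$full
  missing <- setdiff(genes, tbl$gene_id)
  if (length(missing))
    .stopf("ranking does not cover gene(s): %s",
           paste(utils::head(missing, 5L), collapse = ", "))
  stat <- stats::setNames(tbl$statistic, tbl$gene_id)[genes]
  ranked <- genes[order(-abs(stat), genes)]
  nc <- length(ranked)
  if (is.null(sizes))
    sizes <- if (nc >= grid_step) seq(grid_step, nc, by = grid_step) else integer(0)
  sizes <- sort(unique(c(as.integer(sizes), nc)))
  sizes <- sizes[sizes >= 2L & sizes <= nc]
  if (!length(sizes)) .stopf("grid produces no subset of size >= 2")
  out <- lapply(sizes, function(m) ranked[seq_len(m)])
  names(out) <- paste0("size_", sizes)
  out
}

# Youden threshold over midpoints of consecutive distinct scores.
# Predicted positive = score >= threshold; ties in J resolved toward the
# larger cut (higher specificity).
.youden_threshold <- function(scores, labels) {
  u <- sort(unique(scores))
  if (length(u) < 2L) .stopf("all evaluation scores identical; no threshold")
  mids <- (u[-1L] + u[-length(u)]) / 2
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  j <- vapply(mids, function(t) {
    pos <- scores >= t
    sum(pos & labels == 1) / npos + sum(!pos & labels == 0) / nneg - 1
  }, numeric(1L))
  best <- max(j)
  list(threshold = max(mids[j >= best - 1e-12]), youden_j = best)
}

#' Select the final model and fix the decision threshold
#'
#' Each candidate model scores the evaluation cohort; percentile scores are
#' compared to the binary response by ROC AUC with a one-sided
#' Mann-Whitney-Wilcoxon p. Among candidates significant at `alpha` the highest
#' AUC wins, ties going to the smallest gene count (parsimony); if none is
#' significant the maximum AUC is chosen with a warning. The decision threshold
#' is the evaluation-cohort percentile score maximizing Youden's J
#' (specificity + sensitivity - 1), taken at midpoints between consecutive
#' distinct scores; J-ties resolve to the larger cut.
#'
#' @param candidates List of `"pcr_model"` objects.
#' @param eval_expr Evaluation-cohort [expression_matrix()].
#' @param eval_response A [phenotype_table()] with binary response for every
#'   evaluation sample (both classes present).
#' @param alpha Significance level for the selection rule (default 0.05).
#' @return A list of class `"model_selection"`: per-candidate `table`,
#'   `chosen_index`, the chosen `model` (threshold attached), `threshold`,
#'   `youden_j`.
#' @export
select_model <- function(candidates, eval_expr, eval_response, alpha = 0.05) {
  stopifnot(length(candidates) >= 1L,
            all(vapply(candidates, inherits, logical(1L), "pcr_model")),
            inherits(eval_expr, "expression_matrix"),
            inherits(eval_response, "phenotype_table"))
  idx <- match(sample_ids(eval_expr), eval_response$sample_id)
  if (anyNA(idx)) .stopf("phenotype missing for evaluation sample(s)")
  resp <- eval_response$response[idx]
  if (anyNA(resp)) .stopf("binary response required for every evaluation sample")
  if (length(unique(resp)) < 2L) .stopf("degenerate response: only one class present")
  score_list <- lapply(candidates, score_cohort, cohort_expr = eval_expr)
  rocs <- lapply(score_list, function(s) roc_auc(s$percentile, resp))
  tab <- data.frame(
    candidate = if (is.null(names(candidates)))
      paste0("model_", seq_along(candidates)) else names(candidates),
    n_genes = vapply(candidates, function(m) length(m$gene_ids), integer(1L)),
    auc = vapply(rocs, function(r) r$auc, numeric(1L)),
    auc_se = vapply(rocs, function(r) r$se, numeric(1L)),
    auc_p = vapply(rocs, function(r) r$p_value, numeric(1L)),
    stringsAsFactors = FALSE)
  sig <- which(tab$auc_p < alpha)
  pool <- if (length(sig)) sig else {
    .warnf("no candidate significant at %g; choosing maximum AUC", alpha)
    seq_len(nrow(tab))
  }
  chosen <- pool[order(-tab$auc[pool], tab$n_genes[pool])][1L]
  tab$selected <- seq_len(nrow(tab)) == chosen
  yt <- .youden_threshold(score_list[[chosen]]$percentile, resp)
  model <- candidates[[chosen]]
  model$threshold <- yt$threshold
  structure(list(table = tab, chosen_index = chosen, model = model,
                 threshold = yt$threshold, youden_j = yt$youden_j,
                 alpha = alpha),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat(sprintf("<model_selection> chose candidate %d (%d genes, AUC %.3f), threshold %.3f (J = %.3f)\n",
              x$chosen_index, x$table$n_genes[x$chosen_index],
              x$table$auc[x$chosen_index], x$threshold, x$youden_j))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Serialize / restore a fitted model as JSON
#'
#' The JSON document is the package's single model interchange format and
#' round-trips exactly (full-precision numbers).
#'
#' @param model A `"pcr_model"`.
#' @return `model_to_json` returns a JSON string; `write_model` writes it and
#'   returns the path invisibly; `read_model` reconstructs the model.
#' @export
model_to_json <- function(model) {
  stopifnot(inherits(model, "pcr_model"))
  payload <- list(
    format = "concord_pcr_model_v1",
    drug_name = model$drug_name,
    gene_ids = model$gene_ids,
    train_gene_means = unname(model$train_gene_means),
    train_gene_sds = unname(model$train_gene_sds),
    pc_loadings = lapply(seq_len(ncol(model$pc_loadings)),
                         function(j) unname(model$pc_loadings[, j])),
    coefficients = unname(model$coefficients),
    k = model$k,
    variance_share = model$variance_share,
    n_train = model$n_train,
    threshold = model$threshold)
  jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE, null = "null")
}

#' @rdname model_to_json
#' @param path File path for the model JSON.
#' @export
write_model <- function(model, path) {
  writeLines(model_to_json(model), path)
  invisible(path)
}

#' @rdname model_to_json
#' @export
read_model <- function(path) {
  if (!file.exists(path)) .stopf("model file not found: %s", path)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "concord_pcr_model_v1"))
    .stopf("%s is not a concord model JSON", path)
  genes <- as.character(p$gene_ids)
  # JSON stores loadings as an array of k gene-length arrays
  loadings <- if (is.matrix(p$pc_loadings)) t(p$pc_loadings)
    else if (is.list(p$pc_loadings)) do.call(cbind, lapply(p$pc_loadings, as.numeric))
    else matrix(as.numeric(p$pc_loadings), ncol = 1L)
  dimnames(loadings) <- list(genes, paste0("PC", seq_len(ncol(loadings))))
  coefs <- as.numeric(p$coefficients)
  names(coefs) <- c("(Intercept)", paste0("PC", seq_len(length(coefs) - 1L)))
  structure(list(gene_ids = genes,
                 train_gene_means = stats::setNames(as.numeric(p$train_gene_means), genes),
                 train_gene_sds = stats::setNames(as.numeric(p$train_gene_sds), genes),
                 pc_loadings = loadings, coefficients = coefs,
                 k = as.integer(p$k),
                 variance_share = as.numeric(p$variance_share),
                 n_train = as.integer(p$n_train),
                 drug_name = p$drug_name, fitted = NULL,
                 threshold = if (is.null(p$threshold)) NULL else as.numeric(p$threshold)),
            class = "pcr_model")
}
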