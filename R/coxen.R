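# coxen: COXEN coefficients between cancer systems, permutation null,
# wCOXEN/bCOXEN cancer-type gate, three-way concordant biomarker triage.

#' Gene-gene Pearson correlation matrix
#'
#' @param expr An [expression_matrix()] with at least 3 samples.
#' @param genes Gene ids to include (default: all); all must be present and
#'   non-constant.
#' @return An object of class `"correlation_matrix"`: symmetric, unit diagonal.
#' @export
gene_correlation_matrix <- function(expr, genes = gene_ids(expr)) {
  stopifnot(inherits(expr, "expression_matrix"))
  genes <- as.character(genes)
  missing <- setdiff(genes, gene_ids(expr))
  if (length(missing))
    .stopf("gene(s) not present: %s", paste(utils::head(missing, 5L), collapse = ", "))
  if (length(genes) < 2L) .stopf("need at least 2 genes")
  v <- expr$values[genes, , drop = FALSE]
  if (ncol(v) < 3L) .stopf("need at least 3 samples")
  mu <- rowMeans(v)
  sds <- sqrt(rowSums((v - mu)^2) / (ncol(v) - 1L))
  const <- sds <= 1e-12 * pmax(abs(mu), 1)
  if (any(const))
    .stopf("constant gene(s): %s",
           paste(utils::head(genes[const], 5L), collapse = ", "))
  cm <- stats::cor(t(v))
  cm <- (cm + t(cm)) / 2
  diag(cm) <- 1
  structure(list(gene_ids = genes, values = cm, source_label = expr$system_label),
            class = "correlation_matrix")
}

# rc(j) for all j at once. Pearson correlation between column j of U and
# column j of V over k = 1..n ("included", the formula as printed) or k != j
# ("excluded"). Zero-variance columns yield NA (flagged, never fabricated).
.rc_vector <- function(U, V, diagonal_mode = "excluded") {
  n <- nrow(U)
  if (diagonal_mode == "included") {
    m <- n
    su <- colSums(U);      sv <- colSums(V)
    suv <- colSums(U * V)
    suu <- colSums(U * U); svv <- colSums(V * V)
  } else {
    m <- n - 1L
    du <- diag(U); dv <- diag(V)
    su <- colSums(U) - du;      sv <- colSums(V) - dv
    suv <- colSums(U * V) - du * dv
    suu <- colSums(U * U) - du^2; svv <- colSums(V * V) - dv^2
  }
  num <- suv - su * sv / m
  vu <- suu - su^2 / m
  vv <- svv - sv^2 / m
  tol <- 1e-12 * m
  rc <- ifelse(vu <= tol | vv <= tol, NA_real_,
               num / sqrt(pmax(vu, tol) * pmax(vv, tol)))
  pmin(pmax(rc, -1), 1)
}

#' COXEN coefficients between two cancer systems
#'
#' For each gene j, `rc(j)` is the Pearson correlation between column j of the
#' first system's gene-gene correlation matrix and column j of the second
#' system's: the degree to which gene j's co-expression relationships with the
#' other genes agree across the two systems. `diagonal_mode = "included"` sums
#' over k = 1..n, reproducing the literal formula (the constant (j,j) pair
#' inflates rc toward +1); the default `"excluded"` sums over k != j, which
#' preserves the exact anti-concordance identity rc = -1 when off-diagonal
#' correlations are negated.
#'
#' @param U,V `"correlation_matrix"` objects with identical gene ids in
#'   identical order; at least 3 genes.
#' @param diagonal_mode `"excluded"` (default) or `"included"`.
#' @param pair_label Label identifying the system pair.
#' @return An object of class `"coxen_coefficients"` with per-gene `rc`
#'   (NA where a column has zero variance).
#' @export
coxen_coefficients <- function(U, V, diagonal_mode = c("excluded", "included"),
                               pair_label = paste(U$source_label, "vs", V$source_label)) {
  stopifnot(inherits(U, "correlation_matrix"), inherits(V, "correlation_matrix"))
  diagonal_mode <- match.arg(diagonal_mode)
  if (!identical(U$gene_ids, V$gene_ids))
    .stopf("gene ids/order mismatch between the two correlation matrices")
  if (length(U$gene_ids) < 3L) .stopf("need at least 3 genes")
  rc <- .rc_vector(U$values, V$values, diagonal_mode)
  names(rc) <- U$gene_ids
  structure(list(gene_ids = U$gene_ids, rc = rc, pair_label = pair_label,
                 diagonal_mode = diagonal_mode, p_values = NULL),
            class = "coxen_coefficients")
}

#' @export
print.coxen_coefficients <- function(x, ...) {
  cat(sprintf("<coxen_coefficients> %s (%d genes, diagonal %s): median rc = %.3f\n",
              x$pair_label, length(x$rc), x$diagonal_mode,
              stats::median(x$rc, na.rm = TRUE)))
  invisible(x)
}

#' Permutation null for COXEN coefficients
#'
#' Builds the null by B random permutations of gene identity in system B
#' (rows and columns of its correlation matrix permuted jointly), so each
#' system's internal correlation structure is preserved while the cross-system
#' gene correspondence -- exactly what COXEN measures -- is destroyed.
#' Per-gene two-sided p-values are add-one smoothed fractions of pooled null
#' |rc| values at or above the observed |rc(j)|; `null_mode = "per_gene"` uses
#' only that gene's B null draws instead of the pooled B x n values. The
#' cut-off is the configured percentile (default 98, i.e. 2% total on |rc|)
#' of the pooled |null| distribution.
#'
#' @param exprA,exprB [expression_matrix()] objects for the two systems.
#' @param genes Gene ids to analyse (aligned across the systems).
#' @param B Number of permutations, at least 100.
#' @param seed Optional seed; identical seed gives identical output.
#' @param percentile Null percentile for the cut-off (default 98).
#' @param diagonal_mode Passed to [coxen_coefficients()].
#' @param null_mode `"pooled"` (default) or `"per_gene"`.
#' @return A list of class `"coxen_null"`: `gene_ids`, `rc`, `p_values`,
#'   `cutoff`, `exceeds_cutoff`, plus the call parameters.
#' @export
coxen_null <- function(exprA, exprB, genes, B = 500L, seed = NULL,
                       percentile = 98, diagonal_mode = c("excluded", "included"),
                       null_mode = c("pooled", "per_gene")) {
  diagonal_mode <- match.arg(diagonal_mode)
  null_mode <- match.arg(null_mode)
  if (B < 100L) .stopf("null too coarse: B must be at least 100")
  al <- align_by_common_genes(exprA, exprB, genes)
  U <- gene_correlation_matrix(al$a)
  V <- gene_correlation_matrix(al$b)
  n <- length(U$gene_ids)
  rc_obs <- .rc_vector(U$values, V$values, diagonal_mode)
  names(rc_obs) <- U$gene_ids
  nulls <- .with_seed(seed, {
    vapply(seq_len(B), function(b) {
      p <- sample.int(n)
      .rc_vector(U$values, V$values[p, p, drop = FALSE], diagonal_mode)
    }, numeric(n))
  })  # n x B
  abs_null <- abs(nulls)
  pooled <- as.vector(abs_null[is.finite(abs_null)])
  cutoff <- stats::quantile(pooled, percentile / 100, names = FALSE)
  obs <- abs(rc_obs)
  p_values <- if (null_mode == "pooled") {
    vapply(obs, function(o) {
      if (!is.finite(o)) return(NA_real_)
      (1 + sum(pooled >= o)) / (1 + length(pooled))
    }, numeric(1L))
  } else {
    vapply(seq_len(n), function(j) {
      nj <- abs_null[j, ]; nj <- nj[is.finite(nj)]
      if (!is.finite(obs[j])) return(NA_real_)
      (1 + sum(nj >= obs[j])) / (1 + length(nj))
    }, numeric(1L))
  }
  names(p_values) <- U$gene_ids
  structure(list(gene_ids = U$gene_ids, rc = rc_obs, p_values = p_values,
                 cutoff = cutoff, exceeds_cutoff = !is.na(rc_obs) & obs > cutoff,
                 B = B, percentile = percentile, seed = seed,
                 diagonal_mode = diagonal_mode, null_mode = null_mode,
                 pair_label = paste(exprA$system_label, "vs", exprB$system_label)),
            class = "coxen_null")
}

#' COXEN coefficients of a biomarker list between two cohorts
#'
#' Convenience composition: align the cohorts on the biomarkers, build the two
#' gene-gene correlation matrices, and compute [coxen_coefficients()].
#'
#' @param biomarkers Gene-id character vector (or a `"biomarker_set"`).
#' @param cohortA,cohortB [expression_matrix()] objects.
#' @param diagonal_mode Passed through.
#' @return A `"coxen_coefficients"` labeled by the cohort pair.
#' @export
coxen_distribution <- function(biomarkers, cohortA, cohortB,
                               diagonal_mode = c("excluded", "included")) {
  diagonal_mode <- match.arg(diagonal_mode)
  genes <- if (inherits(biomarkers, "biomarker_set"))
    biomarkers$records$gene_id else as.character(biomarkers)
  al <- align_by_common_genes(cohortA, cohortB, genes)
  coxen_coefficients(gene_correlation_matrix(al$a),
                     gene_correlation_matrix(al$b),
                     diagonal_mode = diagonal_mode)
}

.rc_values <- function(x, what = "coefficient set") {
  rc <- if (inherits(x, "coxen_coefficients") || inherits(x, "coxen_null"))
    x$rc else as.numeric(x)
  rc <- rc[is.finite(rc)]
  if (!length(rc)) .stopf("empty %s", what)
  rc
}

.coxen_label <- function(x, fallback) {
  if (!is.null(x$pair_label)) x$pair_label else fallback
}

#' Gate candidate cancer types by wCOXEN vs bCOXEN comparison
#'
#' The reference is the within-cancer (wCOXEN) coefficient set with the lowest
#' median. Each candidate's between-cancer (bCOXEN) set is compared to it by a
#' one-sided Wilcoxon rank-sum test (alternative: the candidate's median is
#' LOWER than the reference), Bonferroni-adjusted by the number of candidates.
#' A candidate cancer type is suitable for cross-cancer prediction when its
#' adjusted p exceeds `alpha` -- i.e. its concordance is not significantly
#' worse than concordance within the original cancer type.
#'
#' @param wcoxen_sets List of within-cancer `"coxen_coefficients"` (or numeric
#'   rc vectors), at least one.
#' @param bcoxen_sets List of candidate between-cancer sets, at least one.
#' @param alpha One-sided significance level (default 0.025).
#' @return A `data.frame` of class `"coxen_gate"`, one row per candidate,
#'   sorted by raw p ascending, with attributes `reference_label`,
#'   `reference_median`, `alpha`.
#' @export
gate_cancer_types <- function(wcoxen_sets, bcoxen_sets, alpha = 0.025) {
  if (inherits(wcoxen_sets, "coxen_coefficients")) wcoxen_sets <- list(wcoxen_sets)
  if (inherits(bcoxen_sets, "coxen_coefficients")) bcoxen_sets <- list(bcoxen_sets)
  if (length(wcoxen_sets) < 1L || length(bcoxen_sets) < 1L)
    .stopf("need at least one wCOXEN and one bCOXEN set")
  w_rc <- lapply(wcoxen_sets, .rc_values, what = "wCOXEN set")
  b_rc <- lapply(bcoxen_sets, .rc_values, what = "bCOXEN set")
  w_med <- vapply(w_rc, stats::median, numeric(1L))
  ref_i <- which.min(w_med)
  ref <- w_rc[[ref_i]]
  labs <- names(bcoxen_sets)
  if (is.null(labs)) labs <- rep(NA_character_, length(bcoxen_sets))
  labs <- ifelse(is.na(labs) | !nzchar(labs),
                 vapply(seq_along(bcoxen_sets), function(i)
                   .coxen_label(bcoxen_sets[[i]], paste0("candidate_", i)),
                   character(1L)),
                 labs)
  k <- length(b_rc)
  raw_p <- vapply(b_rc, function(b) rank_sum_test(b, ref, "less"), numeric(1L))
  out <- data.frame(
    candidate = labs,
    median_bcoxen = vapply(b_rc, stats::median, numeric(1L)),
    p_value = raw_p,
    p_adjusted = pmin(1, raw_p * k),
    suitable = pmin(1, raw_p * k) > alpha,
    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$candidate), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "reference_label") <- .coxen_label(wcoxen_sets[[ref_i]],
                                               paste0("wcoxen_", ref_i))
  attr(out, "reference_median") <- w_med[ref_i]
  attr(out, "alpha") <- alpha
  class(out) <- c("coxen_gate", "data.frame")
  out
}

#' @export
print.coxen_gate <- function(x, ...) {
  cat(sprintf("<coxen_gate> reference %s (median %.3f), alpha %g one-sided\n",
              attr(x, "reference_label"), attr(x, "reference_median"),
              attr(x, "alpha")))
  print.data.frame(x)
  invisible(x)
}

#' Three-way concordant (CONCORD) biomarker triage
#'
#' Runs the COXEN permutation analysis for the three system pairs -- cell panel
#' vs original cancer, cell panel vs new cancer, original vs new cancer --
#' converts permutation p-values to BH q-values within each pair, and keeps the
#' genes significant (`q < fdr`) in ALL three pairs.
#'
#' @param initial A `"biomarker_set"` or gene-id character vector.
#' @param cell_expr,cohortA_expr,cohortB_expr The three systems.
#' @param fdr Per-pair FDR (default 0.2).
#' @param B Permutations per pair.
#' @param seed Optional seed; pair-specific seeds are derived from it.
#' @param diagonal_mode,null_mode Passed to [coxen_null()].
#' @return A list of class `"concord_biomarkers"`: surviving `gene_ids`,
#'   per-pair tables (`rc`, `p`, `q`), survivor `counts`.
#' @export
threeway_select <- function(initial, cell_expr, cohortA_expr, cohortB_expr,
                            fdr = 0.2, B = 500L, seed = NULL,
                            diagonal_mode = c("excluded", "included"),
                            null_mode = c("pooled", "per_gene")) {
  diagonal_mode <- match.arg(diagonal_mode)
  null_mode <- match.arg(null_mode)
  genes <- if (inherits(initial, "biomarker_set"))
    initial$records$gene_id else as.character(initial)
  systems <- list(cell = cell_expr, cohortA = cohortA_expr, cohortB = cohortB_expr)
  common <- sort(Reduce(intersect, c(list(genes), lapply(systems, gene_ids))))
  if (length(common) < 3L)
    .stopf("fewer than 3 initial biomarkers shared by all three systems")
  pairs <- list(cell_vs_A = c("cell", "cohortA"),
                cell_vs_B = c("cell", "cohortB"),
                A_vs_B = c("cohortA", "cohortB"))
  per_pair <- vector("list", length(pairs)); names(per_pair) <- names(pairs)
  survivors <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    s_i <- if (is.null(seed)) NULL else as.integer(seed) + i
    nr <- coxen_null(systems[[pr[1L]]], systems[[pr[2L]]], common, B = B,
                     seed = s_i, diagonal_mode = diagonal_mode,
                     null_mode = null_mode)
    p <- nr$p_values
    p[is.na(p)] <- 1   # undefined rc cannot count as concordant
    q <- bh_fdr(p)
    per_pair[[i]] <- data.frame(gene_id = nr$gene_ids, rc = unname(nr$rc),
                                p_value = unname(p), q_value = q,
                                stringsAsFactors = FALSE)
    survivors[[i]] <- nr$gene_ids[q < fdr]
  }
  keep <- Reduce(intersect, survivors)
  counts <- c(vapply(survivors, length, integer(1L)), intersection = length(keep))
  names(counts)[1:3] <- names(pairs)
  if (length(keep) < 3L)
    .warnf("three-way triage kept only %d gene(s)", length(keep))
  structure(list(gene_ids = keep, per_pair = per_pair, counts = counts,
                 initial_gene_ids = common, fdr = fdr, B = B, seed = seed,
                 pair_labels = vapply(pairs, paste, character(1L), collapse = " vs ")),
            class = "concord_biomarkers")
}

#' @export
print.concord_biomarkers <- function(x, ...) {
  cat(sprintf("<concord_biomarkers> %d of %d initial genes concordant in all three pairs (FDR < %g)\n",
              length(x$gene_ids), length(x$initial_gene_ids), x$fdr))
  print(x$counts)
  invisible(x)
}
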