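# io_core: data model, TSV readers/writers, gene-space alignment,
# per-gene standardization, run configuration.

#' Construct a genes-by-samples expression matrix
#'
#' The central container of the package: a numeric matrix of log-scale
#' expression values with genes in rows and samples in columns, plus a free-text
#' label naming the system it came from (e.g. `"cell_panel"`,
#' `"breast_cohort_A"`). Gene and sample identifiers are opaque strings; any
#' probe-to-gene mapping must happen before construction.
#'
#' @param values Numeric matrix with unique, non-empty rownames (gene ids) and
#'   colnames (sample ids); all entries finite; at least 3 samples.
#' @param system_label Free-text label for the system.
#' @return An object of class `"expression_matrix"`.
#' @export
expression_matrix <- function(values, system_label = "unlabeled") {
  if (!is.matrix(values) || !is.numeric(values))
    .stopf("`values` must be a numeric matrix")
  g <- rownames(values); s <- colnames(values)
  if (is.null(g) || is.null(s))
    .stopf("`values` must have gene rownames and sample colnames")
  if (anyDuplicated(g))
    .stopf("duplicate gene_id(s): %s",
           paste(unique(g[duplicated(g)]), collapse = ", "))
  if (anyDuplicated(s))
    .stopf("duplicate sample_id(s): %s",
           paste(unique(s[duplicated(s)]), collapse = ", "))
  if (any(!nzchar(g)) || any(!nzchar(s)))
    .stopf("empty gene or sample identifier")
  if (ncol(values) < 3L)
    .stopf("expression matrix needs at least 3 samples, got %d", ncol(values))
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    .stopf("non-finite expression value at gene \"%s\", sample \"%s\"",
           g[bad[1L]], s[bad[2L]])
  }
  structure(list(values = values, system_label = as.character(system_label)[1L]),
            class = "expression_matrix")
}

#' @rdname expression_matrix
#' @param x An `expression_matrix`.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname expression_matrix
#' @export
sample_ids <- function(x) colnames(x$values)

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$system_label))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

# Parse a character column to numeric, naming the offending cell on failure.
.parse_numeric_column <- function(col, genes, sample_id) {
  trimmed <- trimws(col)
  v <- suppressWarnings(as.numeric(trimmed))
  bad <- which(is.na(v) | !nzchar(trimmed))
  if (length(bad))
    .stopf("non-numeric or missing value \"%s\" at gene \"%s\", sample \"%s\"",
           col[bad[1L]], genes[bad[1L]], sample_id)
  v
}

#' Read an expression matrix from TSV
#'
#' File dialect: one header row of sample ids, first column header `gene_id`,
#' genes in rows, tab-separated numeric body. Loading is strict: duplicate
#' identifiers and non-numeric/missing cells are rejected with an error naming
#' the offender.
#'
#' @param path Path to a TSV file.
#' @param system_label Label for the loaded system; defaults to the file name
#'   without extension.
#' @param fmt File format; only `"tsv"` is supported.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path,
                                   system_label = sub("\\.[^.]*$", "", basename(path)),
                                   fmt = "tsv") {
  fmt <- match.arg(fmt, "tsv")
  if (!file.exists(path)) .stopf("file not found: %s", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) .stopf("%s: expected a gene_id column plus sample columns", path)
  genes <- trimws(raw[[1L]])
  samples <- colnames(raw)[-1L]
  if (anyDuplicated(genes))
    .stopf("duplicate gene_id(s) in %s: %s", path,
           paste(unique(genes[duplicated(genes)]), collapse = ", "))
  body <- vapply(seq_along(samples),
                 function(j) .parse_numeric_column(raw[[j + 1L]], genes, samples[j]),
                 numeric(length(genes)))
  if (length(genes) == 1L) body <- matrix(body, nrow = 1L)
  dimnames(body) <- list(genes, samples)
  expression_matrix(body, system_label = system_label)
}

#' Write an expression matrix to TSV
#'
#' Values are printed with 17 significant digits so a write/read cycle
#' round-trips doubles exactly.
#'
#' @param x An [expression_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  fmt <- formatC(x$values, digits = 17, format = "g")
  out <- data.frame(gene_id = gene_ids(x), fmt, check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(out) <- c("gene_id", sample_ids(x))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a per-cell-line drug-activity vector
#'
#' Activity is oriented so that LARGER means MORE SENSITIVE (i.e. -log GI50).
#'
#' @param activity Named numeric vector (names = cell-line ids) or unnamed with
#'   `cell_line_ids` supplied.
#' @param drug_name Drug label.
#' @param cell_line_ids Optional ids when `activity` is unnamed.
#' @return An object of class `"drug_activity"`.
#' @export
drug_activity <- function(activity, drug_name = "drug", cell_line_ids = names(activity)) {
  force(cell_line_ids)
  activity <- as.numeric(activity)
  if (is.null(cell_line_ids) || length(cell_line_ids) != length(activity))
    .stopf("`cell_line_ids` must match the length of `activity`")
  if (anyDuplicated(cell_line_ids))
    .stopf("duplicate cell_line_id(s): %s",
           paste(unique(cell_line_ids[duplicated(cell_line_ids)]), collapse = ", "))
  if (!all(is.finite(activity)))
    .stopf("non-finite activity value for cell line \"%s\"",
           cell_line_ids[which(!is.finite(activity))[1L]])
  if (length(activity) >= 2L && all(activity == activity[1L]))
    .stopf("all drug-activity values are identical")
  names(activity) <- cell_line_ids
  structure(list(cell_line_ids = as.character(cell_line_ids),
                 activity = activity,
                 drug_name = as.character(drug_name)[1L]),
            class = "drug_activity")
}

#' Read/write drug activity TSV (columns `cell_line_id`, `activity`)
#' @param path TSV path.
#' @param drug_name Drug label attached to the loaded object.
#' @return [drug_activity()] for the reader; `path` invisibly for the writer.
#' @export
read_drug_activity <- function(path, drug_name = "drug") {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character", check.names = FALSE)
  need <- c("cell_line_id", "activity")
  if (!all(need %in% colnames(raw)))
    .stopf("%s: expected columns %s", path, paste(need, collapse = ", "))
  act <- .parse_numeric_column(raw$activity, raw$cell_line_id, "activity")
  drug_activity(stats::setNames(act, trimws(raw$cell_line_id)), drug_name = drug_name)
}

#' @rdname read_drug_activity
#' @param x A `drug_activity`.
#' @export
write_drug_activity <- function(x, path) {
  stopifnot(inherits(x, "drug_activity"))
  out <- data.frame(cell_line_id = x$cell_line_ids,
                    activity = formatC(x$activity, digits = 17, format = "g"))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a patient phenotype table
#'
#' Holds the clinical endpoints used downstream: optional binary response
#' (1 = pathologic complete response), optional survival time (arbitrary
#' units, nonnegative) and event indicator (1 = event observed). An event
#' column requires a time column.
#'
#' @param sample_id Unique sample identifiers.
#' @param response Optional binary vector (NA allowed).
#' @param time Optional nonnegative survival times.
#' @param event Optional binary event indicators.
#' @return A `data.frame` of class `"phenotype_table"`.
#' @export
phenotype_table <- function(sample_id, response = NULL, time = NULL, event = NULL) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    .stopf("duplicate sample_id(s): %s",
           paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  n <- length(sample_id)
  chk_len <- function(v, nm) {
    if (!is.null(v) && length(v) != n) .stopf("`%s` must have length %d", nm, n)
    v
  }
  response <- chk_len(response, "response")
  time <- chk_len(time, "time")
  event <- chk_len(event, "event")
  if (!is.null(response) && !all(response %in% c(0, 1) | is.na(response)))
    .stopf("`response` must be binary (0/1) where present")
  if (!is.null(event) && is.null(time))
    .stopf("`event` requires `time`")
  if (!is.null(event) && !all(event %in% c(0, 1) | is.na(event)))
    .stopf("`event` must be binary (0/1) where present")
  if (!is.null(time) && any(time < 0, na.rm = TRUE))
    .stopf("`time` must be nonnegative")
  out <- data.frame(sample_id = sample_id, stringsAsFactors = FALSE)
  out$response <- if (is.null(response)) NA_real_ else as.numeric(response)
  out$time <- if (is.null(time)) NA_real_ else as.numeric(time)
  out$event <- if (is.null(event)) NA_real_ else as.numeric(event)
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Read/write phenotype TSV (columns `sample_id`, `response`, `time`, `event`;
#' empty cell = missing)
#' @param path TSV path.
#' @return [phenotype_table()] for the reader; `path` invisibly for the writer.
#' @export
read_phenotype_table <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character", check.names = FALSE)
  if (!"sample_id" %in% colnames(raw)) .stopf("%s: missing column sample_id", path)
  num_or_null <- function(col) {
    if (!col %in% colnames(raw)) return(NULL)
    v <- suppressWarnings(as.numeric(trimws(raw[[col]])))
    bad <- which(is.na(v) & nzchar(trimws(raw[[col]])) &
                   toupper(trimws(raw[[col]])) != "NA")
    if (length(bad))
      .stopf("%s: non-numeric value \"%s\" in column %s (sample \"%s\")",
             path, raw[[col]][bad[1L]], col, raw$sample_id[bad[1L]])
    v
  }
  phenotype_table(trimws(raw$sample_id),
                  response = num_or_null("response"),
                  time = num_or_null("time"),
                  event = num_or_null("event"))
}

#' @rdname read_phenotype_table
#' @param x A `phenotype_table`.
#' @export
write_phenotype_table <- function(x, path) {
  stopifnot(inherits(x, "phenotype_table"))
  fmt <- function(v) ifelse(is.na(v), "", formatC(v, digits = 17, format = "g"))
  out <- data.frame(sample_id = x$sample_id, response = fmt(x$response),
                    time = fmt(x$time), event = fmt(x$event))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict two expression matrices to their shared genes
#'
#' Both outputs carry the gene intersection (optionally further restricted to
#' `genes`) in a canonical lexicographic order, so the result does not depend
#' on the input gene order. Sample sets are untouched.
#'
#' @param a,b [expression_matrix()] objects.
#' @param genes Optional gene-id subset to intersect with.
#' @return A list with elements `a` and `b`.
#' @export
align_by_common_genes <- function(a, b, genes = NULL) {
  stopifnot(inherits(a, "expression_matrix"), inherits(b, "expression_matrix"))
  common <- intersect(gene_ids(a), gene_ids(b))
  if (!is.null(genes)) common <- intersect(common, as.character(genes))
  if (length(common) < 2L)
    .stopf("insufficient shared genes: %d in common", length(common))
  common <- sort(common)
  list(a = expression_matrix(a$values[common, , drop = FALSE], a$system_label),
       b = expression_matrix(b$values[common, , drop = FALSE], b$system_label))
}

# Row-wise z-score of a plain matrix; errors on constant rows.
.zscore_rows <- function(v) {
  mu <- rowMeans(v)
  sds <- sqrt(rowSums((v - mu)^2) / (ncol(v) - 1L))
  const <- sds <= 1e-12 * pmax(abs(mu), 1)
  if (any(const))
    .stopf("constant gene(s), cannot standardize: %s",
           paste(utils::head(rownames(v)[const], 5L), collapse = ", "))
  (v - mu) / sds
}

#' Standardize each gene to mean 0, sample standard deviation 1
#'
#' Per-gene z-scoring within a dataset is the package's cross-platform
#' harmonization step before any model trained in one system is applied to
#' another. Idempotent; errors on constant genes.
#'
#' @param m An [expression_matrix()].
#' @return A standardized [expression_matrix()] with the same label.
#' @export
zscore_genes <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  expression_matrix(.zscore_rows(m$values), m$system_label)
}

#' Default run configuration
#'
#' All pipeline tunables with their defaults: discovery FDR 0.05, three-way
#' FDR 0.2, gate alpha 0.025 (one-sided, Bonferroni-adjusted), permutation
#' null percentile 98, B = 500 permutations, sensitive/resistant tertile cuts
#' 1/3 and 2/3, PC cumulative-variance fraction 0.8, candidate-grid step 4.
#'
#' @return A nested list of tunables.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    discovery = list(method = "correlation", fdr = 0.05,
                     lower_frac = 1 / 3, upper_frac = 2 / 3),
    coxen = list(B = 500L, percentile = 98, diagonal_mode = "excluded",
                 null_mode = "pooled", threeway_fdr = 0.2),
    gate = list(alpha = 0.025),
    modeling = list(variance_frac = 0.8, grid_step = 4L,
                    selection_alpha = 0.05, min_biomarkers = 20L)
  )
}

# Recursive defaults merge: values in `user` override `defaults`.
.merge_config <- function(defaults, user) {
  if (is.null(user)) return(defaults)
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(defaults[[k]]))
      defaults[[k]] <- .merge_config(defaults[[k]], user[[k]])
    else defaults[[k]] <- user[[k]]
  }
  defaults
}

#' Read a run configuration from JSON
#'
#' Unspecified tunables fall back to [default_run_config()]. Input paths and
#' cohort declarations are passed through untouched.
#'
#' @param path Path to a JSON file.
#' @return The merged configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) .stopf("config file not found: %s", path)
  user <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  cfg <- .merge_config(default_run_config(), user)
  with(cfg, {
    stopifnot(discovery$fdr > 0, discovery$fdr < 1,
              coxen$threeway_fdr > 0, coxen$threeway_fdr < 1,
              gate$alpha > 0, gate$alpha < 1,
              coxen$percentile > 0, coxen$percentile < 100)
  })
  cfg
}
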