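# cli/pipeline: orchestrate the six-step analysis end-to-end with enforced
# separation between training inputs and prospective validation cohorts.

.largest_cohort <- function(cohorts, idx) {
  sizes <- vapply(idx, function(i) ncol(cohorts[[i]]$expression$values), integer(1L))
  idx[which.max(sizes)]
}

#' Run the full cross-cancer prediction pipeline on in-memory objects
#'
#' Steps: (1) biomarker discovery on the cell panel; (2) cancer-type gating by
#' wCOXEN/bCOXEN comparison on COXEN-reference cohorts; (3) three-way
#' concordance triage (cell panel, original-cancer reference, chosen new-type
#' reference); (4) PC-regression candidates over a nested size grid; (5) model
#' selection and Youden threshold on the designated evaluation cohort; (6)
#' prospective validation of every `role = "validation"` cohort at the frozen
#' threshold. Validation cohorts are excluded from every earlier step by
#' construction (the runner enforces the roles rather than trusting call
#' order). If the gate leaves no suitable new cancer type the run completes
#' through model training with a `transferable_type = NULL` result.
#'
#' @param cell_expr Cell-panel [expression_matrix()].
#' @param activity [drug_activity()] for the panel.
#' @param cohorts Named list; each element a list with `expression`
#'   ([expression_matrix()]), optional `phenotype` ([phenotype_table()]),
#'   `cancer_type` (text), and `role` (`"coxen_reference"`, `"evaluation"`, or
#'   `"validation"`). Exactly one evaluation cohort; its cancer type is the
#'   original type.
#' @param config Tunables, see [default_run_config()].
#' @return A list of class `"concord_pipeline"`.
#' @export
run_concord <- function(cell_expr, activity, cohorts,
                        config = default_run_config()) {
  config <- .merge_config(default_run_config(), config)
  stopifnot(inherits(cell_expr, "expression_matrix"),
            inherits(activity, "drug_activity"),
            is.list(cohorts), length(cohorts) >= 2L)
  roles <- vapply(cohorts, function(co) co$role, character(1L))
  types <- vapply(cohorts, function(co) co$cancer_type, character(1L))
  eval_i <- which(roles == "evaluation")
  if (length(eval_i) != 1L) .stopf("exactly one cohort must have role 'evaluation'")
  original_type <- types[eval_i]
  val_i <- which(roles == "validation")
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))
  note("validation cohorts held out of all earlier steps: %s",
       paste(names(cohorts)[val_i], collapse = ", "))
  seed <- config$seed

  ## Step 1: discovery on the cell panel --------------------------------------
  initial <- if (identical(config$discovery$method, "ttest")) {
    classing <- classify_sensitivity(activity, config$discovery$lower_frac,
                                     config$discovery$upper_frac)
    discover_ttest(cell_expr, classing, fdr = config$discovery$fdr,
                   drug_name = activity$drug_name)
  } else {
    discover_correlation(cell_expr, activity, fdr = config$discovery$fdr)
  }
  initial_genes <- initial$records$gene_id
  note("discovery (%s): %d of %d genes significant at FDR < %g",
       initial$method, length(initial_genes), nrow(initial$full),
       config$discovery$fdr)
  min_bm <- config$modeling$min_biomarkers
  if (length(initial_genes) < min_bm) {
    full <- initial$full[!initial$full$flagged, , drop = FALSE]
    ranked <- full$gene_id[order(-abs(full$statistic), full$gene_id)]
    initial_genes <- utils::head(ranked, min_bm)
    .warnf("only %d significant biomarkers; topping up to %d by |statistic|",
           nrow(initial$records), length(initial_genes))
    note("discovery fallback: topped up to %d genes by |statistic| ranking",
         length(initial_genes))
  }

  ## Step 2: cancer-type gate --------------------------------------------------
  usable <- which(roles != "validation")   # coxen_reference + evaluation
  orig_usable <- usable[types[usable] == original_type]
  if (length(orig_usable) < 2L)
    .stopf("need >= 2 non-validation cohorts of the original cancer type for wCOXEN")
  orig_ref_i <- .largest_cohort(cohorts, orig_usable)
  wpairs <- utils::combn(orig_usable, 2L, simplify = FALSE)
  wcoxen <- lapply(wpairs, function(pr)
    coxen_distribution(initial_genes, cohorts[[pr[1L]]]$expression,
                       cohorts[[pr[2L]]]$expression,
                       diagonal_mode = config$coxen$diagonal_mode))
  names(wcoxen) <- vapply(wpairs, function(pr)
    paste(names(cohorts)[pr], collapse = "|"), character(1L))

  cand_types <- setdiff(unique(types[usable]), original_type)
  gate <- NULL; chosen_type <- NULL; new_ref_i <- NULL
  if (length(cand_types)) {
    bcoxen <- list()
    cand_ref <- integer()
    for (tp in cand_types) {
      ref_i <- .largest_cohort(cohorts, usable[types[usable] == tp])
      cand_ref[tp] <- ref_i
      bcoxen[[tp]] <- coxen_distribution(initial_genes,
                                         cohorts[[orig_ref_i]]$expression,
                                         cohorts[[ref_i]]$expression,
                                         diagonal_mode = config$coxen$diagonal_mode)
    }
    gate <- gate_cancer_types(wcoxen, bcoxen, alpha = config$gate$alpha)
    ok <- gate$candidate[gate$suitable]
    if (length(ok)) {
      meds <- gate$median_bcoxen[gate$suitable]
      chosen_type <- ok[which.max(meds)]
      new_ref_i <- cand_ref[[chosen_type]]
      note("gate: chose cancer type '%s' (median bCOXEN %.3f)",
           chosen_type, max(meds))
    } else note("gate: no transferable cancer type at alpha %g", config$gate$alpha)
  } else note("gate: no candidate cancer types declared")

  ## Step 3: concordance triage ------------------------------------------------
  concord <- NULL
  model_genes <- if (!is.null(chosen_type)) {
    concord <- suppressWarnings(threeway_select(
      initial_genes, cell_expr, cohorts[[orig_ref_i]]$expression,
      cohorts[[new_ref_i]]$expression,
      fdr = config$coxen$threeway_fdr, B = config$coxen$B,
      seed = if (is.null(seed)) NULL else seed + 10L,
      diagonal_mode = config$coxen$diagonal_mode,
      null_mode = config$coxen$null_mode))
    note("three-way triage: %d -> %d genes (per-pair survivors: %s)",
         length(concord$initial_gene_ids), length(concord$gene_ids),
         paste(concord$counts[1:3], collapse = "/"))
    concord$gene_ids
  } else {
    nr <- coxen_null(cell_expr, cohorts[[orig_ref_i]]$expression, initial_genes,
                     B = config$coxen$B,
                     seed = if (is.null(seed)) NULL else seed + 10L,
                     percentile = config$coxen$percentile,
                     diagonal_mode = config$coxen$diagonal_mode,
                     null_mode = config$coxen$null_mode)
    p <- nr$p_values; p[is.na(p)] <- 1
    keep <- nr$gene_ids[bh_fdr(p) < config$coxen$threeway_fdr]
    note("two-way triage (no transferable type): %d -> %d genes",
         length(initial_genes), length(keep))
    keep
  }
  if (length(model_genes) < 4L) {
    # a usable multi-gene predictor plus its validation-time suitability
    # recheck needs at least 4 genes; fall back to the discovery ranking
    full <- initial$full[!initial$full$flagged, , drop = FALSE]
    ranked <- full$gene_id[order(-abs(full$statistic), full$gene_id)]
    model_genes <- utils::head(intersect(ranked, initial_genes),
                               min(min_bm, length(initial_genes)))
    .warnf("concordance triage left < 4 genes; falling back to initial ranking")
    note("triage fallback: modeling on top %d initial genes", length(model_genes))
  }

  ## Steps 4-5: candidate models, selection, threshold -------------------------
  grid <- candidate_grid(model_genes, initial, grid_step = config$modeling$grid_step)
  models <- lapply(grid, fit_pcr, cell_expr = cell_expr, act = activity,
                   variance_frac = config$modeling$variance_frac)
  eval_cohort <- cohorts[[eval_i]]
  if (is.null(eval_cohort$phenotype))
    .stopf("evaluation cohort '%s' has no phenotype", names(cohorts)[eval_i])
  selection <- select_model(models, eval_cohort$expression, eval_cohort$phenotype,
                            alpha = config$modeling$selection_alpha)
  model <- selection$model
  note("selection: %d-gene model, eval AUC %.3f, threshold %.3f (J = %.3f)",
       length(model$gene_ids), selection$table$auc[selection$chosen_index],
       selection$threshold, selection$youden_j)

  ## Step 6: prospective validation --------------------------------------------
  wcoxen_final <- lapply(wpairs, function(pr)
    coxen_distribution(model$gene_ids, cohorts[[pr[1L]]]$expression,
                       cohorts[[pr[2L]]]$expression,
                       diagonal_mode = config$coxen$diagonal_mode))
  names(wcoxen_final) <- names(wcoxen)
  validations <- list()
  for (i in val_i) {
    nm <- names(cohorts)[i]
    validations[[nm]] <- validate_cohort(
      model, cohorts[[i]]$expression, cohorts[[i]]$phenotype,
      reference_wcoxen = wcoxen_final,
      reference_expr = cohorts[[orig_ref_i]]$expression,
      gate_alpha = config$gate$alpha, cohort_label = nm)
    note("validation %s: suitable = %s%s", nm, validations[[nm]]$suitable,
         if (!is.null(validations[[nm]]$roc))
           sprintf(", AUC %.3f (p = %.3g)", validations[[nm]]$roc$auc,
                   validations[[nm]]$roc$p_value) else "")
  }

  structure(list(initial = initial, initial_genes = initial_genes,
                 gate = gate, chosen_type = chosen_type, concord = concord,
                 grid_sizes = vapply(grid, length, integer(1L)),
                 selection = selection, model = model,
                 threshold = selection$threshold,
                 wcoxen = wcoxen, wcoxen_final = wcoxen_final,
                 validations = validations, original_type = original_type,
                 log = log, seed = seed, config = config),
            class = "concord_pipeline")
}

#' @export
print.concord_pipeline <- function(x, ...) {
  cat("<concord_pipeline>\n")
  for (l in x$log) cat(" -", l, "\n")
  invisible(x)
}

.require_path <- function(path, key) {
  if (is.null(path)) .stopf("config key missing: %s", key)
  if (!file.exists(path)) .stopf("%s: file not found: %s", key, path)
  path
}

#' Run the pipeline from a JSON run configuration
#'
#' The config names the input files and tunables:
#' `cell_expression` / `drug_activity` (TSV paths), `drug_name`, and `cohorts`,
#' a named object whose entries carry `expression` (TSV path), optional
#' `phenotype` (TSV path), `cancer_type`, and `role`. Tunables merge over
#' [default_run_config()]. With `outdir` set, the trained model JSON,
#' per-cohort score TSVs, and a pipeline report JSON are written there.
#'
#' @param config Path to a JSON config or an equivalent list.
#' @param outdir Optional output directory.
#' @return The [run_concord()] result, with `$paths` when `outdir` is given.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  else config <- .merge_config(default_run_config(), config)
  base <- if (!is.null(config$base_dir)) config$base_dir else "."
  resolve <- function(p) if (is.null(p) || file.exists(p)) p else file.path(base, p)
  cell_expr <- read_expression_matrix(
    .require_path(resolve(config$cell_expression), "cell_expression"),
    system_label = "cell_panel")
  activity <- read_drug_activity(
    .require_path(resolve(config$drug_activity), "drug_activity"),
    drug_name = if (is.null(config$drug_name)) "drug" else config$drug_name)
  if (is.null(config$cohorts) || !length(config$cohorts))
    .stopf("config key missing: cohorts")
  cohorts <- lapply(names(config$cohorts), function(nm) {
    cc <- config$cohorts[[nm]]
    list(expression = read_expression_matrix(
           .require_path(resolve(cc$expression), sprintf("cohorts$%s$expression", nm)),
           system_label = nm),
         phenotype = if (!is.null(cc$phenotype))
           read_phenotype_table(.require_path(resolve(cc$phenotype),
                                              sprintf("cohorts$%s$phenotype", nm)))
         else NULL,
         cancer_type = cc$cancer_type, role = cc$role)
  })
  names(cohorts) <- names(config$cohorts)
  res <- run_concord(cell_expr, activity, cohorts, config = config)
  if (!is.null(outdir)) res$paths <- write_pipeline_outputs(res, outdir)
  res
}

#' Write pipeline outputs (model JSON, score TSVs, report JSON)
#'
#' @param res A `"concord_pipeline"` result.
#' @param outdir Output directory, created if needed.
#' @return Named character vector of written paths, invisibly.
#' @export
write_pipeline_outputs <- function(res, outdir) {
  stopifnot(inherits(res, "concord_pipeline"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(model = file.path(outdir, "model.json"))
  write_model(res$model, paths[["model"]])
  for (nm in names(res$validations)) {
    v <- res$validations[[nm]]
    p <- file.path(outdir, paste0("scores_", nm, ".tsv"))
    out <- cbind(v$scores, predicted_class = as.character(v$classes))
    utils::write.table(out, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[paste0("scores_", nm)] <- p
  }
  report <- list(
    drug_name = res$model$drug_name,
    original_type = res$original_type,
    chosen_type = res$chosen_type,
    n_initial_biomarkers = length(res$initial_genes),
    n_concord_biomarkers = if (is.null(res$concord)) NA_integer_
      else length(res$concord$gene_ids),
    model_genes = res$model$gene_ids,
    threshold = res$threshold,
    gate = if (is.null(res$gate)) NULL else as.list(as.data.frame(res$gate)),
    selection = as.list(res$selection$table),
    validations = lapply(res$validations, function(v) list(
      suitable = v$suitable,
      auc = if (is.null(v$roc)) NULL else v$roc$auc,
      auc_p = if (is.null(v$roc)) NULL else v$roc$p_value,
      ppv = if (is.null(v$ppv)) NULL else v$ppv$ppv,
      ppv_p = if (is.null(v$ppv)) NULL else v$ppv$p_value,
      logrank_chisq = if (is.null(v$survival)) NULL else v$survival$chisq,
      logrank_p = if (is.null(v$survival)) NULL else v$survival$p_value,
      notes = v$notes)),
    log = res$log, seed = res$seed)
  paths["report"] <- file.path(outdir, "pipeline_report.json")
  jsonlite::write_json(report, paths[["report"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(paths)
}

#' Map a synthetic dataset onto [run_concord()] inputs and run it
#'
#' @param ds A `"synthetic_dataset"`.
#' @param config Tunables merged over [default_run_config()]; the dataset's
#'   seed is used when the config does not set one.
#' @return A `"concord_pipeline"` result.
#' @export
run_concord_synthetic <- function(ds, config = list()) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  if (!"seed" %in% names(config)) config$seed <- ds$config$seed
  config <- .merge_config(default_run_config(), config)
  run_concord(ds$cell$expression, ds$cell$activity, ds$cohorts, config = config)
}
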