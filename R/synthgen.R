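# synthgen: multi-system synthetic datasets with planted concordant
# co-expression and drug-response signal, so the whole pipeline is testable
# without external data.

#' Synthetic-world configuration
#'
#' The generated world: a cell-line panel plus six patient cohorts sharing
#' latent expression programs. Concordant genes carry a fixed unit-length
#' loading direction over `n_factors` programs (weighted toward program 1, the
#' drug-sensitivity program), scaled by `lambda`, in every system.
#' Pairwise-only genes load a separate block of `n_patient_factors`
#' patient-only programs -- biology shared by the two patient cancers but
#' absent from the in vitro panel -- and are pure noise in the cell panel.
#' Null genes are noise everywhere. Drug activity is program 1 plus Gaussian
#' noise; patient response is Bernoulli with a logistic link on the same
#' program (offset calibrated to the configured baseline rate); survival is
#' exponential with a lower hazard for responders; censoring hits a fixed
#' fraction of patients uniformly within their event time. The "unsuitable"
#' cohort is a copy of the new-cancer-type world whose gene identities are
#' randomly permuted: marginal distributions intact, cross-system concordance
#' destroyed.
#'
#' @param n_genes Total genes (default 100).
#' @param n_concordant,n_pairwise_only,n_null Planted gene-class counts
#'   (30/20/50); any remainder up to `n_genes` is also null.
#' @param n_cell_lines Cell panel size (default 60).
#' @param n_factors Latent programs loaded by concordant genes (default 5).
#' @param n_patient_factors Patient-only programs loaded by pairwise-only
#'   genes (default 3).
#' @param cohort_sizes Named sizes for `original_coxen`, `original_coxen2`,
#'   `original_eval`, `original_val`, `new_coxen`, `new_val`, `unsuitable`.
#'   Two original-type COXEN reference cohorts are generated so the gate's
#'   reference -- the lowest-median wCOXEN over within-type cohort pairs --
#'   spans within-type variability, as the method requires.
#' @param lambda Loading strength: factor-driven variance over noise variance
#'   (default 1).
#' @param sensitivity_weight How strongly planted biomarker genes lean toward
#'   the drug-sensitivity program (program 1) when their loading direction is
#'   drawn (default 1.5). Biomarkers are biomarkers because they track the
#'   sensitivity program; the remaining programs carry the co-expression
#'   idiosyncrasy that COXEN measures.
#' @param sigma_a Activity noise SD (default 0.3).
#' @param beta Logistic steepness of response on the latent program (default 2).
#' @param baseline_response Cohort-level response rate the offset is calibrated
#'   to (default 0.3).
#' @param censor_rate Fraction of patients censored (default 0.3).
#' @param base_hazard Non-responder exponential hazard (default 0.1).
#' @param responder_hazard_ratio Responder hazard multiplier, in (0, 1]
#'   (default 0.4).
#' @param drug_name Drug label.
#' @param seed Seed; all randomness flows from it.
#' @return A validated list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_genes = 100L, n_concordant = 30L,
                             n_pairwise_only = 20L, n_null = 50L,
                             n_cell_lines = 60L, n_factors = 5L,
                             n_patient_factors = 3L,
                             cohort_sizes = c(original_coxen = 100L,
                                              original_coxen2 = 110L,
                                              original_eval = 130L,
                                              original_val = 90L,
                                              new_coxen = 100L,
                                              new_val = 100L,
                                              unsuitable = 80L),
                             lambda = 1, sensitivity_weight = 1.5,
                             sigma_a = 0.3, beta = 2,
                             baseline_response = 0.3, censor_rate = 0.3,
                             base_hazard = 0.1, responder_hazard_ratio = 0.4,
                             drug_name = "drugX", seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_concordant = as.integer(n_concordant),
              n_pairwise_only = as.integer(n_pairwise_only), n_null = as.integer(n_null),
              n_cell_lines = as.integer(n_cell_lines), n_factors = as.integer(n_factors),
              n_patient_factors = as.integer(n_patient_factors),
              cohort_sizes = cohort_sizes, lambda = lambda,
              sensitivity_weight = sensitivity_weight, sigma_a = sigma_a,
              beta = beta, baseline_response = baseline_response,
              censor_rate = censor_rate, base_hazard = base_hazard,
              responder_hazard_ratio = responder_hazard_ratio,
              drug_name = drug_name, seed = seed)
  need <- c("original_coxen", "original_coxen2", "original_eval",
            "original_val", "new_coxen", "new_val", "unsuitable")
  if (!all(need %in% names(cfg$cohort_sizes)))
    .stopf("cohort_sizes must name: %s", paste(need, collapse = ", "))
  if (cfg$n_concordant + cfg$n_pairwise_only + cfg$n_null > cfg$n_genes)
    .stopf("gene-class counts exceed n_genes")
  if (cfg$n_factors < 1L) .stopf("n_factors must be >= 1")
  if (cfg$n_patient_factors < 1L) .stopf("n_patient_factors must be >= 1")
  if (cfg$lambda < 0) .stopf("lambda must be nonnegative")
  if (cfg$sensitivity_weight <= 0) .stopf("sensitivity_weight must be positive")
  if (cfg$sigma_a <= 0) .stopf("sigma_a must be positive")
  if (cfg$beta <= 0) .stopf("beta must be positive")
  for (nm in c("baseline_response", "censor_rate"))
    if (!(cfg[[nm]] > 0 && cfg[[nm]] < 1)) .stopf("%s must lie in (0, 1)", nm)
  if (!(cfg$responder_hazard_ratio > 0 && cfg$responder_hazard_ratio <= 1))
    .stopf("responder_hazard_ratio must lie in (0, 1]")
  if (cfg$base_hazard <= 0) .stopf("base_hazard must be positive")
  if (cfg$n_cell_lines < 4L || any(cfg$cohort_sizes < 4L))
    .stopf("every system needs at least 4 samples")
  class(cfg) <- "synthetic_config"
  cfg
}

# Offset o such that mean over the realized factor of plogis(beta*(f - o))
# equals the configured baseline response rate.
.calibrate_offset <- function(f, beta, baseline) {
  stats::uniroot(function(o) mean(stats::plogis(beta * (f - o))) - baseline,
                 interval = c(-50, 50), tol = 1e-10)$root
}

#' Generate a synthetic multi-system dataset
#'
#' See [synthetic_config()] for the stated world. Identical seeds give
#' bit-identical datasets; the RNG state of the caller is untouched.
#'
#' @param config A [synthetic_config()] (or a list of overrides for it).
#' @return A list of class `"synthetic_dataset"`: `cell` (expression +
#'   activity), `cohorts` (each with expression, optional phenotype,
#'   cancer_type, role), `truth` (gene classes, per-system latent factor,
#'   responder status, the unsuitable cohort's permutation), `config`.
#' @export
generate_synthetic_dataset <- function(config = synthetic_config()) {
  if (!inherits(config, "synthetic_config"))
    config <- do.call(synthetic_config, config)
  cfg <- config
  .with_seed(cfg$seed, {
    G <- cfg$n_genes
    K <- cfg$n_factors; Kp <- cfg$n_patient_factors
    Ktot <- K + Kp                              # programs K+1..Ktot are patient-only
    gene_id <- sprintf("G%03d", seq_len(G))
    classes <- rep("null", G)
    classes[seq_len(cfg$n_concordant)] <- "concordant"
    classes[cfg$n_concordant + seq_len(cfg$n_pairwise_only)] <- "pairwise_only"
    names(classes) <- gene_id

    # fixed per-gene unit loading directions, shared by all systems a gene is
    # active in. Concordant genes live in programs 1..K with program 1 (drug
    # sensitivity) over-weighted; pairwise-only genes live in the patient-only
    # block K+1..Ktot.
    dirs <- matrix(0, G, Ktot)
    conc_i <- which(classes == "concordant")
    pw_i <- which(classes == "pairwise_only")
    d1 <- matrix(stats::rnorm(length(conc_i) * K), length(conc_i), K)
    d1[, 1L] <- d1[, 1L] * cfg$sensitivity_weight
    dirs[conc_i, seq_len(K)] <- d1 / sqrt(rowSums(d1^2))
    d2 <- matrix(stats::rnorm(length(pw_i) * Kp), length(pw_i), Kp)
    dirs[pw_i, K + seq_len(Kp)] <- d2 / sqrt(rowSums(d2^2))
    A <- cfg$lambda * dirs                     # G x Ktot loading matrix

    mask_cell <- classes == "concordant"
    mask_patient <- classes %in% c("concordant", "pairwise_only")

    gen_expr <- function(n, mask, prefix, label) {
      f <- matrix(stats::rnorm(Ktot * n), Ktot, n)  # programs x samples
      Am <- A * mask                           # zero loading outside the mask
      vals <- Am %*% f + matrix(stats::rnorm(G * n), G, n)
      dimnames(vals) <- list(gene_id, sprintf("%s%03d", prefix, seq_len(n)))
      list(expr = expression_matrix(vals, system_label = label), f1 = f[1L, ])
    }
    gen_outcomes <- function(f1, ids, survival = TRUE) {
      off <- .calibrate_offset(f1, cfg$beta, cfg$baseline_response)
      pr <- stats::plogis(cfg$beta * (f1 - off))
      resp <- stats::rbinom(length(f1), 1L, pr)
      if (!survival)
        return(list(ph = phenotype_table(ids, response = resp), resp = resp))
      rate <- cfg$base_hazard *
        ifelse(resp == 1, cfg$responder_hazard_ratio, 1)
      t_event <- stats::rexp(length(f1), rate)
      cens <- stats::rbinom(length(f1), 1L, cfg$censor_rate)
      time <- ifelse(cens == 1, stats::runif(length(f1)) * t_event, t_event)
      list(ph = phenotype_table(ids, response = resp, time = time,
                                event = 1 - cens),
           resp = resp)
    }

    cell <- gen_expr(cfg$n_cell_lines, mask_cell, "CL", "cell_panel")
    activity <- drug_activity(
      stats::setNames(cell$f1 + stats::rnorm(cfg$n_cell_lines, 0, cfg$sigma_a),
                      sample_ids(cell$expr)),
      drug_name = cfg$drug_name)

    sz <- cfg$cohort_sizes
    specs <- list(
      original_coxen = list(n = sz[["original_coxen"]], mask = mask_patient,
                            prefix = "OC", type = "original",
                            role = "coxen_reference", outcomes = "none"),
      original_coxen2 = list(n = sz[["original_coxen2"]], mask = mask_patient,
                             prefix = "OD", type = "original",
                             role = "coxen_reference", outcomes = "none"),
      original_eval = list(n = sz[["original_eval"]], mask = mask_patient,
                           prefix = "OE", type = "original",
                           role = "evaluation", outcomes = "response"),
      original_val = list(n = sz[["original_val"]], mask = mask_patient,
                          prefix = "OV", type = "original",
                          role = "validation", outcomes = "both"),
      new_coxen = list(n = sz[["new_coxen"]], mask = mask_patient,
                       prefix = "NC", type = "new",
                       role = "coxen_reference", outcomes = "none"),
      new_val = list(n = sz[["new_val"]], mask = mask_patient,
                     prefix = "NV", type = "new",
                     role = "validation", outcomes = "both"),
      unsuitable = list(n = sz[["unsuitable"]], mask = mask_patient,
                        prefix = "UN", type = "new",
                        role = "validation", outcomes = "both"))

    cohorts <- list()
    factors <- list(cell_panel = stats::setNames(cell$f1, sample_ids(cell$expr)))
    responders <- list()
    perm_unsuitable <- NULL
    for (nm in names(specs)) {
      sp <- specs[[nm]]
      g <- gen_expr(sp$n, sp$mask, sp$prefix, nm)
      expr <- g$expr
      if (nm == "unsuitable") {
        # scramble gene identity: marginals intact, concordance destroyed
        perm_unsuitable <- sample.int(G)
        vals <- expr$values[perm_unsuitable, , drop = FALSE]
        rownames(vals) <- gene_id
        expr <- expression_matrix(vals, system_label = nm)
      }
      ph <- NULL
      if (sp$outcomes != "none") {
        oc <- gen_outcomes(g$f1, sample_ids(expr),
                           survival = sp$outcomes == "both")
        ph <- oc$ph
        responders[[nm]] <- stats::setNames(oc$resp, sample_ids(expr))
      }
      factors[[nm]] <- stats::setNames(g$f1, sample_ids(expr))
      cohorts[[nm]] <- list(expression = expr, phenotype = ph,
                            cancer_type = sp$type, role = sp$role)
    }

    structure(list(cell = list(expression = cell$expr, activity = activity),
                   cohorts = cohorts,
                   truth = list(gene_classes = classes, factors = factors,
                                responders = responders,
                                unsuitable_permutation = perm_unsuitable),
                   config = cfg),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d genes (%d concordant, %d pairwise-only), %d cell lines, %d cohorts [seed %s]\n",
              x$config$n_genes, x$config$n_concordant, x$config$n_pairwise_only,
              x$config$n_cell_lines, length(x$cohorts),
              format(x$config$seed)))
  invisible(x)
}

#' Write a synthetic dataset to a fixture directory
#'
#' All matrices and tables are written in the package TSV dialects plus a
#' ground-truth gene-class TSV and a JSON manifest listing every file with its
#' row/column counts. Reading the files back reproduces the in-memory dataset.
#'
#' @param ds A `"synthetic_dataset"`.
#' @param dir Output directory (created if needed).
#' @return The manifest list, invisibly.
#' @export
write_fixture <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  add <- function(key, path, rows, cols) {
    files[[key]] <<- list(path = basename(path), rows = rows, cols = cols)
  }
  p <- file.path(dir, "cell_expression.tsv")
  write_expression_matrix(ds$cell$expression, p)
  add("cell_expression", p, nrow(ds$cell$expression$values),
      ncol(ds$cell$expression$values))
  p <- file.path(dir, "drug_activity.tsv")
  write_drug_activity(ds$cell$activity, p)
  add("drug_activity", p, length(ds$cell$activity$activity), 2L)
  for (nm in names(ds$cohorts)) {
    co <- ds$cohorts[[nm]]
    p <- file.path(dir, paste0(nm, "_expression.tsv"))
    write_expression_matrix(co$expression, p)
    add(paste0(nm, "_expression"), p, nrow(co$expression$values),
        ncol(co$expression$values))
    if (!is.null(co$phenotype)) {
      p <- file.path(dir, paste0(nm, "_phenotype.tsv"))
      write_phenotype_table(co$phenotype, p)
      add(paste0(nm, "_phenotype"), p, nrow(co$phenotype), ncol(co$phenotype))
    }
  }
  p <- file.path(dir, "ground_truth_genes.tsv")
  utils::write.table(
    data.frame(gene_id = names(ds$truth$gene_classes),
               class = unname(ds$truth$gene_classes)),
    p, sep = "\t", quote = FALSE, row.names = FALSE)
  add("ground_truth_genes", p, length(ds$truth$gene_classes), 2L)
  manifest <- list(
    generator = "concord_synthetic_v1",
    seed = ds$config$seed,
    drug_name = ds$config$drug_name,
    cohorts = lapply(ds$cohorts, function(co)
      list(cancer_type = co$cancer_type, role = co$role,
           has_phenotype = !is.null(co$phenotype))),
    files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a fixture directory written by [write_fixture()]
#'
#' @param dir Fixture directory containing `manifest.json`.
#' @return A list shaped like the pipeline inputs: `cell` (expression,
#'   activity) and `cohorts` (expression, phenotype, cancer_type, role).
#' @export
read_fixture <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) .stopf("manifest not found: %s", mpath)
  man <- jsonlite::read_json(mpath, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  getp <- function(key) file.path(dir, man$files[[key]]$path)
  cell <- list(expression = read_expression_matrix(getp("cell_expression"),
                                                   system_label = "cell_panel"),
               activity = read_drug_activity(getp("drug_activity"),
                                             drug_name = man$drug_name))
  cohorts <- lapply(names(man$cohorts), function(nm) {
    info <- man$cohorts[[nm]]
    list(expression = read_expression_matrix(getp(paste0(nm, "_expression")),
                                             system_label = nm),
         phenotype = if (isTRUE(info$has_phenotype))
           read_phenotype_table(getp(paste0(nm, "_phenotype"))) else NULL,
         cancer_type = info$cancer_type, role = info$role)
  })
  names(cohorts) <- names(man$cohorts)
  list(cell = cell, cohorts = cohorts, manifest = man)
}
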