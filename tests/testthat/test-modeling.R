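# modeling: PC regression, cohort scoring, candidate grid, model selection.

make_panel <- function(n_genes = 20, n_samples = 40, label = "cell_panel") {
  e <- rand_expr(n_genes, n_samples, label, sample_prefix = "CL")
  act <- drug_activity(setNames(rnorm(n_samples), sample_ids(e)), "d")
  list(expr = e, act = act)
}

test_that("fit_pcr reproduces a noiseless linear function of PC1 exactly", {
  set.seed(30)
  p <- make_panel(10, 30)
  # build activity exactly linear in the first principal component
  z <- t(scale(t(p$expr$values)))
  pc1 <- svd(t(z))$u[, 1]
  act <- drug_activity(setNames(3 + 2 * pc1, sample_ids(p$expr)), "d")
  m <- fit_pcr(p$expr, act, gene_ids(p$expr), variance_frac = 0.8)
  expect_lt(max(abs(m$fitted - act$activity)), 1e-8)
  # loadings are orthonormal
  expect_lt(max(abs(crossprod(m$pc_loadings) - diag(m$k))), 1e-8)
  expect_gte(m$k, 1L)
  expect_lte(m$k, ncol(p$expr$values) - 2L)
})

test_that("fit_pcr recovers a planted factor and is null when signal is destroyed", {
  set.seed(31)
  recover <- replicate(100, {
    n <- 60; g <- 12
    f <- rnorm(n)
    v <- outer(rep(1, g), f) + matrix(rnorm(g * n), g, n)
    dimnames(v) <- list(sprintf("G%03d", 1:g), sprintf("CL%03d", 1:n))
    e <- expression_matrix(v, "panel")
    act <- drug_activity(setNames(f + rnorm(n, 0, 0.3), sample_ids(e)), "d")
    m <- fit_pcr(e, act, gene_ids(e))
    cor(m$fitted, f) >= 0.9
  })
  expect_gte(mean(recover), 0.9)

  # permuted activity: held-out AUC centers on 0.5
  aucs <- replicate(100, {
    n <- 40; g <- 10
    f <- rnorm(n)
    v <- outer(rep(1, g), f) + matrix(rnorm(g * n), g, n)
    dimnames(v) <- list(sprintf("G%03d", 1:g), sprintf("CL%03d", 1:n))
    e <- expression_matrix(v, "panel")
    act <- drug_activity(setNames(sample(f + rnorm(n, 0, 0.3)), sample_ids(e)), "d")
    m <- fit_pcr(e, act, gene_ids(e))
    nc <- 50
    fc <- rnorm(nc)
    vc <- outer(rep(1, g), fc) + matrix(rnorm(g * nc), g, nc)
    dimnames(vc) <- list(gene_ids(e), sprintf("P%03d", 1:nc))
    sc <- score_cohort(m, expression_matrix(vc, "cohort"))
    labels <- as.integer(fc > median(fc))
    roc_auc(sc$percentile, labels)$auc
  })
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})

test_that("score_cohort is self-consistent on the training panel and ranks correctly", {
  set.seed(32)
  p <- make_panel(15, 30)
  m <- fit_pcr(p$expr, p$act, gene_ids(p$expr))
  sc <- score_cohort(m, p$expr)
  expect_equal(sc$raw_score[match(names(m$fitted), sc$sample_id)],
               unname(m$fitted), tolerance = 1e-10)
  # percentile convention: rank/n with 1 = most sensitive
  expect_equal(sort(unique(sc$percentile))[length(unique(sc$percentile))], 1)
  expect_equal(concord:::.percentile_ranks(c(2.5, -1.0, 0.3)), c(1, 1 / 3, 2 / 3))
  # duplicated patients share a percentile (average-rank ties)
  v2 <- cbind(p$expr$values, p$expr$values)
  colnames(v2) <- c(paste0(sample_ids(p$expr), "_a"), paste0(sample_ids(p$expr), "_b"))
  sc2 <- score_cohort(m, expression_matrix(v2, "dup"))
  half <- nrow(sc2) / 2
  expect_equal(sc2$percentile[1:half], sc2$percentile[half + 1:half])
  # percentiles invariant under strictly increasing transform of raw scores
  expect_equal(concord:::.percentile_ranks(sc$raw_score),
               concord:::.percentile_ranks(exp(sc$raw_score)))
  # missing model genes produce a listing error
  bad <- expression_matrix(p$expr$values[1:10, ], "short")
  expect_error(score_cohort(m, bad), "missing from cohort")
})

test_that("candidate_grid builds nested subsets with deterministic tie-breaks", {
  set.seed(33)
  full <- data.frame(gene_id = sprintf("G%02d", 1:30),
                     statistic = c(5, 5, rnorm(28)),   # tie at the top
                     p_value = runif(30), stringsAsFactors = FALSE)
  full$q_value <- bh_fdr(full$p_value); full$direction <- sign(full$statistic)
  full$flagged <- FALSE
  bs <- concord:::.biomarker_set(full, 1.1, "panel", "d", "ttest")
  genes10 <- sprintf("G%02d", 1:10)
  grid <- candidate_grid(genes10, bs, grid_step = 4)
  expect_identical(vapply(grid, length, integer(1)), c(size_4 = 4L, size_8 = 8L, size_10 = 10L))
  for (i in seq_len(length(grid) - 1))
    expect_true(all(grid[[i]] %in% grid[[i + 1]]))
  # tie between G01 and G02 resolves lexicographically
  expect_identical(grid$size_4[1:2], c("G01", "G02"))
  # explicit sort oracle
  stat <- setNames(full$statistic, full$gene_id)[genes10]
  oracle <- genes10[order(-abs(stat), genes10)]
  expect_identical(grid$size_10, oracle)
  expect_error(candidate_grid("G01", bs), "size >= 2")
})

test_that("select_model applies significance -> AUC -> parsimony and Youden threshold", {
  set.seed(34)
  p <- make_panel(24, 40)
  grid <- candidate_grid(gene_ids(p$expr),
                         discover_correlation(p$expr, p$act, fdr = 1.00001),
                         grid_step = 8)
  models <- lapply(grid, fit_pcr, cell_expr = p$expr, act = p$act)

  # perfect-separation evaluation cohort: J = 1, threshold between the classes
  nc <- 30; g <- length(gene_ids(p$expr))
  f <- c(rnorm(nc / 2, -3), rnorm(nc / 2, 3))
  v <- p$expr$values[, 1] %o% rep(0, nc) +
    outer(as.numeric(m1 <- models[[length(models)]]$pc_loadings[, 1]), f) +
    matrix(rnorm(g * nc, 0, 0.01), g, nc)
  dimnames(v) <- list(gene_ids(p$expr), sprintf("P%03d", 1:nc))
  ev <- expression_matrix(v, "eval")
  sc <- score_cohort(models[[length(models)]], ev)
  labels <- as.integer(sc$raw_score > median(sc$raw_score))
  ph <- phenotype_table(sc$sample_id, response = labels)
  sel <- select_model(models[length(models)], ev, ph)
  expect_equal(sel$youden_j, 1)
  hi <- min(sc$percentile[labels == 1]); lo <- max(sc$percentile[labels == 0])
  expect_gt(sel$threshold, lo)
  expect_lt(sel$threshold, hi)

  # parsimony tie-break: identical scores, different sizes -> smaller wins
  m_small <- models[[1]]; m_big <- models[[length(models)]]
  sc_small <- score_cohort(m_small, ev)
  labels2 <- as.integer(sc_small$percentile >= 0.5)
  ph2 <- phenotype_table(sc_small$sample_id, response = labels2)
  sel2 <- select_model(list(a = m_small, b = m_small, c = m_big), ev, ph2)
  expect_lte(sel2$table$n_genes[sel2$chosen_index],
             min(sel2$table$n_genes[sel2$table$auc == max(sel2$table$auc)]))

  # degenerate response errors
  ph3 <- phenotype_table(sc$sample_id, response = rep(1, nc))
  expect_error(select_model(models, ev, ph3), "one class")
})

test_that("select_model and its threshold match an exhaustive oracle", {
  set.seed(35)
  p <- make_panel(20, 30)
  grid <- candidate_grid(gene_ids(p$expr),
                         discover_correlation(p$expr, p$act, fdr = 1.00001),
                         grid_step = 4)
  models <- lapply(grid, fit_pcr, cell_expr = p$expr, act = p$act)
  for (i in 1:25) {
    nc <- 40
    ev <- rand_expr(20, nc, "eval", sample_prefix = "P")
    rownames(ev$values) <- gene_ids(p$expr)
    ev <- expression_matrix(ev$values, "eval")
    scores <- lapply(models, function(m) score_cohort(m, ev)$percentile)
    labels <- rbinom(nc, 1, 0.4)
    if (length(unique(labels)) < 2) next
    ph <- phenotype_table(sample_ids(ev), response = labels)
    sel <- suppressWarnings(select_model(models, ev, ph))
    orc <- oracle_select(scores, labels,
                         sizes = vapply(models, function(m) length(m$gene_ids), integer(1)))
    expect_identical(sel$chosen_index, orc$chosen)
    expect_equal(sel$threshold, orc$threshold, tolerance = 1e-12)
    expect_equal(sel$youden_j, orc$youden_j, tolerance = 1e-12)
  }
})

test_that("model JSON round-trips exactly and scores identically", {
  set.seed(36)
  p <- make_panel(12, 25)
  m <- fit_pcr(p$expr, p$act, gene_ids(p$expr))
  m$threshold <- 0.541
  f <- withr::local_tempfile(fileext = ".json")
  write_model(m, f)
  m2 <- read_model(f)
  expect_identical(m2$gene_ids, m$gene_ids)
  expect_identical(m2$coefficients, m$coefficients)
  expect_identical(unname(m2$pc_loadings), unname(m$pc_loadings))
  expect_identical(m2$threshold, m$threshold)
  sc1 <- score_cohort(m, p$expr); sc2 <- score_cohort(m2, p$expr)
  expect_identical(sc1$raw_score, sc2$raw_score)
})
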