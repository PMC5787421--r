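# discovery: sensitivity classing, t-test / correlation screens, BH, panel choice.

test_that("classify_sensitivity forms tertiles on a ladder and documents ties", {
  act <- drug_activity(setNames(as.numeric(1:9), paste0("c", 1:9)))
  cl <- classify_sensitivity(act, 1 / 3, 2 / 3)
  expect_identical(unname(cl$class[1:3]), rep("resistant", 3))
  expect_identical(unname(cl$class[4:6]), rep("intermediate", 3))
  expect_identical(unname(cl$class[7:9]), rep("sensitive", 3))

  # ties straddling a cut go to the extreme class; verify against explicit
  # enumeration of the quantile definition
  a <- c(1, 1, 1, 2, 2, 3, 3, 3, 3)
  act2 <- drug_activity(setNames(a, paste0("c", 1:9)))
  cl2 <- classify_sensitivity(act2, 1 / 3, 2 / 3)
  ql <- quantile(a, 1 / 3, names = FALSE)
  qu <- quantile(a, 2 / 3, names = FALSE)
  expected <- ifelse(a >= qu, "sensitive", ifelse(a <= ql, "resistant", "intermediate"))
  expect_identical(unname(cl2$class), expected)
  # the class ordering invariant: every sensitive >= every intermediate >= resistant
  expect_true(min(a[cl2$class == "sensitive"]) >=
                max(a[cl2$class == "intermediate"]))
  expect_true(max(a[cl2$class == "resistant"]) <=
                min(a[cl2$class == "intermediate"]))

  # constant activity cannot even be constructed as a drug_activity
  expect_error(drug_activity(setNames(rep(1, 4), paste0("c", 1:4))), "identical")
  # the extreme-to-the-tie rule keeps both extreme classes non-empty even
  # under heavy ties (the intermediate class may empty out instead)
  act3 <- drug_activity(setNames(c(1, 2, 2, 2, 2, 2, 2, 2, 2), paste0("c", 1:9)))
  cl3 <- classify_sensitivity(act3, 1 / 3, 2 / 3)
  expect_true(any(cl3$class == "sensitive") && any(cl3$class == "resistant"))
})

test_that("discover_ttest finds a planted shift, is antisymmetric, matches t.test", {
  set.seed(10)
  expr <- rand_expr(20, 18, label = "panel")
  act <- drug_activity(setNames(c(rnorm(9, 0), rnorm(9, 5)),
                                sample_ids(expr)), "d")
  cl <- classify_sensitivity(act)
  sens <- names(cl$class)[cl$class == "sensitive"]
  v <- expr$values
  v["G001", sens] <- v["G001", sens] + 10
  expr <- expression_matrix(v, "panel")
  bs <- discover_ttest(expr, cl, fdr = 0.05)
  expect_identical(bs$records$gene_id[1L], "G001")
  expect_lt(bs$records$q_value[1L], 0.05)
  expect_equal(bs$records$direction[1L], 1)

  # swapping class labels flips statistics, leaves p and q unchanged
  cl_sw <- cl
  cl_sw$class[cl$class == "sensitive"] <- "resistant"
  cl_sw$class[cl$class == "resistant"] <- "sensitive"
  bs_sw <- discover_ttest(expr, cl_sw, fdr = 0.05)
  m <- match(bs$full$gene_id, bs_sw$full$gene_id)
  expect_equal(bs_sw$full$statistic[m], -bs$full$statistic)
  expect_equal(bs_sw$full$p_value[m], bs$full$p_value, tolerance = 1e-12)

  # agreement with a per-gene stats::t.test loop to 1e-10
  res <- names(cl$class)[cl$class == "resistant"]
  for (g in sample(gene_ids(expr), 8)) {
    tt <- t.test(expr$values[g, sens], expr$values[g, res])
    i <- match(g, bs$full$gene_id)
    expect_equal(bs$full$statistic[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(bs$full$p_value[i], tt$p.value, tolerance = 1e-10)
  }

  # constant-in-both-classes gene is flagged with p = 1, not dropped
  v2 <- v; v2["G002", ] <- 7
  bs2 <- discover_ttest(expression_matrix(v2, "panel"), cl)
  i <- match("G002", bs2$full$gene_id)
  expect_true(bs2$full$flagged[i])
  expect_equal(bs2$full$p_value[i], 1)
})

test_that("t-test screen controls the FDR under the global null", {
  set.seed(11)
  n_rep <- 200
  fdp <- replicate(n_rep, {
    expr <- rand_expr(1000, 20, label = "null")
    act <- drug_activity(setNames(rnorm(20), sample_ids(expr)))
    cl <- classify_sensitivity(act)
    bs <- discover_ttest(expr, cl, fdr = 0.05)
    nrow(bs$records) > 0   # every discovery is false here
  })
  # P(any false discovery) <= alpha under BH with independent nulls;
  # allow 3 binomial SEs above 0.05
  expect_lte(mean(fdp), 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("discover_correlation matches cor.test, recovers planted correlation", {
  set.seed(12)
  expr <- rand_expr(30, 25, label = "panel")
  act <- drug_activity(setNames(rnorm(25), sample_ids(expr)))
  # gene equal to the activity vector -> r = 1 and first rank
  v <- expr$values
  v["G001", ] <- act$activity[sample_ids(expr)]
  v["G002", ] <- -act$activity[sample_ids(expr)]
  expr <- expression_matrix(v, "panel")
  bs <- discover_correlation(expr, act, fdr = 0.05)
  expect_setequal(bs$records$gene_id[1:2], c("G001", "G002"))
  full <- bs$full
  expect_equal(full$statistic[full$gene_id == "G001"], 1)
  expect_equal(full$statistic[full$gene_id == "G002"], -1)
  expect_equal(full$direction[full$gene_id == "G002"], -1)
  # agreement with per-gene cor.test
  for (g in sprintf("G%03d", 3:10)) {
    ct <- cor.test(expr$values[g, sample_ids(expr)], unname(act$activity))
    i <- match(g, full$gene_id)
    expect_equal(full$statistic[i], unname(ct$estimate), tolerance = 1e-10)
    expect_equal(full$p_value[i], ct$p.value, tolerance = 1e-10)
  }

  # planted-correlation recovery: 20 signal genes among 520, n = 60 lines
  n_seeds <- 100
  stats <- t(replicate(n_seeds, {
    n <- 60
    a <- rnorm(n)
    g_sig <- 20; g_null <- 500
    vals <- rbind(
      t(replicate(g_sig, 0.8 / sqrt(1 - 0.8^2) * a + rnorm(n))),
      matrix(rnorm(g_null * n), g_null, n))
    dimnames(vals) <- list(sprintf("G%03d", seq_len(g_sig + g_null)),
                           sprintf("S%03d", seq_len(n)))
    e <- expression_matrix(vals, "sim")
    da <- drug_activity(setNames(a, sample_ids(e)))
    found <- discover_correlation(e, da, fdr = 0.05)$records$gene_id
    planted <- sprintf("G%03d", seq_len(g_sig))
    c(recall = length(intersect(found, planted)) / g_sig,
      fdp = if (length(found)) length(setdiff(found, planted)) / length(found) else 0)
  }))
  expect_gte(mean(stats[, "recall"]), 0.95)
  expect_lte(mean(stats[, "fdp"]), 0.1)
})

test_that("bh_fdr matches the step-up formula and its invariances", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(13)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))^2
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12) && all(q <= 1))
    perm <- sample(length(p))
    expect_equal(bh_fdr(p[perm]), q[perm], tolerance = 1e-12)
  }
})

test_that("select_panel picks the largest significant count, ties lexicographic", {
  set.seed(14)
  mk <- function(label, n_sig) {
    full <- data.frame(gene_id = sprintf("G%02d", 1:20),
                       statistic = c(rep(10, n_sig), rep(0.1, 20 - n_sig)),
                       p_value = c(rep(1e-6, n_sig), rep(0.9, 20 - n_sig)),
                       stringsAsFactors = FALSE)
    full$q_value <- bh_fdr(full$p_value)
    full$direction <- 1; full$flagged <- FALSE
    concord:::.biomarker_set(full, 0.05, label, "d", "ttest")
  }
  chosen <- select_panel(list(mk("NCI-60", 15), mk("GDSC", 4), mk("CCLE", 2)))
  expect_identical(chosen$panel_label, "NCI-60")
  expect_identical(select_panel(list(mk("B", 10), mk("A", 10)))$panel_label, "A")
  expect_error(select_panel(list(mk("A", 0), mk("B", 0))), "no informative panel")
})
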