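# coxen: correlation matrices, rc(j), permutation null, gate, three-way triage.

test_that("gene_correlation_matrix matches a double-loop oracle", {
  set.seed(20)
  e <- rand_expr(6, 20)
  cm <- gene_correlation_matrix(e)
  for (i in 1:6) for (j in 1:6)
    expect_equal(cm$values[i, j],
                 cor(e$values[i, ], e$values[j, ]), tolerance = 1e-12)
  expect_equal(cm$values, t(cm$values))
  expect_equal(unname(diag(cm$values)), rep(1, 6))

  # identical rows give off-diagonal 1; a negated row gives -1
  v <- e$values
  v[2, ] <- v[1, ]
  v[3, ] <- -v[1, ]
  cm2 <- gene_correlation_matrix(expression_matrix(v, "x"))
  expect_equal(cm2$values[1, 2], 1)
  expect_equal(cm2$values[1, 3], -1)

  v[4, ] <- 3
  expect_error(gene_correlation_matrix(expression_matrix(v, "x")), "G004")
})

test_that("coxen_coefficients: self-concordance, anti-concordance, oracle equality", {
  set.seed(21)
  U <- gene_correlation_matrix(rand_expr(8, 25, "A"))
  # U = V -> rc = 1 in both diagonal modes
  for (mode in c("excluded", "included")) {
    cc <- coxen_coefficients(U, U, diagonal_mode = mode)
    expect_equal(unname(cc$rc), rep(1, 8), tolerance = 1e-12)
  }
  # negated off-diagonal -> rc = -1 in excluded mode
  vneg <- -U$values; diag(vneg) <- 1
  Vneg <- structure(list(gene_ids = U$gene_ids, values = vneg,
                         source_label = "neg"), class = "correlation_matrix")
  cc <- coxen_coefficients(U, Vneg, diagonal_mode = "excluded")
  expect_equal(unname(cc$rc), rep(-1, 8), tolerance = 1e-12)

  # random paired systems vs brute-force column-correlation oracle
  for (rep in 1:20) {
    ng <- sample(8:15, 1)
    U2 <- gene_correlation_matrix(rand_expr(ng, 30, "A"))
    V2 <- gene_correlation_matrix(rand_expr(ng, 30, "B"))
    for (mode in c("excluded", "included")) {
      cc2 <- coxen_coefficients(U2, V2, diagonal_mode = mode)
      expect_equal(unname(cc2$rc), oracle_rc(U2$values, V2$values, mode),
                   tolerance = 1e-10)
    }
  }

  # rc invariant under a simultaneous identical gene permutation
  ng <- 10
  ea <- rand_expr(ng, 30, "A"); eb <- rand_expr(ng, 30, "B")
  U3 <- gene_correlation_matrix(ea); V3 <- gene_correlation_matrix(eb)
  cc3 <- coxen_coefficients(U3, V3)
  perm <- sample(ng)
  Up <- structure(list(gene_ids = U3$gene_ids[perm],
                       values = U3$values[perm, perm], source_label = "A"),
                  class = "correlation_matrix")
  Vp <- structure(list(gene_ids = V3$gene_ids[perm],
                       values = V3$values[perm, perm], source_label = "B"),
                  class = "correlation_matrix")
  cc3p <- coxen_coefficients(Up, Vp)
  expect_equal(unname(cc3p$rc), unname(cc3$rc[perm]), tolerance = 1e-12)

  # mismatched gene order is rejected
  expect_error(coxen_coefficients(U3, Vp), "mismatch")
})

test_that("zero-variance columns yield NA rc, not fabricated values", {
  # a 3-gene system where one gene is equi-correlated with the others
  ids <- c("G1", "G2", "G3", "G4")
  u <- diag(4)
  u[2, 1] <- u[3, 1] <- u[4, 1] <- 0.5   # G1 equi-correlated with everyone
  u[3, 2] <- 0.2; u[4, 2] <- 0.8; u[4, 3] <- 0.3
  u[upper.tri(u)] <- t(u)[upper.tri(u)]
  # column 1 of u (excluding the diagonal) is constant 0.5
  U <- structure(list(gene_ids = ids, values = u, source_label = "A"),
                 class = "correlation_matrix")
  set.seed(22)
  V <- gene_correlation_matrix(rand_expr(4, 20, "B", prefix = "G"))
  V$gene_ids <- ids; dimnames(V$values) <- list(ids, ids)
  cc <- coxen_coefficients(U, V, diagonal_mode = "excluded")
  expect_true(is.na(cc$rc[["G1"]]))
  expect_true(all(!is.na(cc$rc[c("G2", "G3", "G4")])))
})

test_that("coxen_null is deterministic, rejects coarse B, and has power", {
  set.seed(23)
  ea <- rand_expr(20, 30, "A"); eb <- rand_expr(20, 30, "B")
  genes <- gene_ids(ea)
  n1 <- coxen_null(ea, eb, genes, B = 100, seed = 42)
  n2 <- coxen_null(ea, eb, genes, B = 100, seed = 42)
  expect_identical(n1$p_values, n2$p_values)
  expect_identical(n1$cutoff, n2$cutoff)
  expect_error(coxen_null(ea, eb, genes, B = 99), "too coarse")

  # planted shared structure: planted genes get smaller p than null genes
  wins <- replicate(40, {
    pr <- shared_structure_pair(n_genes = 50, n_shared = 30, n1 = 40, n2 = 40)
    nr <- coxen_null(pr$a, pr$b, gene_ids(pr$a), B = 120, seed = NULL)
    median(nr$p_values[pr$shared_genes]) < median(nr$p_values[pr$other_genes])
  })
  expect_gte(mean(wins), 0.95)
})

test_that("coxen_distribution composes alignment and rc", {
  set.seed(24)
  a <- rand_expr(12, 25, "A")
  cc <- coxen_distribution(gene_ids(a), a, a)
  expect_equal(unname(cc$rc), rep(1, 12), tolerance = 1e-12)
  # sample order in either cohort is irrelevant
  b <- expression_matrix(a$values[, sample(ncol(a$values))], "Aperm")
  cc2 <- coxen_distribution(gene_ids(a), a, b)
  expect_equal(cc2$rc, cc$rc, tolerance = 1e-12)
  # shared latent factor on half the biomarkers: those genes have higher rc
  pr <- shared_structure_pair(n_genes = 40, n_shared = 20, n1 = 60, n2 = 60)
  cc3 <- coxen_distribution(gene_ids(pr$a), pr$a, pr$b)
  expect_gt(mean(cc3$rc[pr$shared_genes]), mean(cc3$rc[pr$other_genes]))
})

test_that("gate_cancer_types: dominance, exact-enumeration oracle, Bonferroni", {
  set.seed(25)
  mkc <- function(rc, label) structure(
    list(gene_ids = sprintf("G%02d", seq_along(rc)), rc = rc,
         pair_label = label, diagonal_mode = "excluded", p_values = NULL),
    class = "coxen_coefficients")
  ref <- mkc(c(0.31, 0.42, 0.55, 0.28, 0.49, 0.36), "w1")
  w2 <- mkc(ref$rc + 0.2, "w2")          # higher median: not the reference
  dom <- mkc(ref$rc + 1e3, "dominating") # every value above every reference value
  g <- gate_cancer_types(list(ref, w2), list(dominating = dom), alpha = 0.025)
  expect_identical(attr(g, "reference_label"), "w1")
  expect_gt(g$p_value[1], 0.95)
  expect_true(g$suitable[1])

  # shifted-down candidate: raw p matches exact rank-sum enumeration (n <= 8)
  for (i in 1:10) {
    x <- runif(sample(4:8, 1)); y <- runif(sample(4:8, 1)) + runif(1, 0, 0.8)
    cand <- mkc(x, "cand")
    refc <- mkc(y, "ref")
    g2 <- gate_cancer_types(list(refc), list(cand = cand), alpha = 0.025)
    expect_equal(g2$p_value[1], oracle_ranksum_less(x, y), tolerance = 1e-12)
  }

  # Bonferroni arithmetic decides suitability with three candidates
  borderline <- mkc(ref$rc - 0.12, "borderline")
  g3 <- gate_cancer_types(list(ref), list(a = dom, b = dom, c = borderline),
                          alpha = 0.025)
  i <- match("c", g3$candidate)
  expect_equal(g3$p_adjusted[i], min(1, 3 * g3$p_value[i]))
  expect_identical(g3$suitable[i], g3$p_adjusted[i] > 0.025)

  # adding a dominating candidate never changes another candidate's raw p
  g4 <- gate_cancer_types(list(ref), list(c = borderline), alpha = 0.025)
  expect_equal(g4$p_value[g4$candidate == "c"], g3$p_value[i], tolerance = 1e-12)

  expect_error(gate_cancer_types(list(), list(cand = dom)), "at least one")
})

test_that("threeway_select keeps all-pair concordant genes, drops partial ones", {
  set.seed(26)
  # three systems: genes G001..G030 share structure everywhere (programs 1-3);
  # G031..G045 share their own programs (4-5) between sys1 and sys2 only;
  # G046..G070 are noise
  G <- 70; K <- 5; n <- 60
  dirs <- matrix(0, G, K)
  d1 <- matrix(rnorm(30 * 3), 30, 3)
  dirs[1:30, 1:3] <- d1 / sqrt(rowSums(d1^2))
  d2 <- matrix(rnorm(15 * 2), 15, 2)
  dirs[31:45, 4:5] <- d2 / sqrt(rowSums(d2^2))
  ids <- sprintf("G%03d", 1:G)
  mask12 <- c(rep(1, 45), rep(0, 25))
  mask3 <- c(rep(1, 30), rep(0, 40))
  mk <- function(mask, label, n) {
    f <- matrix(rnorm(K * n), K, n)
    v <- (dirs * mask) %*% f + matrix(rnorm(G * n), G, n)
    dimnames(v) <- list(ids, sprintf("%s%02d", label, 1:n))
    expression_matrix(v, label)
  }
  concordant <- ids[1:30]; pairwise <- ids[31:45]
  stats <- sapply(1:5, function(s) {
    set.seed(100 + s)
    s1 <- mk(mask12, "s1", n); s2 <- mk(mask12, "s2", n); s3 <- mk(mask3, "s3", n)
    tw <- suppressWarnings(
      threeway_select(ids, s1, s2, s3, fdr = 0.2, B = 150, seed = s))
    # survivors are a subset of the initial set and of each per-pair set
    expect_true(all(tw$gene_ids %in% ids))
    expect_lte(length(tw$gene_ids), min(tw$counts[1:3]))
    c(recall = length(intersect(tw$gene_ids, concordant)) / 30,
      leak = length(intersect(tw$gene_ids, pairwise)) / 15)
  })
  expect_gte(mean(stats["recall", ]), 0.8)
  expect_lte(mean(stats["leak", ]), 0.2)
})
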