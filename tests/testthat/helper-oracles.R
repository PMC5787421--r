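# Shared fixtures and independent oracles used across test files.
# Oracles are deliberately naive (loops, enumeration, explicit formulas) and
# never share code with the implementation paths they check.

# random genes x samples expression matrix
rand_expr <- function(n_genes, n_samples, label = "sys", prefix = "G",
                      sample_prefix = "S") {
  v <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
              dimnames = list(sprintf("%s%03d", prefix, seq_len(n_genes)),
                              sprintf("%s%03d", sample_prefix, seq_len(n_samples))))
  expression_matrix(v, system_label = label)
}

# brute-force rc(j): materialize the two column vectors and call cor()
oracle_rc <- function(U, V, diagonal_mode = "excluded") {
  n <- nrow(U)
  vapply(seq_len(n), function(j) {
    ks <- if (diagonal_mode == "included") seq_len(n) else setdiff(seq_len(n), j)
    u <- U[ks, j]; v <- V[ks, j]
    if (stats::sd(u) == 0 || stats::sd(v) == 0) return(NA_real_)
    stats::cor(u, v)
  }, numeric(1L))
}

# explicit BH step-up: q_(i) = min_{j >= i} p_(j) * m / j, capped at 1
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- ps * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# AUC by the O(n_pos x n_neg) pairwise concordance loop (ties = 1/2)
oracle_auc <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  total <- 0
  for (a in sp) for (b in sn)
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  total / (length(sp) * length(sn))
}

# exact one-sided binomial upper tail by explicit pmf summation
oracle_binom_upper <- function(x, n, p0) {
  sum(vapply(x:n, function(k) choose(n, k) * p0^k * (1 - p0)^(n - k), numeric(1L)))
}

# exact rank-sum enumeration: distribution of the Mann-Whitney U of group x
# under all assignments of the combined values to the two groups
oracle_ranksum_less <- function(x, y) {
  m <- length(x); n <- length(y)
  comb <- c(x, y)
  r <- rank(comb)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  sets <- utils::combn(m + n, m)
  u_all <- apply(sets, 2L, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  mean(u_all <= u_obs)
}

# Kaplan-Meier product-limit estimate by explicit risk-table walk
oracle_km <- function(times, events) {
  ut <- sort(unique(times[events == 1]))
  s <- 1
  out <- data.frame(time = ut, survival = NA_real_)
  for (i in seq_along(ut)) {
    at_risk <- sum(times >= ut[i])
    d <- sum(times == ut[i] & events == 1)
    s <- s * (1 - d / at_risk)
    out$survival[i] <- s
  }
  out
}

# two-group log-rank chi-square by explicit observed-minus-expected tables
# with the hypergeometric variance
oracle_logrank <- function(times, events, groups) {
  g <- as.integer(factor(groups))
  ut <- sort(unique(times[events == 1]))
  o_minus_e <- 0; v <- 0
  for (t in ut) {
    at_risk <- times >= t
    n_tot <- sum(at_risk)
    n1 <- sum(at_risk & g == 1L)
    d_tot <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g == 1L)
    e1 <- d_tot * n1 / n_tot
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n_tot > 1)
      v <- v + d_tot * (n1 / n_tot) * (1 - n1 / n_tot) * (n_tot - d_tot) / (n_tot - 1)
  }
  (o_minus_e)^2 / v
}

# exhaustive model-selection oracle: AUC by pair counting, MWW p via
# wilcox.test, rule applied by explicit loops; threshold by trying every
# midpoint of consecutive distinct scores
oracle_select <- function(score_list, labels, sizes, alpha = 0.05) {
  k <- length(score_list)
  auc <- numeric(k); p <- numeric(k)
  for (i in seq_len(k)) {
    auc[i] <- oracle_auc(score_list[[i]], labels)
    p[i] <- suppressWarnings(stats::wilcox.test(
      score_list[[i]][labels == 1], score_list[[i]][labels == 0],
      alternative = "greater", exact = FALSE, correct = FALSE)$p.value)
  }
  pool <- which(p < alpha)
  if (!length(pool)) pool <- seq_len(k)
  best <- pool[1L]
  for (i in pool)
    if (auc[i] > auc[best] || (auc[i] == auc[best] && sizes[i] < sizes[best]))
      best <- i
  s <- score_list[[best]]
  u <- sort(unique(s))
  mids <- (u[-1] + u[-length(u)]) / 2
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  best_j <- -Inf; best_t <- NA_real_
  for (t in mids) {
    pos <- s >= t
    j <- sum(pos & labels == 1) / npos + sum(!pos & labels == 0) / nneg - 1
    if (j > best_j + 1e-12 || (abs(j - best_j) <= 1e-12 && t > best_t)) {
      best_j <- j; best_t <- t
    }
  }
  list(chosen = best, threshold = best_t, youden_j = best_j)
}

# small synthetic two-system pair sharing latent structure on some genes
shared_structure_pair <- function(n_genes = 50, n_shared = 30, n1 = 40, n2 = 40,
                                  k = 2, lambda = 1) {
  dirs <- matrix(rnorm(n_genes * k), n_genes, k)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  ids <- sprintf("G%03d", seq_len(n_genes))
  shared <- seq_len(n_shared)
  make <- function(n, label, own_dirs) {
    f <- matrix(rnorm(k * n), k, n)
    v <- lambda * own_dirs %*% f + matrix(rnorm(n_genes * n), n_genes, n)
    dimnames(v) <- list(ids, sprintf("%s%03d", label, seq_len(n)))
    expression_matrix(v, system_label = label)
  }
  d1 <- dirs
  d2 <- dirs
  if (n_shared < n_genes) {
    other <- setdiff(seq_len(n_genes), shared)
    redraw <- matrix(rnorm(length(other) * k), length(other), k)
    d2[other, ] <- redraw / sqrt(rowSums(redraw^2))
  }
  list(a = make(n1, "A", d1), b = make(n2, "B", d2),
       shared_genes = ids[shared], other_genes = setdiff(ids, ids[shared]))
}
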