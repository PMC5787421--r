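# Internal helpers shared across modules.

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards. seed = NULL leaves the RNG untouched.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    .stopf("`seed` must be a single finite number")
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# rank/n percentile with average ranks for ties; 1 = largest value.
.percentile_ranks <- function(x) {
  rank(x, ties.method = "average") / length(x)
}

#' Wilcoxon rank-sum p-value with exact small-sample enumeration
#'
#' Two-group rank-sum test used by the cancer-type gate. The null is computed
#' exactly (enumeration of the rank-sum distribution) when both groups have at
#' most 8 observations and there are no ties, and by the normal approximation
#' with tie correction otherwise.
#'
#' @param x,y Numeric vectors, the two groups.
#' @param alternative `"less"` (x stochastically smaller than y), `"greater"`,
#'   or `"two.sided"`.
#' @return A single p-value.
#' @export
rank_sum_test <- function(x, y, alternative = c("less", "greater", "two.sided")) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L) .stopf("both groups must be non-empty")
  if (anyNA(x) || anyNA(y)) .stopf("rank_sum_test: missing values not allowed")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && length(x) <= 8L && length(y) <= 8L
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative,
                       exact = exact, correct = TRUE)$p.value
  )
}
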