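#' Permutation t-test
#'
#' Two-sample comparison with a permutation null, suited to the very small
#' group sizes of per-pond summary statistics. Unpaired: the statistic is the
#' Welch t, and the null is built by reshuffling group labels. Paired: the
#' statistic is the mean difference and the null is built by sign-flipping
#' the paired differences; for `n <= 20` pairs all `2^n` sign patterns are
#' enumerated and the p-value is exact. Two-sided throughout; random nulls
#' carry the plus-one correction.
#'
#' @param x,y numeric vectors (matched order when `paired = TRUE`, e.g. the
#'   same ponds).
#' @param paired logical.
#' @param n_perm permutations (ignored when the paired null is enumerated).
#' @return list with `statistic`, `p`, `method`, `n_perm`, `exact`.
#' @export
permutation_t_test <- function(x, y, paired = FALSE, n_perm = 9999L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (paired) {
    if (length(x) != length(y)) stopf("paired test needs equal lengths")
    d <- x - y
    n <- length(d)
    if (n < 2L) stopf("need at least 2 pairs")
    obs <- mean(d)
    if (all(d == 0))
      return(list(statistic = 0, p = 1, method = "paired sign-flip",
                  n_perm = 0L, exact = TRUE))
    if (n <= 20L) {
      signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
      stats <- as.vector(signs %*% d) / n
      p <- mean(abs(stats) >= abs(obs) - 1e-12)
      return(list(statistic = obs, p = p, method = "paired sign-flip",
                  n_perm = nrow(signs), exact = TRUE))
    }
    stats <- vapply(seq_len(n_perm), function(b)
      mean(d * sample(c(-1, 1), n, replace = TRUE)), numeric(1L))
    p <- (1 + sum(abs(stats) >= abs(obs) - 1e-12)) / (n_perm + 1)
    return(list(statistic = obs, p = p, method = "paired sign-flip",
                n_perm = n_perm, exact = FALSE))
  }
  if (length(x) < 2L || length(y) < 2L) stopf("need n >= 2 per group")
  welch <- function(a, b) {
    (mean(a) - mean(b)) /
      sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
  }
  pool <- sort(c(x, y))   # canonical pool: p is invariant to swapping x and y
  if (stats::var(pool) == 0)
    return(list(statistic = 0, p = 1, method = "label permutation (Welch t)",
                n_perm = 0L, exact = TRUE))
  obs <- welch(x, y)
  k <- min(length(x), length(y))   # |t| is the same for complementary splits
  stats <- vapply(seq_len(n_perm), function(b) {
    idx <- sample.int(length(pool), k)
    welch(pool[idx], pool[-idx])
  }, numeric(1L))
  p <- (1 + sum(abs(stats) >= abs(obs) - 1e-12)) / (n_perm + 1)
  list(statistic = obs, p = p, method = "label permutation (Welch t)",
       n_perm = n_perm, exact = FALSE)
}

# One-way ANOVA F statistic for a list of groups.
anova_f <- function(groups) {
  k <- length(groups)
  n <- lengths(groups)
  N <- sum(n)
  means <- vapply(groups, mean, numeric(1L))
  grand <- sum(n * means) / N
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1L)))
  if (ssw == 0) return(if (ssb == 0) 0 else Inf)
  (ssb / (k - 1)) / (ssw / (N - k))
}

#' Resampled one-way ANOVA
#'
#' Observed one-way F statistic with a resampling null, for comparing a
#' summary statistic across life stages when group sizes are far too small
#' for the parametric F distribution. Two nulls are available:
#' `method = "permutation"` (default, recommended) shuffles group labels;
#' `method = "bootstrap"` pools all values and draws group-sized resamples
#' with replacement from the pool. Both report
#' `p = (1 + #{F* >= F_obs}) / (n_resamples + 1)`.
#'
#' @param groups list of numeric vectors, each of length >= 2.
#' @param n_resamples resampling replicates.
#' @param method `"permutation"` or `"bootstrap"`.
#' @return list with `f`, `p`, `method`, `n_resamples`.
#' @export
bootstrap_anova <- function(groups, n_resamples = 9999L,
                            method = c("permutation", "bootstrap")) {
  method <- match.arg(method)
  if (length(groups) < 2L) stopf("need at least 2 groups")
  if (any(lengths(groups) < 2L)) stopf("every group needs n >= 2")
  groups <- lapply(groups, as.numeric)
  obs <- anova_f(groups)
  pool <- unlist(groups, use.names = FALSE)
  n <- lengths(groups)
  idx_end <- cumsum(n)
  idx_start <- c(1L, utils::head(idx_end, -1L) + 1L)
  fs <- vapply(seq_len(n_resamples), function(b) {
    v <- if (method == "permutation") sample(pool)
         else sample(pool, length(pool), replace = TRUE)
    anova_f(mapply(function(s, e) v[s:e], idx_start, idx_end,
                   SIMPLIFY = FALSE))
  }, numeric(1L))
  list(f = obs, p = (1 + sum(fs >= obs - 1e-12)) / (n_resamples + 1),
       method = method, n_resamples = n_resamples)
}

#' Mean and population standard deviation
#'
#' Summary convention for small fixed sets of per-pond values (all five
#' ponds are observed, not sampled): the standard deviation uses the `n`
#' denominator, so a single value has sd 0. Sample-denominator summaries are
#' available via `denominator = "n-1"`.
#'
#' @param values numeric vector, length >= 1.
#' @param denominator `"n"` (population, default) or `"n-1"` (sample).
#' @return list with `mean`, `sd`, `n`.
#' @examples
#' summarize_with_population_sd(c(62, 70, 60))  # mean 64, sd 4.32
#' @export
summarize_with_population_sd <- function(values, denominator = c("n", "n-1")) {
  denominator <- match.arg(denominator)
  values <- as.numeric(values)
  if (!length(values)) stopf("empty input")
  n <- length(values)
  m <- mean(values)
  ss <- sum((values - m)^2)
  s <- if (denominator == "n") sqrt(ss / n)
       else if (n > 1L) sqrt(ss / (n - 1L)) else 0
  if (n == 1L) s <- 0
  list(mean = m, sd = s, n = n)
}
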