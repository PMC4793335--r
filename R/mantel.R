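# Shared machinery: r between the upper triangles, and vectorised
# computation of r over a set of row/column permutations of one matrix.

mantel_align <- function(gdist, ddist) {
  validate_dist_matrix(gdist); validate_dist_matrix(ddist)
  if (!setequal(rownames(gdist), rownames(ddist)))
    stopf("distance matrices have different labels")
  ddist <- ddist[rownames(gdist), rownames(gdist)]
  n <- nrow(gdist)
  if (n < 3L) stopf("need at least 3 labels")
  list(g = upper_vec(gdist), dm = ddist, n = n)
}

# r between g (fixed) and the upper triangle of dm permuted by each row of
# `perms`. Permuting labels permutes the pair multiset, so the permuted
# vectors share mean(d) and sd(d); the correlation reduces to a single
# matrix product.
mantel_perm_r <- function(g, dm, perms) {
  n <- ncol(perms)
  pairs <- which(upper.tri(dm), arr.ind = TRUE)
  d <- upper_vec(dm)
  if (stats::sd(g) == 0 || stats::sd(d) == 0)
    stopf("constant distance matrix: Mantel r undefined")
  m <- nrow(pairs)
  idx <- perms[, pairs[, 1L]] + (perms[, pairs[, 2L]] - 1L) * n
  P <- matrix(dm[idx], nrow(perms), m)
  gc <- g - mean(g)    # centred, so the mean(d) cross term vanishes
  as.vector(P %*% gc) / ((m - 1) * stats::sd(d) * stats::sd(g))
}

#' Simple Mantel test by permutation
#'
#' Pearson correlation `r` between the upper triangles of two labelled
#' distance matrices, with significance from simultaneous row/column
#' permutations of the second matrix. The default tail is one-sided upper
#' (isolation-by-distance predicts a positive correlation);
#' `tail = "two-sided"` uses `|r|`. The p-value carries the plus-one
#' correction `p = (1 + #{r* >= r_obs}) / (n_perm + 1)`, and permuted values
#' tying with the observed one count as extreme.
#'
#' With few labels the attainable p-value floor is set by the number of
#' distinct relabelings, not by `n_perm`: for 5 labels there are only
#' `5! = 120` arrangements, so no test on 5 populations can report
#' `p < 1/120` (about 0.0083). See [mantel_exact()] for full enumeration.
#'
#' @param gdist,ddist labelled symmetric distance matrices over the same
#'   label set (e.g. genetic and geographic).
#' @param n_perm number of random permutations.
#' @param tail `"greater"` (default) or `"two-sided"`.
#' @return object of class `mantel_result`: list with `r`, `p`, `n_perm`,
#'   `exact = FALSE`, `tail`.
#' @export
mantel_test <- function(gdist, ddist, n_perm = 9999,
                        tail = c("greater", "two-sided")) {
  tail <- match.arg(tail)
  al <- mantel_align(gdist, ddist)
  r_obs <- stats::cor(al$g, upper_vec(al$dm))
  perms <- t(vapply(seq_len(n_perm), function(i) sample.int(al$n),
                    integer(al$n)))
  r_perm <- mantel_perm_r(al$g, al$dm, perms)
  eps <- 1e-12
  extreme <- if (tail == "greater") r_perm >= r_obs - eps
             else abs(r_perm) >= abs(r_obs) - eps
  structure(list(r = r_obs, p = (1 + sum(extreme)) / (n_perm + 1),
                 n_perm = n_perm, exact = FALSE, tail = tail),
            class = "mantel_result")
}

#' Exact Mantel test by full enumeration
#'
#' Enumerates all `n!` relabelings (identity included) and reports
#' `p = #{r* >= r_obs} / n!` (or the `|r|` version for the two-sided tail).
#' Ties with the observed statistic count as extreme. Refuses `n > 8`
#' (combinatorial guard); designed for small inter-population designs, where
#' enumeration replaces Monte-Carlo error entirely.
#'
#' @inheritParams mantel_test
#' @return object of class `mantel_result` with `exact = TRUE` and
#'   `n_perm = n!`.
#' @export
mantel_exact <- function(gdist, ddist, tail = c("greater", "two-sided")) {
  tail <- match.arg(tail)
  al <- mantel_align(gdist, ddist)
  if (al$n > 8L) stopf("exact enumeration refused for n > 8 (n = %d)", al$n)
  perms <- all_perms(al$n)
  r_perm <- mantel_perm_r(al$g, al$dm, perms)
  r_obs <- stats::cor(al$g, upper_vec(al$dm))
  eps <- 1e-12
  extreme <- if (tail == "greater") r_perm >= r_obs - eps
             else abs(r_perm) >= abs(r_obs) - eps
  structure(list(r = r_obs, p = mean(extreme), n_perm = nrow(perms),
                 exact = TRUE, tail = tail),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel r = %.4f, p = %.5g (%s, %s, n_perm = %d)\n",
              x$r, x$p, x$tail,
              if (x$exact) "exact enumeration" else "permutation", x$n_perm))
  invisible(x)
}
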