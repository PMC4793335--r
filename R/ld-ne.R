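#' Effective population size from linkage disequilibrium
#'
#' Burrows composite-disequilibrium estimator of contemporary Ne. For every
#' pair of loci and every pair of retained alleles (one per locus), the
#' Burrows composite disequilibrium
#' \deqn{\hat\Delta_{AB} = \frac{1}{2S}\sum_i X_{Ai} X_{Bi} - 2\hat p_A \hat p_B}
#' (with \eqn{X_{Ai}} the copy number of allele A in individual i) is
#' standardised to a squared correlation
#' \eqn{\hat r^2 = \hat\Delta^2 / [p_A(1-p_A)\,p_B(1-p_B)]}. The mean
#' \eqn{\hat r^2} is corrected for the sampling contribution `1/S`
#' (Waples-style), and for random mating
#' \deqn{\hat N_e = 1 / (3\,(\bar r^2 - 1/S)).}
#' When the corrected disequilibrium is not positive the estimate is flagged
#' infinite (no drift signal beyond sampling).
#'
#' Alleles below `min_freq` are excluded, the common guard against the
#' upward bias of rare alleles in LD-based estimation.
#'
#' @param x a [genotype_table]; all individuals are treated as one sample.
#' @param min_freq minimum allele frequency for inclusion (default 0.05).
#' @return list with `ne` (estimate, possibly `Inf`), `r2_mean`, `r2_drift`,
#'   `S` (mean pairwise sample size), `n_pairs` (number of allele-pair
#'   comparisons), and `note`.
#' @export
ld_ne <- function(x, min_freq = 0.05) {
  stopifnot(inherits(x, "genotype_table"))
  L <- length(x$loci)
  n <- nrow(x$meta)
  if (n < 10L) warnf("fewer than 10 individuals; LD-Ne will be very noisy")

  # retained alleles and copy-number matrices per locus
  copies <- vector("list", L)
  for (l in seq_len(L)) {
    v1 <- x$a1[, l]; v2 <- x$a2[, l]
    ok <- !is.na(v1)
    al <- sort(unique(c(v1[ok], v2[ok])))
    if (length(al) < 2L) { copies[[l]] <- NULL; next }
    X <- sapply(al, function(a) (v1 == a) + (v2 == a))   # n x A, NA if missing
    p <- colMeans(X, na.rm = TRUE) / 2
    keep <- p >= min_freq
    if (!any(keep)) { copies[[l]] <- NULL; next }
    copies[[l]] <- X[, keep, drop = FALSE]
  }
  usable <- which(!vapply(copies, is.null, logical(1L)))
  if (length(usable) < 2L)
    stopf("need at least 2 polymorphic loci with retained alleles")

  r2 <- numeric(0); Ss <- numeric(0)
  for (ii in seq_len(length(usable) - 1L)) for (jj in seq(ii + 1L, length(usable))) {
    XA_all <- copies[[usable[ii]]]
    XB_all <- copies[[usable[jj]]]
    ok <- !is.na(XA_all[, 1L]) & !is.na(XB_all[, 1L])
    S <- sum(ok)
    if (S < 2L) next
    XA <- XA_all[ok, , drop = FALSE]; XB <- XB_all[ok, , drop = FALSE]
    pA <- colMeans(XA) / 2; pB <- colMeans(XB) / 2
    # Burrows delta for all allele pairs at once
    D <- crossprod(XA, XB) / (2 * S) - 2 * outer(pA, pB)
    denom <- outer(pA * (1 - pA), pB * (1 - pB))
    val <- (D^2 / denom)[denom > 0]
    r2 <- c(r2, val)
    Ss <- c(Ss, rep(S, length(val)))
  }
  if (!length(r2)) stopf("no usable locus pairs")
  r2_mean <- mean(r2)
  S_mean <- mean(Ss)
  r2_drift <- r2_mean - 1 / S_mean
  ne <- if (r2_drift <= 0) Inf else 1 / (3 * r2_drift)
  list(ne = ne, r2_mean = r2_mean, r2_drift = r2_drift, S = S_mean,
       n_pairs = length(r2),
       note = if (is.infinite(ne)) "no LD signal beyond sampling" else "ok")
}
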