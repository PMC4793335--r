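#' Observed heterozygosity per group
#'
#' Per locus, the fraction of non-missing individuals carrying two different
#' alleles; the group value is the unweighted mean over loci with data. Loci
#' at which a group has no genotypes are skipped for that group (pairwise
#' deletion) and recorded in the `skipped` attribute.
#'
#' @param x a [genotype_table].
#' @param grouping see [allele_frequencies()].
#' @return list with `locus` (group x locus matrix of per-locus Ho, `NA`
#'   where a group has no data) and `mean` (named vector of group means).
#' @export
observed_heterozygosity <- function(x, grouping = "pond") {
  g <- resolve_grouping(x, grouping)
  G <- nlevels(g); gi <- as.integer(g)
  L <- length(x$loci)
  ho <- matrix(NA_real_, G, L, dimnames = list(levels(g), x$loci))
  for (l in seq_len(L)) {
    ok <- !is.na(x$a1[, l])
    n <- tabulate(gi[ok], G)
    het <- tabulate(gi[ok & x$a1[, l] != x$a2[, l]], G)
    ho[, l] <- ifelse(n > 0L, het / n, NA_real_)
  }
  if (any(rowSums(!is.na(ho)) == 0L))
    stopf("group(s) with no genotype data at any locus: %s",
          paste(levels(g)[rowSums(!is.na(ho)) == 0L], collapse = ", "))
  means <- rowMeans(ho, na.rm = TRUE)
  structure(list(locus = ho, mean = means),
            skipped = which(is.na(ho), arr.ind = TRUE))
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a standardised subsample of `g`
#' gene copies, computed from the hypergeometric expectation
#' \deqn{A_r = \sum_a \left[1 - \binom{N - N_a}{g} / \binom{N}{g}\right]}
#' where \eqn{N_a} are the allele counts and \eqn{N = \sum_a N_a}. Rarefying
#' to the smallest sample makes richness comparable across groups with
#' unequal sample sizes. The default `g` is twice the smallest per-group
#' non-missing individual count over all groups and loci (the "smallest
#' sample" convention); a per-locus minimum can be supplied instead via `g`.
#'
#' @param x a [genotype_table] or [allele_frequencies()] result.
#' @param grouping see [allele_frequencies()] (ignored when `x` is already an
#'   `allele_freq_table`).
#' @param g rarefaction size in gene copies (`>= 2`). Cells with
#'   `0 < n_gc < g` are an error naming the group/locus; cells with no data
#'   are skipped.
#' @return list with `g`, `locus` (group x locus matrix of per-locus Ar) and
#'   `mean` (named vector of group means over loci with data).
#' @examples
#' # counts {A:9, B:1}: Ar at g = 2 is 1 + (1 - 36/45) = 1.2
#' @export
rarefied_allelic_richness <- function(x, grouping = "pond", g = NULL) {
  af <- if (inherits(x, "allele_freq_table")) x else
    allele_frequencies(x, grouping)
  n_gc <- af$n_gc
  if (is.null(g)) {
    pos <- n_gc[n_gc > 0L]
    if (!length(pos)) stopf("no genotype data at all")
    g <- min(pos)
  }
  g <- as.integer(g)
  if (g < 2L) stopf("rarefaction size g must be >= 2")
  short <- which(n_gc > 0L & n_gc < g, arr.ind = TRUE)
  if (nrow(short))
    stopf("g = %d exceeds gene copies for group '%s' at locus '%s' (n_gc = %d)",
          g, af$groups[short[1L, 1L]], af$loci[short[1L, 2L]],
          n_gc[short[1L, , drop = FALSE]])
  G <- length(af$groups); L <- length(af$loci)
  ar <- matrix(NA_real_, G, L, dimnames = list(af$groups, af$loci))
  for (l in seq_len(L)) {
    cnt <- af$counts[[l]]
    N <- rowSums(cnt)
    for (i in seq_len(G)) {
      if (N[i] == 0L) next
      # P(allele absent from g-subsample) = C(N - N_a, g) / C(N, g)
      keep <- cnt[i, ] > 0L
      p_absent <- exp(lchoose(N[i] - cnt[i, keep], g) - lchoose(N[i], g))
      ar[i, l] <- sum(1 - p_absent)
    }
  }
  list(g = g, locus = ar, mean = rowMeans(ar, na.rm = TRUE))
}

# Per-locus per-group sufficient statistics for Weir-Cockerham estimation:
# sample sizes, allele counts, and per-allele heterozygote-carrier counts.
locus_group_stats <- function(x, g) {
  G <- nlevels(g); gi <- as.integer(g)
  lapply(seq_along(x$loci), function(l) {
    v1 <- x$a1[, l]; v2 <- x$a2[, l]
    ok <- !is.na(v1)
    al <- sort(unique(c(v1[ok], v2[ok])))
    A <- max(length(al), 1L)
    ai1 <- match(v1[ok], al); ai2 <- match(v2[ok], al)
    cnt <- tab2(gi[ok], ai1, G, A) + tab2(gi[ok], ai2, G, A)
    hz <- ok & v1 != v2
    het <- tab2(gi[hz], match(v1[hz], al), G, A) +
           tab2(gi[hz], match(v2[hz], al), G, A)
    list(n = tabulate(gi[ok], G), cnt = cnt, het = het)
  })
}

# Multilocus Weir-Cockerham theta over the groups in `idx` from
# locus_group_stats output: ratio of summed variance components.
wc_theta_from_stats <- function(ls, idx) {
  r <- length(idx)
  num <- den <- 0
  for (st in ls) {
    n_i <- st$n[idx]
    if (any(n_i == 0L)) next          # pairwise deletion of the locus
    nbar <- mean(n_i)
    if (nbar <= 1) next
    sum_n <- sum(n_i)
    nc <- (sum_n - sum(n_i^2) / sum_n) / (r - 1)
    p <- st$cnt[idx, , drop = FALSE] / (2 * n_i)
    h <- st$het[idx, , drop = FALSE] / n_i
    pbar <- colSums(n_i * p) / sum_n
    s2 <- colSums(n_i * sweep(p, 2, pbar)^2) / ((r - 1) * nbar)
    hbar <- colSums(n_i * h) / sum_n
    inner <- pbar * (1 - pbar) - (r - 1) / r * s2
    a <- (nbar / nc) * (s2 - (inner - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (inner - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + sum(a)
    den <- den + sum(a + b + cc)
  }
  if (den == 0) NA_real_ else num / den
}

#' Weir-Cockerham F_ST
#'
#' Multilocus theta from the Weir & Cockerham (1984) variance components:
#' per locus and allele, the among-population (`a`), among-individual
#' (`b`) and within-individual (`c`) components are computed from sample
#' sizes, allele frequencies and observed heterozygote frequencies, and
#' theta is the "ratio of averages" `sum(a) / sum(a + b + c)` over all
#' alleles and loci. Estimates can legitimately be negative in the absence of
#' differentiation and are returned raw (clamp for presentation only).
#' Loci at which a group has no data are dropped for the affected
#' comparison (pairwise deletion).
#'
#' @param x a [genotype_table].
#' @param grouping see [allele_frequencies()].
#' @param pairwise if `TRUE`, return the matrix of pairwise theta values
#'   (each computed from the two samples only); otherwise the global
#'   multilocus theta over all groups.
#' @return a single numeric value, or a labelled symmetric matrix when
#'   `pairwise = TRUE`.
#' @export
wc_fst <- function(x, grouping = "pond", pairwise = FALSE) {
  g <- resolve_grouping(x, grouping)
  if (nlevels(g) < 2L) stopf("need at least 2 groups")
  ls <- locus_group_stats(x, g)
  # pre: every group must have >= 2 individuals at some locus
  max_n <- Reduce(pmax, lapply(ls, `[[`, "n"))
  if (any(max_n < 2L))
    stopf("group(s) with fewer than 2 genotyped individuals at every locus: %s",
          paste(levels(g)[max_n < 2L], collapse = ", "))
  if (!pairwise) return(wc_theta_from_stats(ls, seq_len(nlevels(g))))
  G <- nlevels(g)
  m <- matrix(0, G, G, dimnames = list(levels(g), levels(g)))
  for (i in seq_len(G - 1L)) for (j in seq(i + 1L, G)) {
    m[i, j] <- m[j, i] <- wc_theta_from_stats(ls, c(i, j))
  }
  m
}

#' Cavalli-Sforza & Edwards chord distance
#'
#' Allele-frequency distance on the square-root (angular) geometry of the
#' frequency simplex. With per-locus frequency vectors `p`, `q` and
#' `S_l = sum_a sqrt(p_la * q_la)`:
#' * `variant = "angular"` (default): `D = sqrt(1 - mean_l S_l)`, bounded in
#'   `[0, 1]`;
#' * `variant = "takezaki-nei"`: `D = mean_l (2/pi) sqrt(2 (1 - S_l))`, the
#'   normalisation of Takezaki & Nei (1996).
#'
#' Loci with no data in either member of a pair are skipped for that pair;
#' a pair with no usable loci is an error. The variant used is recorded in
#' the `"variant"` attribute of the result.
#'
#' @param x a [genotype_table] or [allele_frequencies()] result.
#' @param grouping see [allele_frequencies()].
#' @param variant `"angular"` or `"takezaki-nei"`.
#' @return labelled symmetric matrix of chord distances.
#' @export
chord_distance <- function(x, grouping = "pond",
                           variant = c("angular", "takezaki-nei")) {
  variant <- match.arg(variant)
  af <- if (inherits(x, "allele_freq_table")) x else
    allele_frequencies(x, grouping)
  G <- length(af$groups); L <- length(af$loci)
  if (G < 2L) stopf("need at least 2 groups")
  # S[g1, g2] accumulated per locus via sqrt-frequency cross products
  S <- array(NA_real_, c(G, G, L))
  for (l in seq_len(L)) {
    sq <- sqrt(af$freq[[l]])
    s <- sq %*% t(sq)
    s[af$n_gc[, l] == 0L, ] <- NA_real_
    s[, af$n_gc[, l] == 0L] <- NA_real_
    S[, , l] <- s
  }
  m <- matrix(0, G, G, dimnames = list(af$groups, af$groups))
  for (i in seq_len(G - 1L)) for (j in seq(i + 1L, G)) {
    s_l <- S[i, j, ]
    s_l <- s_l[!is.na(s_l)]
    if (!length(s_l))
      stopf("no usable loci for pair %s / %s", af$groups[i], af$groups[j])
    s_l <- pmin(s_l, 1)               # guard rounding above 1
    d <- switch(variant,
      "angular" = sqrt(max(0, 1 - mean(s_l))),
      "takezaki-nei" = mean(2 / pi * sqrt(2 * (1 - s_l))))
    m[i, j] <- m[j, i] <- d
  }
  attr(m, "variant") <- variant
  m
}
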