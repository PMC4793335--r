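# Resampling engines. The per-replicate statistics kernel works on an
# integer-encoded copy of the genotype table so that thousands of bootstrap
# replicates stay cheap: allele codes are replaced by per-locus dictionary
# indices once, and each replicate only tabulates.

encode_table <- function(x, ponds = sort(unique(x$meta$pond))) {
  g <- factor(x$meta$pond, levels = ponds)
  if (anyNA(g)) stopf("individual(s) from ponds outside the pond set")
  n <- nrow(x$meta); L <- length(x$loci)
  e1 <- matrix(NA_integer_, n, L); e2 <- e1
  K <- integer(L)
  for (l in seq_len(L)) {
    al <- sort(unique(c(x$a1[, l], x$a2[, l])))
    al <- al[!is.na(al)]
    K[l] <- max(length(al), 1L)
    e1[, l] <- match(x$a1[, l], al)
    e2[, l] <- match(x$a2[, l], al)
  }
  list(gi = as.integer(g), ponds = ponds, loci = x$loci, K = K,
       e1 = e1, e2 = e2)
}

# Statistics for one replicate: rows (individual indices) and loci_idx
# select the resample. Returns per-pond Ho and Ar means over loci, and
# pairwise Dc / W-C Fst matrices, as requested in `want`.
rep_stats <- function(enc, rows, loci_idx, want, variant = "angular",
                      g_rar = NULL) {
  gi <- enc$gi[rows]; G <- length(enc$ponds)
  nl <- length(loci_idx)
  ho_mat <- matrix(NA_real_, G, nl)
  acc <- matrix(0, G, G); L_pair <- matrix(0L, G, G)
  ls <- vector("list", nl)
  cnts <- vector("list", nl); ns <- matrix(0L, G, nl)
  for (t in seq_len(nl)) {
    l <- loci_idx[t]; K <- enc$K[l]
    v1 <- enc$e1[rows, l]; v2 <- enc$e2[rows, l]
    ok <- !is.na(v1)
    gio <- gi[ok]; v1o <- v1[ok]; v2o <- v2[ok]
    n_i <- tabulate(gio, G)
    cnt <- tab2(gio, v1o, G, K) + tab2(gio, v2o, G, K)
    ns[, t] <- n_i
    if ("ar" %in% want) cnts[[t]] <- cnt
    hz <- v1o != v2o
    if ("ho" %in% want)
      ho_mat[, t] <- ifelse(n_i > 0L, tabulate(gio[hz], G) / n_i, NA_real_)
    if ("fst" %in% want) {
      het <- tab2(gio[hz], v1o[hz], G, K) + tab2(gio[hz], v2o[hz], G, K)
      ls[[t]] <- list(n = n_i, cnt = cnt, het = het)
    }
    if ("dc" %in% want) {
      fr <- cnt / ifelse(n_i > 0L, 2 * n_i, 1L)
      sq <- sqrt(fr)
      s <- pmin(sq %*% t(sq), 1)
      okg <- n_i > 0L
      use <- outer(okg, okg)
      contrib <- if (variant == "angular") s
                 else 2 / pi * sqrt(2 * (1 - s))
      acc <- acc + ifelse(use, contrib, 0)
      L_pair <- L_pair + use
    }
  }
  out <- list()
  if ("ho" %in% want) out$ho <- rowMeans(ho_mat, na.rm = TRUE)
  if ("ar" %in% want) {
    g_use <- g_rar %||% (2L * min(ns[ns > 0L]))
    ar_mat <- matrix(NA_real_, G, nl)
    for (t in seq_len(nl)) {
      cnt <- cnts[[t]]; N <- 2L * ns[, t]
      for (i in seq_len(G)) {
        if (N[i] < g_use) next
        keep <- cnt[i, ] > 0L
        ar_mat[i, t] <- sum(1 - exp(lchoose(N[i] - cnt[i, keep], g_use) -
                                      lchoose(N[i], g_use)))
      }
    }
    out$ar <- rowMeans(ar_mat, na.rm = TRUE)
    out$g_rar <- g_use
  }
  if ("dc" %in% want) {
    dc <- matrix(0, G, G, dimnames = list(enc$ponds, enc$ponds))
    mean_s <- acc / ifelse(L_pair > 0L, L_pair, 1L)
    dc[] <- if (variant == "angular") sqrt(pmax(0, 1 - mean_s)) else mean_s
    diag(dc) <- 0
    out$dc <- dc
  }
  if ("fst" %in% want) {
    fst <- matrix(0, G, G, dimnames = list(enc$ponds, enc$ponds))
    for (i in seq_len(G - 1L)) for (j in seq(i + 1L, G))
      fst[i, j] <- fst[j, i] <- wc_theta_from_stats(ls, c(i, j))
    out$fst <- fst
  }
  out
}

# Percentile summary of a replicate x unit matrix.
ci_summary <- function(mat, labels, stat) {
  data.frame(unit = labels, stat = stat,
             mean = colMeans(mat),
             lo = apply(mat, 2L, stats::quantile, 0.025, names = FALSE),
             hi = apply(mat, 2L, stats::quantile, 0.975, names = FALSE),
             stringsAsFactors = FALSE)
}

#' Bootstrap resampling of pooled (mixed-tissue) population samples
#'
#' Emulates the mixed-tissue treatment: all available individuals in a pond
#' (whatever their life stage) form the pond's pool, and each replicate
#' draws `n_sample` individuals per pond -- without replacement by default,
#' i.e. subsampling -- then recomputes the requested statistics. Percentile
#' 95% intervals over replicates are reported per pond (Ho, Ar) and per pond
#' pair (F_ST, D_C).
#'
#' @param x a [genotype_table] (typically all stages pooled, after pruning).
#' @param n_sample individuals drawn per pond each replicate.
#' @param n_boot replicates.
#' @param stats subset of `c("ho", "ar", "fst", "dc")`.
#' @param variant chord-distance variant, see [chord_distance()].
#' @param g_rar rarefaction size for Ar; `NULL` applies the smallest-sample
#'   rule within each replicate.
#' @param replace draw with replacement instead of subsampling.
#' @return object of class `mixed_bootstrap`: list with `per_pond` and
#'   `per_pair` data.frames (`unit, stat, mean, lo, hi`), plus the settings.
#' @export
bootstrap_mixed <- function(x, n_sample = 25L, n_boot = 1000L,
                            stats = c("ho", "ar", "fst", "dc"),
                            variant = c("angular", "takezaki-nei"),
                            g_rar = NULL, replace = FALSE) {
  variant <- match.arg(variant)
  stats <- match.arg(stats, several.ok = TRUE)
  enc <- encode_table(x)
  G <- length(enc$ponds)
  by_pond <- split(seq_along(enc$gi), enc$gi)
  small <- vapply(by_pond, length, integer(1L)) < n_sample
  if (!replace && any(small))
    stopf("pond(s) with pool smaller than n_sample = %d: %s", n_sample,
          paste(enc$ponds[small], collapse = ", "))
  pond_mats <- lapply(intersect(stats, c("ho", "ar")), function(s)
    matrix(NA_real_, n_boot, G))
  names(pond_mats) <- intersect(stats, c("ho", "ar"))
  pl <- pair_labels(enc$ponds)
  pair_mats <- lapply(intersect(stats, c("fst", "dc")), function(s)
    matrix(NA_real_, n_boot, length(pl)))
  names(pair_mats) <- intersect(stats, c("fst", "dc"))
  for (b in seq_len(n_boot)) {
    rows <- unlist(lapply(by_pond, function(r)
      r[sample.int(length(r), n_sample, replace = replace)]),
      use.names = FALSE)
    st <- rep_stats(enc, rows, seq_along(enc$loci), stats, variant, g_rar)
    for (s in names(pond_mats)) pond_mats[[s]][b, ] <- st[[s]]
    for (s in names(pair_mats)) pair_mats[[s]][b, ] <- upper_vec(st[[s]])
  }
  per_pond <- do.call(rbind, lapply(names(pond_mats), function(s)
    ci_summary(pond_mats[[s]], enc$ponds, s)))
  per_pair <- do.call(rbind, lapply(names(pair_mats), function(s)
    ci_summary(pair_mats[[s]], pl, s)))
  structure(list(per_pond = per_pond, per_pair = per_pair,
                 n_sample = n_sample, n_boot = n_boot, variant = variant,
                 replace = replace),
            class = "mixed_bootstrap")
}

#' @export
print.mixed_bootstrap <- function(x, ...) {
  cat(sprintf("<mixed_bootstrap> n_sample = %d, n_boot = %d%s\n",
              x$n_sample, x$n_boot,
              if (x$replace) " (with replacement)" else ""))
  print(x$per_pond, digits = 3)
  invisible(x)
}

# Precompute the permutation structure of the geographic matrix for fast
# repeated Mantel tests against varying genetic matrices.
mantel_prep <- function(ddist, n_perm, exact) {
  n <- nrow(ddist)
  perms <- if (exact) all_perms(n)
           else rbind(seq_len(n),
                      t(vapply(seq_len(n_perm), function(i) sample.int(n),
                               integer(n))))
  pairs <- which(upper.tri(ddist), arr.ind = TRUE)
  idx <- perms[, pairs[, 1L]] + (perms[, pairs[, 2L]] - 1L) * n
  P <- matrix(ddist[idx], nrow(perms), nrow(pairs))
  d <- upper_vec(ddist)
  list(P = P, d = d, sd_d = stats::sd(d), m = length(d), exact = exact,
       n_arr = nrow(perms))
}

mantel_from_prep <- function(gvec, prep) {
  sd_g <- stats::sd(gvec)
  if (sd_g == 0) return(c(r = NA_real_, p = NA_real_))
  gc <- gvec - mean(gvec)
  r_all <- as.vector(prep$P %*% gc) / ((prep$m - 1) * prep$sd_d * sd_g)
  r_obs <- r_all[1L]    # first row is the identity arrangement
  eps <- 1e-12
  p <- if (prep$exact) mean(r_all >= r_obs - eps)
       else (1 + sum(r_all[-1L] >= r_obs - eps)) / prep$n_arr
  c(r = r_obs, p = p)
}

#' Juvenile-proportion x locus-count mixture grid
#'
#' The headline resampling design: how do the isolation-by-distance signal
#' and diversity summaries change as the population sample shifts from
#' adults to juveniles, and as fewer loci are genotyped? For every
#' proportion `pi` on the grid and every locus count `L`, each bootstrap
#' replicate draws `k = round(pi * n_per_pond)` juveniles (half away from
#' zero) and `n_per_pond - k` adults per pond without replacement, draws `L`
#' loci without replacement, computes the pairwise genetic distance of the
#' chosen kind, a Mantel test against the fixed geographic distances, and
#' the population-averaged Ho and Ar. Cell summaries are the replicate mean
#' and percentile 95% interval. `pi = 0` is an adult-only sample, `pi = 1`
#' juveniles only.
#'
#' With up to 8 ponds the Mantel p-value is computed by exact enumeration of
#' all relabelings (the limit of the permutation test); set
#' `mantel = "permutation"` to force Monte-Carlo permutations with `n_perm`
#' draws per replicate.
#'
#' @param adults,juveniles [genotype_table]s over the same ponds and loci
#'   (typically sibling-pruned); juveniles are usually larvae and embryos
#'   pooled.
#' @param ddist labelled geographic distance matrix over the ponds.
#' @param n_per_pond individuals drawn per pond each replicate.
#' @param proportions grid of juvenile proportions.
#' @param loci_counts numbers of loci to subsample.
#' @param n_boot replicates per cell.
#' @param gdist_kind `"dc"` or `"fst"`.
#' @param variant chord-distance variant (when `gdist_kind = "dc"`).
#' @param mantel `"auto"` (exact enumeration when feasible), `"exact"`, or
#'   `"permutation"`.
#' @param n_perm permutations per replicate when `mantel = "permutation"`.
#' @return object of class `mixture_curve`: a long data.frame
#'   (`proportion, n_loci, stat, mean, lo, hi`) for stats `mantel_r`,
#'   `mantel_p`, `ho`, `ar`, with the settings as attributes.
#' @export
mixture_grid <- function(adults, juveniles, ddist, n_per_pond = 18L,
                         proportions = seq(0, 1, by = 0.05),
                         loci_counts = c(5L, 10L, 15L), n_boot = 1000L,
                         gdist_kind = c("dc", "fst"),
                         variant = c("angular", "takezaki-nei"),
                         mantel = c("auto", "exact", "permutation"),
                         n_perm = 100000L) {
  gdist_kind <- match.arg(gdist_kind)
  variant <- match.arg(variant)
  mantel <- match.arg(mantel)
  if (any(proportions < 0 | proportions > 1))
    stopf("proportions must lie in [0, 1]")
  ponds <- sort(unique(adults$meta$pond))
  if (!setequal(ponds, unique(juveniles$meta$pond)))
    stopf("adults and juveniles must cover the same ponds")
  if (!identical(adults$loci, juveniles$loci))
    stopf("adults and juveniles must share the locus panel")
  if (any(loci_counts > length(adults$loci)))
    stopf("loci_counts exceed the %d available loci", length(adults$loci))
  validate_dist_matrix(ddist)
  if (!setequal(rownames(ddist), ponds)) stopf("ddist labels must match ponds")
  ddist <- ddist[ponds, ponds]

  pooled <- bind_genotypes(adults, juveniles)
  enc <- encode_table(pooled, ponds)
  n_ad <- nrow(adults$meta)
  is_adult <- c(rep(TRUE, n_ad), rep(FALSE, nrow(juveniles$meta)))
  lev <- seq_along(ponds)
  ad_by_pond <- split(which(is_adult), factor(enc$gi[is_adult], levels = lev))
  ju_by_pond <- split(which(!is_adult), factor(enc$gi[!is_adult], levels = lev))
  short <- function(lst) enc$ponds[vapply(lst, length, integer(1L)) < n_per_pond]
  bad <- unique(c(short(ad_by_pond), short(ju_by_pond)))
  if (length(bad))
    stopf("pond(s) with fewer than n_per_pond = %d adults or juveniles: %s",
          n_per_pond, paste(bad, collapse = ", "))

  use_exact <- mantel == "exact" ||
    (mantel == "auto" && length(ponds) <= 8L)
  prep <- mantel_prep(ddist, n_perm, use_exact)

  cells <- expand.grid(proportion = proportions, n_loci = loci_counts)
  res <- vector("list", nrow(cells))
  want <- c("ho", "ar", gdist_kind)
  for (ci in seq_len(nrow(cells))) {
    prop <- cells$proportion[ci]; L <- cells$n_loci[ci]
    k <- as.integer(round_half_away(prop * n_per_pond))
    reps <- matrix(NA_real_, n_boot, 4L,
                   dimnames = list(NULL, c("mantel_r", "mantel_p", "ho", "ar")))
    for (b in seq_len(n_boot)) {
      stopifnot(k + (n_per_pond - k) == n_per_pond)
      rows <- unlist(c(
        lapply(ju_by_pond, function(r) r[sample.int(length(r), k)]),
        lapply(ad_by_pond, function(r) r[sample.int(length(r), n_per_pond - k)])),
        use.names = FALSE)
      loci_idx <- sort(sample.int(length(enc$loci), L))
      st <- rep_stats(enc, rows, loci_idx, want, variant)
      mr <- mantel_from_prep(upper_vec(st[[gdist_kind]]), prep)
      reps[b, ] <- c(mr["r"], mr["p"], mean(st$ho), mean(st$ar))
    }
    res[[ci]] <- data.frame(proportion = prop, n_loci = L,
                            stat = colnames(reps),
                            mean = colMeans(reps, na.rm = TRUE),
                            lo = apply(reps, 2L, stats::quantile, 0.025,
                                       na.rm = TRUE, names = FALSE),
                            hi = apply(reps, 2L, stats::quantile, 0.975,
                                       na.rm = TRUE, names = FALSE),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, class = c("mixture_curve", "data.frame"),
            n_boot = n_boot, gdist_kind = gdist_kind, variant = variant,
            mantel = if (use_exact) "exact" else "permutation",
            n_per_pond = n_per_pond)
}

#' @export
print.mixture_curve <- function(x, ...) {
  cat(sprintf("<mixture_curve> %d cells, n_boot = %d, gdist = %s, mantel = %s\n",
              nrow(x) / 4L, attr(x, "n_boot"), attr(x, "gdist_kind"),
              attr(x, "mantel")))
  NextMethod()
}
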