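#' Monte-Carlo exact test of Hardy-Weinberg proportions
#'
#' For each (group, locus) cell, the observed gene copies are permuted and
#' re-paired `n_mc` times; the two-sided p-value is the plus-one-corrected
#' fraction of permuted tables whose heterozygote count is at least as far
#' from the permutation mean as the observed count:
#' `p = (1 + #{|het* - mean(het*)| >= |het_obs - mean(het*)|}) / (n_mc + 1)`.
#' Cells that are monomorphic within the group, or have fewer than 2
#' genotyped individuals, return `NA`.
#'
#' @param x a [genotype_table].
#' @param grouping see [allele_frequencies()]; HWE is a within-population
#'   property, so the default groups by pond.
#' @param n_mc Monte-Carlo permutations per cell.
#' @return matrix of p-values (groups x loci).
#' @export
hwe_test <- function(x, grouping = "pond", n_mc = 999L) {
  g <- resolve_grouping(x, grouping)
  G <- nlevels(g); L <- length(x$loci)
  p <- matrix(NA_real_, G, L, dimnames = list(levels(g), x$loci))
  for (gi in seq_len(G)) {
    rows <- which(as.integer(g) == gi)
    for (l in seq_len(L)) {
      v1 <- x$a1[rows, l]; v2 <- x$a2[rows, l]
      ok <- !is.na(v1)
      if (sum(ok) < 2L) next
      copies <- c(v1[ok], v2[ok])
      if (length(unique(copies)) < 2L) next
      n <- sum(ok)
      het_obs <- sum(v1[ok] != v2[ok])
      het_mc <- vapply(seq_len(n_mc), function(b) {
        s <- sample(copies)
        sum(s[seq_len(n)] != s[n + seq_len(n)])
      }, numeric(1L))
      mu <- mean(het_mc)
      p[gi, l] <- (1 + sum(abs(het_mc - mu) >= abs(het_obs - mu) - 1e-9)) /
        (n_mc + 1)
    }
  }
  p
}

#' Screen loci: monomorphism and Hardy-Weinberg deviation
#'
#' Removes (a) loci with at most one allele observed overall and (b) loci
#' whose [hwe_test()] p-value in any population falls below the
#' Bonferroni-corrected threshold `alpha / (n_loci_tested * n_groups)`.
#' Bonferroni across loci x populations is the conservative default for a
#' screening step; the report records every removal and its reason.
#'
#' @param x a [genotype_table].
#' @param alpha family-wise significance level, in (0, 1).
#' @param n_mc Monte-Carlo permutations per HWE cell.
#' @param grouping population grouping for the HWE test (default pond).
#' @return list with `table` (filtered [genotype_table]) and `report`
#'   (data.frame `locus, reason, detail`).
#' @export
filter_loci <- function(x, alpha = 0.05, n_mc = 999L, grouping = "pond") {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stopf("alpha must be in (0, 1)")
  if (nrow(x$meta) == 0L) stopf("empty genotype table")
  L <- length(x$loci)
  n_allele <- vapply(seq_len(L), function(l) {
    length(unique(c(x$a1[, l], x$a2[, l])[!is.na(c(x$a1[, l], x$a2[, l]))]))
  }, integer(1L))
  mono <- n_allele <= 1L

  pm <- hwe_test(x[, !mono], grouping = grouping, n_mc = n_mc)
  g <- resolve_grouping(x, grouping)
  thr <- alpha / (ncol(pm) * nlevels(g))
  min_p <- suppressWarnings(apply(pm, 2L, min, na.rm = TRUE))
  min_p[!is.finite(min_p)] <- NA_real_
  hwe_fail <- !is.na(min_p) & min_p < thr

  report <- data.frame(locus = character(0), reason = character(0),
                       detail = character(0), stringsAsFactors = FALSE)
  if (any(mono))
    report <- rbind(report, data.frame(
      locus = x$loci[mono], reason = "monomorphic",
      detail = sprintf("%d allele(s) observed", n_allele[mono]),
      stringsAsFactors = FALSE))
  if (any(hwe_fail))
    report <- rbind(report, data.frame(
      locus = names(min_p)[hwe_fail], reason = "hwe",
      detail = sprintf("min p = %.4g < %.4g (Bonferroni)",
                       min_p[hwe_fail], thr),
      stringsAsFactors = FALSE))
  keep <- setdiff(x$loci, report$locus)
  if (!length(keep)) stopf("all loci removed by filtering")
  list(table = x[, keep], report = report)
}

#' Prune full siblings (and parent-offspring pairs) to one per family
#'
#' Approximates independent draws from the breeding population by retaining
#' exactly one individual per full-sib family. With
#' `scope = "within_stage"`, retention is applied within each (pond, stage)
#' group -- the treatment used when each life stage is analysed on its own.
#' With `scope = "pooled"`, retention is applied within each pond across all
#' stages, and, when a pedigree is supplied, any retained juvenile whose
#' recorded parent is itself a retained adult in the same pond is removed as
#' well -- the preparation used before pooling life stages. The retained
#' representative of a family is always the lexicographically smallest id,
#' so pruning is deterministic and idempotent.
#'
#' @param x a [genotype_table]; every individual must carry a family label
#'   (use [heuristic_sib_flags()] or simulator truth to assign them).
#' @param scope `"within_stage"` or `"pooled"`.
#' @param pedigree optional data.frame with columns `id, mother, father`
#'   (e.g. the simulator's truth pedigree) enabling parent-offspring removal
#'   in pooled scope.
#' @return list with `table` (pruned [genotype_table]) and `report`
#'   (data.frame `pond, stage, n_input, n_removed, proportion_removed`; for
#'   pooled scope one row per pond with `stage = "combined"`).
#' @export
prune_siblings <- function(x, scope = c("within_stage", "pooled"),
                           pedigree = NULL) {
  scope <- match.arg(scope)
  m <- x$meta
  if (anyNA(m$family))
    stopf(paste("family labels missing for %d individual(s); assign them",
                "with heuristic_sib_flags() or simulator truth"),
          sum(is.na(m$family)))
  key <- if (scope == "within_stage")
    paste(m$pond, ifelse(is.na(m$stage), "unknown", m$stage), sep = ":")
  else m$pond

  ord <- order(m$id)
  first <- !duplicated(paste(key, m$family, sep = "|")[ord])
  keep <- logical(nrow(m)); keep[ord] <- first

  if (scope == "pooled" && !is.null(pedigree)) {
    ped <- pedigree[match(m$id, pedigree$id), , drop = FALSE]
    retained_by_pond <- split(m$id[keep], m$pond[keep])
    is_juv <- !is.na(m$stage) & m$stage %in% c("embryo", "larva")
    po <- keep & is_juv & !is.na(ped$mother) &
      mapply(function(mo, fa, pond) {
        ret <- retained_by_pond[[pond]]
        !is.null(ret) && (mo %in% ret || fa %in% ret)
      }, ped$mother, ped$father, m$pond)
    keep[po] <- FALSE
  }

  grp <- if (scope == "within_stage")
    data.frame(pond = m$pond, stage = ifelse(is.na(m$stage), "unknown", m$stage))
  else data.frame(pond = m$pond, stage = "combined")
  agg <- stats::aggregate(cbind(n_input = rep(1L, nrow(m)),
                                n_removed = as.integer(!keep)),
                          by = grp, FUN = sum)
  agg$proportion_removed <- agg$n_removed / agg$n_input
  agg <- agg[order(agg$pond, agg$stage), ]
  rownames(agg) <- NULL
  list(table = x[keep, ], report = agg)
}

#' Pairwise Queller-Goodnight relatedness
#'
#' Symmetrised multilocus Queller & Goodnight (1989) estimator. Reference
#' allele frequencies default to the supplied sample itself; when the sample
#' is family-structured (a pond's larvae, say) a larger reference such as
#' the pond's adults should be passed via `ref`, otherwise the relatives'
#' own alleles inflate the reference frequencies and depress the estimator.
#' Expected value ~0.5 for full sibs and parent-offspring, ~0 for unrelated
#' individuals under the reference frequencies.
#'
#' @param x a [genotype_table]; relatedness is computed among all its
#'   individuals.
#' @param ref optional [genotype_table] supplying reference allele
#'   frequencies (same locus panel).
#' @return symmetric matrix of pairwise relatedness (diagonal `NA`).
#' @export
qg_relatedness <- function(x, ref = NULL) {
  n <- nrow(x$meta)
  if (n < 2L) stopf("need at least 2 individuals")
  L <- length(x$loci)
  if (!is.null(ref) && !identical(ref$loci, x$loci))
    stopf("ref must share the locus panel")
  fx <- ref %||% x
  af <- allele_frequencies(fx, grouping = rep("all", nrow(fx$meta)))
  # per-individual per-locus: alleles and their reference frequencies
  pa <- pb <- matrix(NA_real_, n, L)
  for (l in seq_len(L)) {
    f <- af$freq[[l]][1L, ]
    al <- af$alleles[[l]]
    pa[, l] <- f[match(x$a1[, l], al)]
    pb[, l] <- f[match(x$a2[, l], al)]
  }
  if (anyNA(pa[!is.na(x$a1)]))
    stopf("allele(s) in x absent from the reference sample")
  hom <- x$a1 == x$a2
  out <- matrix(NA_real_, n, n, dimnames = list(x$meta$id, x$meta$id))
  for (i in seq_len(n - 1L)) {
    ai <- x$a1[i, ]; bi <- x$a2[i, ]
    for (j in seq(i + 1L, n)) {
      aj <- x$a1[j, ]; bj <- x$a2[j, ]
      ok <- !is.na(ai) & !is.na(aj)
      if (!any(ok)) next
      sh_i <- 0.5 * ((ai == aj) + (ai == bj) + (bi == aj) + (bi == bj))
      num_i <- sh_i - pa[i, ] - pb[i, ]
      den_i <- 1 + hom[i, ] - pa[i, ] - pb[i, ]
      num_j <- sh_i - pa[j, ] - pb[j, ]
      den_j <- 1 + hom[j, ] - pa[j, ] - pb[j, ]
      out[i, j] <- out[j, i] <-
        (sum(num_i[ok]) + sum(num_j[ok])) / (sum(den_i[ok]) + sum(den_j[ok]))
    }
  }
  out
}

#' Heuristic family labels from relatedness clustering
#'
#' A pragmatic stand-in for likelihood-based sibship reconstruction: within
#' each (pond, stage) group, pairs whose Queller-Goodnight relatedness
#' exceeds `threshold` are linked, and single-linkage connected components
#' become putative full-sib families. Downstream pruning consumes these
#' labels exactly like truth labels. The default threshold 0.35 sits between
#' the expectations for unrelated pairs (~0) and full sibs (~0.5).
#'
#' @param x a [genotype_table].
#' @param threshold relatedness cutoff for linking a pair.
#' @return the [genotype_table] with `family` labels assigned.
#' @export
heuristic_sib_flags <- function(x, threshold = 0.35) {
  if (length(x$loci) < 5L)
    warnf("fewer than 5 loci: relatedness-based sib flags will be unreliable")
  m <- x$meta
  key <- paste(m$pond, ifelse(is.na(m$stage), "unknown", m$stage), sep = ":")
  fam <- character(nrow(m))
  for (k in unique(key)) {
    rows <- which(key == k)
    if (length(rows) == 1L) { fam[rows] <- paste0(k, "_H1"); next }
    # reference frequencies from the whole pond (all stages): less distorted
    # by the family structure of the group being screened
    pond_rows <- which(m$pond == m$pond[rows[1L]])
    r <- qg_relatedness(x[rows, ], ref = x[pond_rows, ])
    # single-linkage components over pairs above threshold
    comp <- seq_along(rows)
    link <- which(r > threshold & upper.tri(r), arr.ind = TRUE)
    if (nrow(link)) for (e in seq_len(nrow(link))) {
      ci <- comp[link[e, 1L]]; cj <- comp[link[e, 2L]]
      if (ci != cj) comp[comp == cj] <- ci
    }
    fam[rows] <- paste0(k, "_H", match(comp, unique(comp)))
  }
  x$meta$family <- fam
  validate_genotype_table(x)
  x
}
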