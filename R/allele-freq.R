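#' Per-group allele frequencies
#'
#' Tabulates allele counts per (group, locus) over non-missing gene copies
#' and normalises to frequencies. The allele set at each locus is the union
#' over all groups, so frequency vectors are directly comparable between
#' groups. `n_gc` records the number of gene copies behind each frequency
#' vector (2 x non-missing individuals); a group with no data at a locus gets
#' an all-zero frequency vector and `n_gc = 0`, which downstream statistics
#' must skip.
#'
#' @param x a [genotype_table].
#' @param grouping `"pond"` (default), `"stage"`, `"pond_stage"`, or a vector
#'   of group labels, one per individual.
#' @return An object of class `allele_freq_table`: a list with `groups`,
#'   `loci`, and per-locus `alleles` (sorted union codes), `counts`
#'   (group x allele integer matrices), `freq` (matrices of frequencies),
#'   `n_ind` and `n_gc` (group x locus matrices).
#' @examples
#' meta <- data.frame(id = c("i1", "i2"), pond = "P1")
#' a1 <- matrix(c(1L, 1L), 2, dimnames = list(NULL, "locA"))
#' a2 <- matrix(c(1L, 2L), 2, dimnames = list(NULL, "locA"))
#' af <- allele_frequencies(genotype_table(meta, a1, a2))
#' af$freq$locA   # 0.75 / 0.25
#' @export
allele_frequencies <- function(x, grouping = "pond") {
  g <- resolve_grouping(x, grouping)
  if (any(tabulate(g, nlevels(g)) == 0L))
    stopf("empty group(s) in grouping")
  G <- nlevels(g); L <- length(x$loci)
  gi <- as.integer(g)

  alleles <- counts <- freq <- stats::setNames(vector("list", L), x$loci)
  n_gc <- matrix(0L, G, L, dimnames = list(levels(g), x$loci))
  for (l in seq_len(L)) {
    v1 <- x$a1[, l]; v2 <- x$a2[, l]
    ok <- !is.na(v1)
    al <- sort(unique(c(v1[ok], v2[ok])))
    A <- max(length(al), 1L)
    ai1 <- match(v1[ok], al); ai2 <- match(v2[ok], al)
    cnt <- tab2(gi[ok], ai1, G, A) + tab2(gi[ok], ai2, G, A)
    if (!length(al)) cnt <- matrix(0L, G, 1L)
    tot <- rowSums(cnt)
    fr <- cnt / ifelse(tot > 0L, tot, 1L)
    dimnames(cnt) <- dimnames(fr) <-
      list(levels(g), if (length(al)) al else "none")
    alleles[[l]] <- al
    counts[[l]] <- cnt
    freq[[l]] <- fr
    n_gc[, l] <- tot
  }
  structure(list(groups = levels(g), loci = x$loci, alleles = alleles,
                 counts = counts, freq = freq, n_gc = n_gc,
                 n_ind = n_gc / 2),
            class = "allele_freq_table")
}

#' @export
print.allele_freq_table <- function(x, ...) {
  cat(sprintf("<allele_freq_table> %d groups x %d loci\n",
              length(x$groups), length(x$loci)))
  cat("  groups:", paste(x$groups, collapse = ", "), "\n")
  invisible(x)
}
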