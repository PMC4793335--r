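#' @name genotype_table
#' @title Diploid multilocus genotype table
#'
#' @description
#' The universal input of the pipeline: a set of diploid individuals typed at
#' a shared, ordered panel of codominant loci (microsatellites), together with
#' per-individual metadata (pond of origin, life stage, full-sib family
#' label). Allele calls are positive integer codes (repeat sizes or arbitrary
#' labels); a missing genotype is missing as a whole, i.e. both alleles of a
#' locus are `NA` -- half-missing calls are rejected.
#'
#' @details
#' Invariants enforced by the constructor:
#' * `id` unique, `pond` non-empty for every individual;
#' * `stage`, when present, is one of `"adult"`, `"embryo"`, `"larva"`;
#' * a family label never spans ponds (full-sib families are hatched in one
#'   pond);
#' * `is.na(a1)` and `is.na(a2)` agree elementwise;
#' * allele codes are positive integers.
#'
#' @param meta data.frame with columns `id`, `pond` and optionally `stage`
#'   and `family` (use `NA` where unknown).
#' @param a1,a2 integer matrices (individuals x loci) holding the first and
#'   second allele of each genotype; column names are the locus names.
#' @return An object of class `genotype_table` with fields `meta`, `a1`,
#'   `a2` and `loci`.
#' @examples
#' meta <- data.frame(id = c("i1", "i2"), pond = "P1",
#'                    stage = "adult", family = NA)
#' a1 <- matrix(c(1L, 1L), 2, 1, dimnames = list(NULL, "locA"))
#' a2 <- matrix(c(1L, 2L), 2, 1, dimnames = list(NULL, "locA"))
#' gt <- genotype_table(meta, a1, a2)
#' @export
genotype_table <- function(meta, a1, a2) {
  stopifnot(is.data.frame(meta))
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  if (!identical(dim(a1), dim(a2)))
    stopf("allele matrices must have identical dimensions")
  if (is.null(colnames(a1)))
    stopf("allele matrices must carry locus names as column names")
  if (anyDuplicated(colnames(a1)))
    stopf("duplicate locus names")
  if (!identical(colnames(a1), colnames(a2)))
    stopf("a1/a2 locus names disagree")
  if (nrow(meta) != nrow(a1))
    stopf("meta has %d rows but allele matrices have %d", nrow(meta), nrow(a1))
  storage.mode(a1) <- "integer"
  storage.mode(a2) <- "integer"

  if (!all(c("id", "pond") %in% names(meta)))
    stopf("meta must contain columns 'id' and 'pond'")
  meta$id <- as.character(meta$id)
  meta$pond <- as.character(meta$pond)
  if (!"stage" %in% names(meta)) meta$stage <- NA_character_
  if (!"family" %in% names(meta)) meta$family <- NA_character_
  meta$stage <- as.character(meta$stage)
  meta$family <- as.character(meta$family)
  meta <- meta[c("id", "pond", "stage", "family")]
  rownames(meta) <- NULL

  x <- structure(list(meta = meta, a1 = a1, a2 = a2, loci = colnames(a1)),
                 class = "genotype_table")
  validate_genotype_table(x)
  x
}

STAGES <- c("adult", "embryo", "larva")

#' Validate a genotype table
#'
#' Checks all `genotype_table` invariants and errors with an informative
#' message on the first violation. Called by the constructor; exposed so that
#' pipelines can re-assert invariants after external manipulation.
#'
#' @param x a `genotype_table`.
#' @return `x`, invisibly.
#' @export
validate_genotype_table <- function(x) {
  m <- x$meta
  if (anyDuplicated(m$id))
    stopf("duplicate individual id(s): %s",
          paste(unique(m$id[duplicated(m$id)]), collapse = ", "))
  if (anyNA(m$pond) || any(!nzchar(m$pond)))
    stopf("pond labels must be non-empty")
  bad_stage <- !is.na(m$stage) & !m$stage %in% STAGES
  if (any(bad_stage))
    stopf("unknown stage token(s): %s",
          paste(unique(m$stage[bad_stage]), collapse = ", "))
  if (any(is.na(x$a1) != is.na(x$a2)))
    stopf("half-missing genotype call(s): a genotype is missing as a whole")
  if (any(x$a1 <= 0L, na.rm = TRUE) || any(x$a2 <= 0L, na.rm = TRUE))
    stopf("allele codes must be positive integers")
  fam <- m$family[!is.na(m$family)]
  if (length(fam)) {
    ponds_per_fam <- tapply(m$pond[!is.na(m$family)], fam,
                            function(p) length(unique(p)))
    if (any(ponds_per_fam > 1L))
      stopf("family label(s) span multiple ponds: %s",
            paste(names(ponds_per_fam)[ponds_per_fam > 1L], collapse = ", "))
  }
  invisible(x)
}

# Trusted internal constructor (no validation); used on hot paths where the
# inputs are slices of an already-validated table.
new_genotype_table <- function(meta, a1, a2) {
  rownames(meta) <- NULL
  structure(list(meta = meta, a1 = a1, a2 = a2, loci = colnames(a1)),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  n <- nrow(x$meta)
  miss <- mean(is.na(x$a1))
  cat(sprintf("<genotype_table> %d individuals x %d loci (%.2f%% missing)\n",
              n, length(x$loci), 100 * miss))
  st <- table(factor(x$meta$stage, levels = STAGES), useNA = "ifany")
  cat("  ponds:", paste(sort(unique(x$meta$pond)), collapse = ", "), "\n")
  cat("  stages:", paste(sprintf("%s=%d", names(st), st), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a genotype table
#'
#' @param x a `genotype_table`.
#' @param i individual selector (integer, logical, or individual ids).
#' @param j locus selector (integer, logical, or locus names).
#' @param ... unused.
#' @return a `genotype_table`.
#' @export
`[.genotype_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$meta))
  if (is.character(i)) i <- match(i, x$meta$id)
  if (missing(j)) j <- seq_along(x$loci)
  if (anyNA(i)) stopf("unknown individual id(s) in subset")
  a1 <- x$a1[i, j, drop = FALSE]
  a2 <- x$a2[i, j, drop = FALSE]
  new_genotype_table(x$meta[i, , drop = FALSE], a1, a2)
}

#' Number of individuals in a genotype table
#' @param x a `genotype_table`.
#' @return integer count.
#' @export
n_ind <- function(x) nrow(x$meta)

#' Concatenate genotype tables sharing a locus panel
#'
#' @param ... `genotype_table` objects with identical locus panels.
#' @return a single `genotype_table`.
#' @export
bind_genotypes <- function(...) {
  parts <- list(...)
  stopifnot(length(parts) >= 1L)
  loci <- parts[[1L]]$loci
  for (p in parts)
    if (!identical(p$loci, loci)) stopf("locus panels differ between tables")
  genotype_table(do.call(rbind, lapply(parts, `[[`, "meta")),
                 do.call(rbind, lapply(parts, `[[`, "a1")),
                 do.call(rbind, lapply(parts, `[[`, "a2")))
}

# Resolve a grouping argument into a factor over individuals.
resolve_grouping <- function(x, grouping) {
  n <- nrow(x$meta)
  if (is.character(grouping) && length(grouping) == 1L) {
    g <- switch(grouping,
      pond = x$meta$pond,
      stage = x$meta$stage,
      pond_stage = paste(x$meta$pond, x$meta$stage, sep = ":"),
      stopf("unknown grouping '%s' (use 'pond', 'stage', 'pond_stage', or a vector)",
            grouping))
  } else {
    if (length(grouping) != n)
      stopf("grouping vector has length %d, expected %d", length(grouping), n)
    g <- grouping
  }
  if (anyNA(g)) stopf("grouping contains NA")
  factor(g)
}
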