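#' Read genotypes from the CSV dialect
#'
#' The canonical rich format of the package: one row per individual with
#' header `id,pond,stage,family,<locus>.a1,<locus>.a2,...`. Empty cells in
#' allele columns encode a missing genotype (both alleles of a locus must be
#' empty together); empty `stage`/`family` cells become `NA`. Stage tokens
#' must be `adult`, `embryo` or `larva`.
#'
#' @param path path to a CSV file.
#' @return a [genotype_table].
#' @seealso [write_csv_genotypes()]
#' @export
read_csv_genotypes <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  need <- c("id", "pond")
  if (!all(need %in% names(df)))
    stopf("CSV must contain columns 'id' and 'pond'")
  acols <- grep("\\.a[12]$", names(df), value = TRUE)
  loci1 <- sub("\\.a1$", "", grep("\\.a1$", acols, value = TRUE))
  loci2 <- sub("\\.a2$", "", grep("\\.a2$", acols, value = TRUE))
  if (!setequal(loci1, loci2))
    stopf("unpaired allele columns: every locus needs both .a1 and .a2")
  loci <- loci1  # order of first appearance
  if (!length(loci)) stopf("no locus columns (<locus>.a1/<locus>.a2) found")

  to_int <- function(v) {
    v[!nzchar(trimws(v))] <- NA_character_
    suppressWarnings(out <- as.integer(v))
    if (any(!is.na(v) & is.na(out)))
      stopf("non-integer allele value(s): %s",
            paste(utils::head(unique(v[!is.na(v) & is.na(out)]), 3L),
                  collapse = ", "))
    out
  }
  a1 <- sapply(loci, function(l) to_int(df[[paste0(l, ".a1")]]))
  a2 <- sapply(loci, function(l) to_int(df[[paste0(l, ".a2")]]))
  if (nrow(df) == 1L) { a1 <- rbind(a1); a2 <- rbind(a2) }
  colnames(a1) <- colnames(a2) <- loci

  blank_na <- function(v) { v[!nzchar(trimws(v))] <- NA_character_; v }
  meta <- data.frame(
    id = df$id, pond = df$pond,
    stage = if ("stage" %in% names(df)) blank_na(df$stage) else NA_character_,
    family = if ("family" %in% names(df)) blank_na(df$family) else NA_character_,
    stringsAsFactors = FALSE)
  genotype_table(meta, a1, a2)
}

#' Write a genotype table in the CSV dialect
#'
#' Exact inverse of [read_csv_genotypes()]: `read(write(x))` reproduces `x`
#' including stage/family metadata and missing genotypes.
#'
#' @param x a [genotype_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_csv_genotypes <- function(x, path) {
  out <- x$meta
  out$stage[is.na(out$stage)] <- ""
  out$family[is.na(out$family)] <- ""
  for (l in x$loci) {
    out[[paste0(l, ".a1")]] <- ifelse(is.na(x$a1[, l]), "", x$a1[, l])
    out[[paste0(l, ".a2")]] <- ifelse(is.na(x$a2[, l]), "", x$a2[, l])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write labelled distance matrices
#'
#' `write_dist_matrix()` stores a labelled square matrix as CSV with the
#' labels in the first row and column; `read_dist_matrix()` reads it back and
#' asserts symmetry and a zero diagonal. `write_dist_phylip()` writes the
#' lower-triangle PHYLIP-style layout used by classic population-genetics
#' tools.
#'
#' @param m labelled symmetric matrix with zero diagonal.
#' @param path file path.
#' @return the matrix (read) or `path` invisibly (write).
#' @export
write_dist_matrix <- function(m, path) {
  validate_dist_matrix(m)
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_dist_matrix
#' @export
read_dist_matrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  m <- as.matrix(df)
  colnames(m) <- colnames(df)
  validate_dist_matrix(m)
  m
}

#' @rdname write_dist_matrix
#' @export
write_dist_phylip <- function(m, path) {
  validate_dist_matrix(m)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%5d", nrow(m)), con)
  for (i in seq_len(nrow(m))) {
    row <- if (i == 1L) "" else paste(sprintf("%.6f", m[i, seq_len(i - 1L)]),
                                      collapse = " ")
    writeLines(trimws(paste(rownames(m)[i], row)), con)
  }
  invisible(path)
}

#' Validate a labelled distance matrix
#'
#' Asserts the `DistanceMatrix` invariants: square, unique labels, symmetric
#' within `1e-12` (relative to the largest entry), zero diagonal.
#'
#' @param m a matrix.
#' @return `m`, invisibly.
#' @export
validate_dist_matrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stopf("not a square matrix")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    stopf("distance matrix needs unique row/column labels")
  if (!identical(rownames(m), colnames(m)))
    stopf("row and column labels disagree")
  tol <- 1e-12 * max(1, abs(m))
  if (max(abs(m - t(m))) > tol) stopf("matrix is not symmetric")
  if (max(abs(diag(m))) > tol) stopf("diagonal is not zero")
  invisible(m)
}
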