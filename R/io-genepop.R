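#' Read a GENEPOP genotype file
#'
#' Parses GENEPOP 4.x text files: a title line, locus names (one per line or
#' comma-separated on one line), then `Pop` blocks of individuals. Diploid
#' genotypes are concatenated 2- or 3-digit allele codes (`0101`, `001002`);
#' the digit width is auto-detected per locus and must be consistent within a
#' locus. `0000`/`000000` encodes a missing genotype; a genotype with exactly
#' one zero allele (a half-missing call) is a parse error.
#'
#' Following GENEPOP convention, each population (pond) is labelled by the
#' identifier of the *last* individual in its `Pop` block. Stage and family
#' metadata cannot be expressed in GENEPOP; they come back as `NA` and are
#' supplied via the richer CSV dialect (see [read_csv_genotypes()]).
#'
#' @param path path to a GENEPOP file.
#' @return a [genotype_table].
#' @seealso [write_genepop()]
#' @export
read_genepop <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) stopf("not a GENEPOP file (too short): %s", path)

  is_pop <- grepl("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  first_pop <- which(is_pop)[1L]
  if (is.na(first_pop)) stopf("no 'Pop' separator found in %s", path)

  locus_lines <- trimws(lines[2:(first_pop - 1L)])
  loci <- unlist(strsplit(locus_lines[nzchar(locus_lines)], ","))
  loci <- trimws(loci)
  loci <- loci[nzchar(loci)]
  if (!length(loci)) stopf("no locus names found in %s", path)
  L <- length(loci)

  ids <- character(0); pond_of <- integer(0)
  geno_strings <- list()
  block <- 0L
  block_last_id <- character(0)
  for (ln in seq(first_pop, length(lines))) {
    line <- lines[ln]
    if (is_pop[ln]) { block <- block + 1L; block_last_id[block] <- NA_character_; next }
    if (!nzchar(trimws(line))) next
    comma <- regexpr(",", line, fixed = TRUE)
    if (comma < 0L)
      stopf("line %d: expected 'name , genotypes' (no comma found)", ln)
    id <- trimws(substr(line, 1L, comma - 1L))
    toks <- strsplit(trimws(substr(line, comma + 1L, nchar(line))),
                     "\\s+")[[1L]]
    toks <- toks[nzchar(toks)]
    if (length(toks) != L)
      stopf("line %d: individual '%s' has %d genotypes, expected %d loci",
            ln, id, length(toks), L)
    if (!all(grepl("^[0-9]+$", toks)))
      stopf("line %d: non-numeric genotype token", ln)
    ids <- c(ids, id)
    pond_of <- c(pond_of, block)
    geno_strings[[length(ids)]] <- toks
    block_last_id[block] <- id
  }
  if (!length(ids)) stopf("no individuals found in %s", path)
  if (anyDuplicated(ids))
    stopf("duplicate individual id(s) in %s: %s", path,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))

  gm <- do.call(rbind, geno_strings)
  a1 <- matrix(NA_integer_, nrow(gm), L, dimnames = list(NULL, loci))
  a2 <- a1
  for (l in seq_len(L)) {
    w <- unique(nchar(gm[, l]))
    if (length(w) != 1L)
      stopf("locus '%s': mixed genotype string widths (%s)", loci[l],
            paste(sort(w), collapse = ", "))
    if (!w %in% c(4L, 6L))
      stopf("locus '%s': genotype strings must be 4 or 6 digits, got %d",
            loci[l], w)
    d <- w / 2L
    x1 <- as.integer(substr(gm[, l], 1L, d))
    x2 <- as.integer(substr(gm[, l], d + 1L, w))
    half <- xor(x1 == 0L, x2 == 0L)
    if (any(half))
      stopf("locus '%s': half-missing genotype (one zero allele) for %s",
            loci[l], paste(ids[half], collapse = ", "))
    miss <- x1 == 0L
    x1[miss] <- NA_integer_; x2[miss] <- NA_integer_
    a1[, l] <- x1; a2[, l] <- x2
  }

  ponds <- block_last_id[pond_of]
  genotype_table(data.frame(id = ids, pond = ponds, stage = NA_character_,
                            family = NA_character_, stringsAsFactors = FALSE),
                 a1, a2)
}

#' Write a genotype table in GENEPOP format
#'
#' Individuals are grouped into `Pop` blocks by pond, preserving row order
#' within ponds. Allele codes wider than 99 switch the whole file to 3-digit
#' encoding. GENEPOP cannot carry stage or family metadata, so the export is
#' lossy by design; note also that re-reading assigns pond labels from the
#' last individual of each block (GENEPOP convention), so
#' `read -> write -> read` round-trips exactly but `write -> read` of an
#' arbitrary table renames ponds.
#'
#' @param x a [genotype_table].
#' @param path output path.
#' @param title title line for the file.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(x, path, title = "stagemix export") {
  digits <- if (max(c(x$a1, x$a2, 1L), na.rm = TRUE) > 99L) 3L else 2L
  fmt <- sprintf("%%0%dd%%0%dd", digits, digits)
  miss <- paste(rep("0", 2L * digits), collapse = "")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(x$loci, con)
  for (pond in unique(x$meta$pond)) {
    writeLines("Pop", con)
    rows <- which(x$meta$pond == pond)
    for (i in rows) {
      g <- sprintf(fmt, x$a1[i, ], x$a2[i, ])
      g[is.na(x$a1[i, ])] <- miss
      writeLines(paste0(x$meta$id[i], " , ", paste(g, collapse = " ")), con)
    }
  }
  invisible(path)
}
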