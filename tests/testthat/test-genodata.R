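test_that("GENEPOP decoding handles 2-digit codes and the missing sentinel", {
  f <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("toy file", "locA", "locB", "Pop",
               "ind1 , 0101 0000",
               "pondX , 0102 0203"), f)
  gt <- read_genepop(f)
  expect_equal(gt$loci, c("locA", "locB"))
  expect_equal(gt$meta$pond, c("pondX", "pondX"))  # last individual labels the block
  expect_equal(unname(gt$a1[, "locA"]), c(1L, 1L))
  expect_equal(unname(gt$a2[, "locA"]), c(1L, 2L))
  expect_true(is.na(gt$a1[1, "locB"]) && is.na(gt$a2[1, "locB"]))
})

test_that("GENEPOP parse errors name the offending line or locus", {
  f <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("t", "locA", "locB", "Pop", "i1 , 0101"), f)
  expect_error(read_genepop(f), "line 5")
  writeLines(c("t", "locA", "Pop", "i1 , 0101", "i2 , 010101"), f)
  expect_error(read_genepop(f), "mixed genotype string widths")
  writeLines(c("t", "locA", "Pop", "i1 , 0100"), f)
  expect_error(read_genepop(f), "half-missing")
  writeLines(c("t", "locA", "Pop", "i1 , 0101", "i1 , 0101"), f)
  expect_error(read_genepop(f), "duplicate")
})

test_that("read -> write -> read round-trips GENEPOP, including 3-digit codes", {
  withr::local_seed(11)
  for (digits in c(2, 3)) {
    x <- random_table(n_per_pond = 6, ponds = c("A", "B", "C"), n_loci = 4,
                      missing_rate = 0.1)
    if (digits == 3) { x$a1 <- x$a1 + 100L; x$a2 <- x$a2 + 100L }
    f1 <- withr::local_tempfile(fileext = ".gen")
    f2 <- withr::local_tempfile(fileext = ".gen")
    write_genepop(x, f1)
    r1 <- read_genepop(f1)
    write_genepop(r1, f2)
    r2 <- read_genepop(f2)
    expect_identical(r1$meta, r2$meta)
    expect_identical(r1$a1, r2$a1)
    expect_identical(r1$a2, r2$a2)
  }
})

test_that("CSV dialect round-trips with stages, families, and missing cells", {
  withr::local_seed(12)
  x <- random_table(n_per_pond = 5, ponds = c("P1", "P2"), n_loci = 3,
                    missing_rate = 0.15)
  x$meta$stage <- rep(c("adult", "embryo", "larva", "adult", "embryo"), 2)
  x$meta$family[3] <- NA
  f <- withr::local_tempfile(fileext = ".csv")
  write_csv_genotypes(x, f)
  y <- read_csv_genotypes(f)
  expect_identical(x$meta, y$meta)
  expect_identical(x$a1, y$a1)
  expect_identical(x$a2, y$a2)
})

test_that("CSV reader rejects unknown stages and cross-pond families", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,pond,stage,family,L1.a1,L1.a2",
               "i1,P1,tadpole,,1,2"), f)
  expect_error(read_csv_genotypes(f), "stage")
  writeLines(c("id,pond,stage,family,L1.a1,L1.a2",
               "i1,P1,adult,F1,1,2",
               "i2,P2,adult,F1,1,1"), f)
  expect_error(read_csv_genotypes(f), "span")
  writeLines(c("id,pond,stage,family,L1.a1,L1.a2",
               "i1,P1,adult,,1,"), f)
  expect_error(read_csv_genotypes(f), "half-missing")
})

test_that("allele_frequencies counts gene copies and shares the allele union", {
  x <- table_from_genotypes(list(P1 = list(i1 = list(c(1, 1)),
                                           i2 = list(c(1, 2)))))
  af <- allele_frequencies(x)
  expect_equal(unname(af$freq$L01[1, ]), c(0.75, 0.25))
  expect_equal(unname(af$n_gc[1, 1]), 4)
  # one individual missing -> n_gc drops to 2
  x$a1[2, 1] <- NA_integer_; x$a2[2, 1] <- NA_integer_
  af <- allele_frequencies(x)
  expect_equal(unname(af$n_gc[1, 1]), 2)
})

test_that("frequencies sum to one and conserve gene-copy counts", {
  withr::local_seed(13)
  for (rep in 1:5) {
    x <- random_table(n_per_pond = 7, ponds = c("P1", "P2", "P3"),
                      n_loci = 4, missing_rate = 0.2)
    af <- allele_frequencies(x)
    for (l in seq_along(af$loci)) {
      sums <- rowSums(af$freq[[l]])
      has <- af$n_gc[, l] > 0
      expect_true(all(abs(sums[has] - 1) < 1e-9))
      expect_equal(unname(rowSums(af$counts[[l]])), unname(af$n_gc[, l]))
    }
  }
})

test_that("euclidean distances: 3-4-5, translation invariance, brute force", {
  p <- data.frame(pond = c("a", "b"), x = c(0, 3), y = c(0, 4))
  expect_equal(euclidean_distances(p)["a", "b"], 5)
  withr::local_seed(14)
  q <- data.frame(pond = sprintf("p%d", 1:6), x = runif(6, 0, 100),
                  y = runif(6, 0, 100))
  m <- euclidean_distances(q)
  q2 <- q; q2$x <- q2$x + 1000; q2$y <- q2$y - 50
  expect_equal(euclidean_distances(q2), m)
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(m[i, j], sqrt((q$x[i] - q$x[j])^2 + (q$y[i] - q$y[j])^2))
})

test_that("distance-matrix CSV and PHYLIP writers round-trip / format", {
  withr::local_seed(15)
  m <- random_dist(4)
  f <- withr::local_tempfile(fileext = ".csv")
  write_dist_matrix(m, f)
  expect_equal(read_dist_matrix(f), m, tolerance = 1e-12)
  fp <- withr::local_tempfile(fileext = ".phy")
  write_dist_phylip(m, fp)
  lines <- readLines(fp)
  expect_equal(as.integer(trimws(lines[1])), 4L)
  expect_length(strsplit(trimws(lines[4]), "\\s+")[[1]], 3L)  # label + 2 values
})

test_that("genotype_table invariants reject malformed input", {
  meta <- data.frame(id = c("a", "b"), pond = "P1")
  a1 <- matrix(c(1L, 2L), 2, dimnames = list(NULL, "L1"))
  a2 <- matrix(c(1L, NA), 2, dimnames = list(NULL, "L1"))
  expect_error(genotype_table(meta, a1, a2), "half-missing")
  a2[2] <- -1L
  expect_error(genotype_table(meta, a1, a2), "positive")
  meta2 <- data.frame(id = c("a", "a"), pond = "P1")
  expect_error(genotype_table(meta2, a1, abs(a2)), "duplicate")
})
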