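test_that("observed heterozygosity: hand counts, missing handling, errors", {
  x <- table_from_genotypes(list(P1 = list(
    i1 = list(c(1, 2)), i2 = list(c(1, 1)), i3 = list(c(2, 2)),
    i4 = list(c(1, 2)))))
  expect_equal(unname(observed_heterozygosity(x)$mean), 0.5)

  x2 <- table_from_genotypes(list(P1 = list(i1 = list(c(1, 1), c(1, 1)))))
  expect_equal(unname(observed_heterozygosity(x2)$mean), 0)

  # missing genotypes leave the denominator
  x3 <- table_from_genotypes(list(P1 = list(i1 = list(c(1, 2)),
                                            i2 = list(c(1, 1)))))
  x3$a1[2, 1] <- NA_integer_; x3$a2[2, 1] <- NA_integer_
  expect_equal(unname(observed_heterozygosity(x3)$mean), 1)

  x3$a1[1, 1] <- NA_integer_; x3$a2[1, 1] <- NA_integer_
  expect_error(observed_heterozygosity(x3), "no genotype data")
})

test_that("rarefied allelic richness matches hypergeometric arithmetic", {
  # counts {A:9, B:1}, g = 2: Ar = 1 + (1 - C(9,2)/C(10,2)) = 1.2
  pops <- list(P1 = lapply(1:5, function(i) list(c(1, 1))),
               P2 = lapply(1:5, function(i) list(c(1, 1))))
  x <- table_from_genotypes(pops)
  x$a2[1, 1] <- 2L  # pop P1 now has counts {1:9, 2:1}
  ar <- rarefied_allelic_richness(x, g = 2)
  expect_equal(unname(ar$locus["P1", 1]), 1.2)
  # monomorphic group stays at 1 for any g
  expect_equal(unname(ar$locus["P2", 1]), 1)
  # g = N returns the observed allele count
  ar_full <- rarefied_allelic_richness(x, g = 10)
  expect_equal(unname(ar_full$locus["P1", 1]), 2)
  expect_error(rarefied_allelic_richness(x, g = 12), "exceeds gene copies")
  expect_error(rarefied_allelic_richness(x, g = 1), ">= 2")
})

test_that("closed-form rarefaction equals the Monte-Carlo subset oracle", {
  withr::local_seed(41)
  for (rep in 1:4) {
    k <- sample(2:6, 1)
    counts <- as.vector(rmultinom(1, size = sample(20:60, 1),
                                  prob = rgamma(k, 1)))
    counts <- counts[counts > 0]
    if (length(counts) < 2) next
    N <- sum(counts)
    g <- sample(2:(N - 1), 1)
    exact <- sum(1 - exp(lchoose(N - counts, g) - lchoose(N, g)))
    mc <- ar_mc_oracle(counts, g, n_mc = 20000)
    expect_lt(abs(exact - mc["mean"]), 3 * mc["se"] + 10 / 20000)
  }
})

test_that("W-C theta: fixed difference gives 1, split pool hovers at zero", {
  fixed <- table_from_genotypes(list(
    A = lapply(1:6, function(i) list(c(1, 1), c(3, 3))),
    B = lapply(1:6, function(i) list(c(2, 2), c(4, 4)))))
  expect_equal(wc_fst(fixed), 1)

  withr::local_seed(42)
  thetas <- replicate(30, {
    x <- random_table(n_per_pond = 24, ponds = "P1", n_loci = 5)
    g <- rep(c("g1", "g2"), 12)   # split one sample into two labels
    wc_fst(x, grouping = g)
  })
  expect_lt(abs(mean(thetas)), 0.01)   # E[theta] = 0 under no differentiation
})

test_that("W-C theta equals the independent variance-components oracle", {
  withr::local_seed(43)
  for (rep in 1:12) {
    x <- random_table(n_per_pond = sample(4:8, 1),
                      ponds = c("P1", "P2", "P3")[1:sample(2:3, 1)],
                      n_loci = sample(2:4, 1), max_alleles = 5,
                      missing_rate = 0.1)
    expect_equal(wc_fst(x), wc_fst_oracle(x), tolerance = 1e-12)
  }
  # pairwise entries match oracle restricted to the pair
  x <- random_table(n_per_pond = 6, ponds = c("P1", "P2", "P3"), n_loci = 3)
  pw <- wc_fst(x, pairwise = TRUE)
  x12 <- x[x$meta$pond != "P3", ]
  expect_equal(pw["P1", "P2"], wc_fst_oracle(x12), tolerance = 1e-12)
})

test_that("W-C theta is invariant to allele relabeling and row order", {
  withr::local_seed(44)
  x <- random_table(n_per_pond = 8, ponds = c("P1", "P2"), n_loci = 3)
  base <- wc_fst(x)
  y <- x
  y$a1 <- y$a1 * 7L + 3L   # strictly monotone recode keeps identity structure
  y$a2 <- y$a2 * 7L + 3L
  expect_equal(wc_fst(y), base, tolerance = 1e-12)
  perm <- sample(nrow(x$meta))
  expect_equal(wc_fst(x[perm, ]), base, tolerance = 1e-12)
  expect_equal(wc_fst(x[, c(3, 1, 2)]), base, tolerance = 1e-12)
})

test_that("chord distance: identity, orthogonal fixation, direct arithmetic", {
  same <- table_from_genotypes(list(
    A = lapply(1:4, function(i) list(c(1, 2))),
    B = lapply(1:4, function(i) list(c(1, 2)))))
  expect_equal(unname(chord_distance(same)["A", "B"]), 0)

  fixed <- table_from_genotypes(list(
    A = lapply(1:4, function(i) list(c(1, 1))),
    B = lapply(1:4, function(i) list(c(2, 2)))))
  expect_equal(unname(chord_distance(fixed)["A", "B"]), 1)

  # p = (.5, .5) vs q = (.8, .2): D = sqrt(1 - (sqrt(.4) + sqrt(.1)))
  mix <- table_from_genotypes(list(
    A = list(i1 = list(c(1, 1)), i2 = list(c(1, 2)), i3 = list(c(2, 2)),
             i4 = list(c(1, 2))),
    B = list(j1 = list(c(1, 1)), j2 = list(c(1, 1)), j3 = list(c(1, 1)),
             j4 = list(c(1, 1)), j5 = list(c(2, 2)))))
  af <- allele_frequencies(mix)
  expect_equal(unname(af$freq$L01["A", ]), c(0.5, 0.5))
  skip_val <- sqrt(1 - (sqrt(0.5 * 0.8) + sqrt(0.5 * 0.2)))
  expect_equal(unname(chord_distance(mix)["A", "B"]), skip_val,
               tolerance = 1e-12)
  expect_equal(round(skip_val, 4), 0.2265)
})

test_that("chord distance variants: bounds, symmetry, variant metadata", {
  withr::local_seed(45)
  x <- random_table(n_per_pond = 10, ponds = c("P1", "P2", "P3"), n_loci = 5,
                    missing_rate = 0.05)
  for (v in c("angular", "takezaki-nei")) {
    d <- chord_distance(x, variant = v)
    expect_silent(validate_dist_matrix(d))
    expect_identical(attr(d, "variant"), v)
    if (v == "angular") expect_true(all(d >= 0 & d <= 1))
  }
})

test_that("popstats skip loci without data in a group instead of imputing", {
  x <- random_table(n_per_pond = 6, ponds = c("P1", "P2"), n_loci = 3)
  x$a1[x$meta$pond == "P2", 2] <- NA_integer_
  x$a2[x$meta$pond == "P2", 2] <- NA_integer_
  expect_silent(d <- chord_distance(x))
  expect_silent(f <- wc_fst(x, pairwise = TRUE))
  # equal to dropping the locus entirely for this pair
  expect_equal(d["P1", "P2"], chord_distance(x[, c(1, 3)])["P1", "P2"])
  expect_equal(f["P1", "P2"], wc_fst(x[, c(1, 3)], pairwise = TRUE)["P1", "P2"])
})
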