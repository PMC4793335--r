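test_that("identical config and seed reproduce the dataset exactly", {
  cfg <- sim_config(seed = 99, n_loci = 5, n_adults = 8, n_clutches = 12,
                    n_embryo_samples = 6, n_larvae_samples = 8)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$table$meta, d2$table$meta)
  expect_identical(d1$table$a1, d2$table$a1)
  expect_identical(d1$ponds, d2$ponds)
})

test_that("vanishing drift leaves ponds essentially undifferentiated", {
  withr::local_seed(21)
  cfg <- sim_config(drift_F = 1e-6, n_loci = 8, missing_rate = 0)
  pf <- simulate_pond_freqs(cfg)
  for (l in seq_along(pf$freqs)) {
    spread <- apply(pf$freqs[[l]], 2, function(col) diff(range(col)))
    expect_lt(max(spread), 0.01)
  }
  ad <- simulate_adults(pf, cfg)
  expect_lt(abs(wc_fst(ad)), 0.01)
})

test_that("expected differentiation from the truth covariance rises with distance", {
  withr::local_seed(22)
  pf <- simulate_pond_freqs(sim_config())
  d <- euclidean_distances(pf$ponds)
  s <- pf$truth$sigma
  # expected Var(p_i - p_j) proportional to s_ii + s_jj - 2 s_ij
  n <- nrow(d)
  dv <- ev <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dv <- c(dv, d[i, j]); ev <- c(ev, s[i, i] + s[j, j] - 2 * s[i, j])
  }
  expect_true(all(diff(ev[order(dv)]) >= -1e-12))
})

test_that("adult genotypes are Hardy-Weinberg draws from the pond field", {
  withr::local_seed(23)
  cfg <- sim_config(n_ponds = 2, n_breeders = 4000, n_adults = 4000,
                    n_loci = 6, drift_F = 0.001,
                    coords = data.frame(pond = c("P1", "P2"),
                                        x = c(0, 1000), y = c(0, 0)))
  pf <- simulate_pond_freqs(cfg)
  ad <- simulate_adults(pf, cfg)
  ho <- observed_heterozygosity(ad)
  for (l in seq_along(pf$freqs)) {
    exp_ho <- 1 - sum(pf$freqs[[l]]["P1", ]^2)
    se <- sqrt(exp_ho * (1 - exp_ho) / 4000)
    expect_lt(abs(ho$locus["P1", l] - exp_ho), 4 * se + 1e-3)
  }
})

test_that("a monomorphic pond field makes all adults homozygous", {
  withr::local_seed(24)
  cfg <- sim_config(n_ponds = 2, n_adults = 20, n_loci = 2,
                    coords = data.frame(pond = c("P1", "P2"),
                                        x = c(0, 500), y = c(0, 0)))
  pf <- simulate_pond_freqs(cfg)
  pf$freqs[[1]] <- matrix(c(1, 1), 2, 1,
                          dimnames = list(c("P1", "P2"), "1"))
  ad <- simulate_adults(pf, cfg)
  expect_true(all(ad$a1[, 1] == ad$a2[, 1]))
  expect_equal(unname(observed_heterozygosity(ad)$locus[, 1]), c(0, 0))
})

test_that("offspring are Mendelian: fixed-cross toy and pedigree-wide check", {
  # parents (1,1) x (2,2) must give only (1,2) offspring
  meta <- data.frame(id = c("m", "f"), pond = "P1", stage = "adult",
                     family = c("fm", "ff"))
  a1 <- matrix(c(1L, 2L), 2, 2, dimnames = list(NULL, c("L1", "L2")))
  a2 <- matrix(c(1L, 2L), 2, 2, dimnames = list(NULL, c("L1", "L2")))
  adults <- genotype_table(meta, a1, a2)
  cfg <- sim_config(n_ponds = 2, n_adults = 2, n_clutches = 4,
                    n_embryo_samples = 3, n_larvae_samples = 5,
                    ponds_without_larvae = 0)
  withr::local_seed(25)
  off <- simulate_offspring(adults, cfg)
  expect_true(all(sort(c(off$table$a1, off$table$a2)) %in% 1:2))
  expect_true(all(off$table$a1 != off$table$a2))  # always heterozygous 1/2

  # pedigree consistency on a simulated dataset without masking: every
  # juvenile allele pair must be drawable from its recorded breeder parents
  cfg2 <- sim_config(seed = 26, missing_rate = 0, n_loci = 6)
  ds <- generate_dataset(cfg2)
  ped <- ds$truth$pedigree
  tab <- ds$table
  br <- ds$truth$breeders
  rows <- match(ped$id, tab$meta$id)
  mrow <- match(ped$mother, br$meta$id)
  frow <- match(ped$father, br$meta$id)
  expect_false(anyNA(c(mrow, frow)))
  for (l in seq_along(tab$loci)) {
    kid <- cbind(tab$a1[rows, l], tab$a2[rows, l])
    mom_ok <- kid[, 1] == br$a1[mrow, l] | kid[, 1] == br$a2[mrow, l]
    dad_ok <- kid[, 2] == br$a1[frow, l] | kid[, 2] == br$a2[frow, l]
    expect_true(all(mom_ok & dad_ok))
  }
})

test_that("missingness masking matches the configured rate", {
  d0 <- generate_dataset(sim_config(seed = 27, missing_rate = 0))
  expect_false(anyNA(d0$table$a1))
  d1 <- generate_dataset(sim_config(seed = 27, missing_rate = 0.02))
  obs <- mean(is.na(d1$table$a1))
  n_cells <- length(d1$table$a1)
  expect_lt(abs(obs - 0.02), 4 * sqrt(0.02 * 0.98 / n_cells))
  # dataset passes its own invariants
  expect_silent(validate_genotype_table(d1$table))
})

test_that("study design shows through: sample sizes, missing stages, sib labels", {
  ds <- generate_dataset(sim_config(seed = 28))
  m <- ds$table$meta
  expect_equal(sum(m$stage == "adult"), 125)
  expect_equal(sum(m$stage == "embryo"), 125)
  expect_equal(sum(m$stage == "larva"), 90)      # 3 of 5 ponds
  expect_length(unique(m$pond[m$stage == "larva"]), 3)
  # adults default to singleton families
  expect_false(anyDuplicated(m$family[m$stage == "adult"]) > 0)
  # configurable adult sibs: ~13% of adults redundant
  ds2 <- generate_dataset(sim_config(seed = 29, adult_sib_fraction = 0.13))
  ad <- ds2$table[ds2$table$meta$stage == "adult", ]
  rep <- prune_siblings(ad)$report
  expect_equal(sum(rep$n_removed) / sum(rep$n_input), 0.12)
})

test_that("few clutches inflate juvenile differentiation beyond adults", {
  withr::local_seed(30)
  n_rep <- 100
  diff_fst <- replicate(n_rep, {
    ds <- generate_dataset(sim_config(n_clutches = 10, n_embryo_samples = 10,
                                      missing_rate = 0))
    ad <- ds$table[ds$table$meta$stage == "adult", ]
    em <- ds$table[ds$table$meta$stage == "embryo", ]
    fa <- wc_fst(ad, pairwise = TRUE)
    fe <- wc_fst(em, pairwise = TRUE)
    mean(fe[upper.tri(fe)]) - mean(fa[upper.tri(fa)])
  })
  expect_lt(t.test(diff_fst, alternative = "greater")$p.value, 0.05)
  expect_gt(mean(diff_fst), 0)
})

test_that("sim_config validates its inputs", {
  expect_error(sim_config(drift_F = 1.2), "drift_F")
  expect_error(sim_config(missing_rate = 0.2), "missing_rate")
  expect_error(sim_config(n_embryo_samples = 50, n_clutches = 20),
               "exceeds n_clutches")
  expect_error(sim_config(ponds_without_larvae = 5), "ponds_without_larvae")
})

test_that("sim_config round-trips through YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_ponds: 4", "n_loci: 7", "seed: 5",
               "larval_clumping: 0.8"), f)
  cfg <- read_sim_config(f)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_ponds, 4L)
  expect_equal(cfg$larval_clumping, 0.8)
  writeLines("bogus_field: 3", f)
  expect_error(read_sim_config(f), "unknown sim_config field")
})
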