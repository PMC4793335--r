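#' Simulate pond allele-frequency fields with isolation by distance
#'
#' For each locus, ancestral frequencies `p0` are drawn from a symmetric
#' Dirichlet; pond-level deviations are drawn multivariate-normal across
#' ponds with covariance `Sigma_ij = drift_F * exp(-d_ij / ibd_range_m)`,
#' scaled per allele by `p0_a (1 - p0_a)`, then applied on the frequency
#' scale, clipped to `[0, 1]` and renormalised. Because nearby ponds share
#' their drift, expected pairwise F_ST grows with distance roughly as
#' `drift_F * (1 - exp(-d / ibd_range_m))`: adults sampled from these fields
#' show isolation by distance, and in the no-drift (`drift_F -> 0`) or
#' infinite-range limits differentiation vanishes.
#'
#' @param cfg a [sim_config()]. Consumes the current RNG stream.
#' @return list with `ponds` (data.frame `pond, x, y`), `freqs` (per-locus
#'   matrices ponds x alleles), and a `truth` record holding `p0`, the base
#'   covariance `sigma`, and the realised frequencies.
#' @export
simulate_pond_freqs <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ponds <- if (!is.null(cfg$coords)) {
    data.frame(pond = as.character(cfg$coords$pond),
               x = cfg$coords$x, y = cfg$coords$y)
  } else {
    data.frame(pond = sprintf("P%d", seq_len(cfg$n_ponds)),
               x = stats::runif(cfg$n_ponds, 0, cfg$extent_m),
               y = stats::runif(cfg$n_ponds, 0, cfg$extent_m))
  }
  d <- euclidean_distances(ponds)
  sigma <- cfg$drift_F * exp(-d / cfg$ibd_range_m)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) {   # numerical safety net; exp kernel is PD in theory
    sigma_j <- sigma + diag(1e-10 * cfg$drift_F, nrow(sigma))
    ch <- chol(sigma_j)
    message("covariance jittered to restore positive definiteness")
  }
  G <- cfg$n_ponds
  freqs <- p0s <- vector("list", cfg$n_loci)
  loci <- sprintf("loc%02d", seq_len(cfg$n_loci))
  for (l in seq_len(cfg$n_loci)) {
    K <- sample(cfg$alleles_min:cfg$alleles_max, 1L)
    p0 <- as.vector(rdirichlet(1L, rep(cfg$dirichlet_conc, K)))
    # MVN deviations: ponds x alleles, allele-a sd scaled by sqrt(p0(1-p0))
    z <- t(ch) %*% matrix(stats::rnorm(G * K), G, K)
    dev <- sweep(z, 2L, sqrt(p0 * (1 - p0)), `*`)
    p <- pmin(pmax(sweep(dev, 2L, p0, `+`), 0), 1)
    p <- p / rowSums(p)
    dimnames(p) <- list(ponds$pond, seq_len(K))
    freqs[[l]] <- p
    p0s[[l]] <- p0
  }
  names(freqs) <- names(p0s) <- loci
  list(ponds = ponds, freqs = freqs,
       truth = list(p0 = p0s, sigma = sigma, pond_freqs = freqs))
}

# Draw n diploid HWE genotypes from an allele-frequency vector; returns a
# 2-column matrix of allele codes.
draw_hwe <- function(n, p) {
  codes <- as.integer(names(p) %||% seq_along(p))
  cbind(sample(codes, n, replace = TRUE, prob = p),
        sample(codes, n, replace = TRUE, prob = p))
}

#' Simulate the adult sample (and the breeding pool behind it)
#'
#' Per pond, `n_breeders` diploid genotypes are drawn allele-wise from the
#' pond frequencies (Hardy-Weinberg equilibrium); the first `n_adults` of
#' these exchangeable breeders form the trapped adult sample that is
#' returned. The full breeding pool is attached as the `"breeders"`
#' attribute and is what [simulate_offspring()] draws clutch parents from --
#' so a sampled juvenile's parent is in the adult sample with probability
#' `1 - (1 - n_adults/n_breeders)^2`, not always.
#'
#' Each adult gets a singleton family label; when `adult_sib_fraction > 0`,
#' that fraction of sampled adults is made redundant by sharing the family
#' label of another sampled adult in the same pond (label-level emulation of
#' sampled adult full sibs).
#'
#' @param pf result of [simulate_pond_freqs()].
#' @param cfg the same [sim_config()].
#' @return a [genotype_table] of the `n_adults` sampled adults per pond (no
#'   missing data; masking happens in [generate_dataset()]), with the full
#'   breeder table as `attr(, "breeders")`.
#' @export
simulate_adults <- function(pf, cfg) {
  loci <- names(pf$freqs)
  metas <- list(); a1s <- list(); a2s <- list()
  for (pi in seq_len(cfg$n_ponds)) {
    pond <- pf$ponds$pond[pi]
    n <- cfg$n_breeders
    a1 <- matrix(NA_integer_, n, length(loci), dimnames = list(NULL, loci))
    a2 <- a1
    for (l in seq_along(loci)) {
      p <- pf$freqs[[l]][pi, ]
      names(p) <- colnames(pf$freqs[[l]])
      g <- draw_hwe(n, p)
      a1[, l] <- g[, 1L]; a2[, l] <- g[, 2L]
    }
    metas[[pi]] <- data.frame(
      id = sprintf("%s_A%03d", pond, seq_len(n)), pond = pond,
      stage = "adult", family = sprintf("%s_FA%03d", pond, seq_len(n)),
      stringsAsFactors = FALSE)
    a1s[[pi]] <- a1; a2s[[pi]] <- a2
  }
  breeders <- genotype_table(do.call(rbind, metas), do.call(rbind, a1s),
                             do.call(rbind, a2s))
  sampled <- breeders$meta$id[ave(seq_len(nrow(breeders$meta)),
                                  breeders$meta$pond, FUN = seq_along) <=
                                cfg$n_adults]
  out <- breeders[match(sampled, breeders$meta$id), ]
  n_red <- round_half_away(cfg$adult_sib_fraction * cfg$n_adults)
  if (n_red > 0L) {
    for (pond in unique(out$meta$pond)) {
      rows <- which(out$meta$pond == pond)
      out$meta$family[rows[seq_len(n_red)]] <-
        out$meta$family[rows[n_red + seq_len(n_red)]]
    }
  }
  validate_genotype_table(out)
  attr(out, "breeders") <- breeders
  out
}

# Mendelian offspring: one random allele from each recorded parent, per
# locus, vectorised over offspring x loci.
mendelian_draw <- function(adults, mom_rows, dad_rows) {
  L <- length(adults$loci)
  n <- length(mom_rows)
  pick <- function(m1, m2) {
    takes <- matrix(stats::runif(n * L) < 0.5, n, L)
    ifelse(takes, m1, m2)
  }
  list(a1 = pick(adults$a1[mom_rows, , drop = FALSE],
                 adults$a2[mom_rows, , drop = FALSE]),
       a2 = pick(adults$a1[dad_rows, , drop = FALSE],
                 adults$a2[dad_rows, , drop = FALSE]))
}

#' Simulate embryo and larval samples with clutch structure
#'
#' Per pond, `n_clutches` parent pairs are drawn from the pond's breeding
#' pool (`attr(adults, "breeders")` when present, otherwise the supplied
#' adults themselves): pairs of distinct breeders, drawn with replacement
#' across clutches, so the same pair can found several clutches and produce
#' cryptic full sibs even under one-embryo-per-clutch sampling. Embryos: one Mendelian offspring
#' from each of `n_embryo_samples` distinct clutches. Larvae:
#' `n_larvae_samples` offspring allocated to clutches with probabilities
#' drawn from a symmetric Dirichlet(`larval_clumping`) over clutches --
#' clumped early-life survival and netting concentrate the larval sample in
#' few families (Type III survivorship). The last `ponds_without_larvae`
#' ponds yield no larvae. A juvenile's family label is its clutch's
#' parent-pair id, shared across the embryo and larval stages.
#'
#' @param adults a [genotype_table] of adults (from [simulate_adults()]).
#' @param cfg the [sim_config()].
#' @return list with `table` (a [genotype_table] of embryos + larvae) and
#'   `pedigree` (data.frame `id, pond, stage, clutch, mother, father,
#'   family`).
#' @export
simulate_offspring <- function(adults, cfg) {
  pool <- attr(adults, "breeders") %||% adults
  ponds <- unique(adults$meta$pond)
  no_larvae <- if (cfg$ponds_without_larvae > 0L)
    utils::tail(ponds, cfg$ponds_without_larvae) else character(0)
  loci <- adults$loci
  metas <- a1s <- a2s <- peds <- list()
  for (pond in ponds) {
    rows <- which(pool$meta$pond == pond)
    if (length(rows) < 2L) stopf("pond %s has fewer than 2 adults", pond)
    # clutches: unordered pairs of distinct adults, iid across clutches
    moms <- dads <- integer(cfg$n_clutches)
    for (k in seq_len(cfg$n_clutches)) {
      pr <- sample(rows, 2L)
      moms[k] <- pr[1L]; dads[k] <- pr[2L]
    }
    pair_key <- paste0(pond, "_F", pmin(moms, dads), "_", pmax(moms, dads))
    clutch_id <- sprintf("%s_C%03d", pond, seq_len(cfg$n_clutches))

    # embryo sample: one offspring from each of n_embryo_samples clutches
    emb_cl <- sample.int(cfg$n_clutches, cfg$n_embryo_samples)
    # larval sample: clutch weights ~ Dirichlet(kappa)
    lar_cl <- integer(0)
    if (!pond %in% no_larvae) {
      w <- as.vector(rdirichlet(1L, rep(cfg$larval_clumping, cfg$n_clutches)))
      lar_cl <- sample.int(cfg$n_clutches, cfg$n_larvae_samples,
                           replace = TRUE, prob = w)
      over <- table(lar_cl) > cfg$clutch_size
      if (any(over))
        stopf("clutch_size exceeded when sampling larvae in pond %s", pond)
    }
    cl <- c(emb_cl, lar_cl)
    stage <- rep(c("embryo", "larva"), c(length(emb_cl), length(lar_cl)))
    off <- mendelian_draw(pool, moms[cl], dads[cl])
    colnames(off$a1) <- colnames(off$a2) <- loci
    ids <- c(sprintf("%s_E%03d", pond, seq_along(emb_cl)),
             sprintf("%s_L%03d", pond, seq_along(lar_cl)))
    metas[[pond]] <- data.frame(id = ids, pond = pond, stage = stage,
                                family = pair_key[cl],
                                stringsAsFactors = FALSE)
    a1s[[pond]] <- off$a1; a2s[[pond]] <- off$a2
    peds[[pond]] <- data.frame(
      id = ids, pond = pond, stage = stage, clutch = clutch_id[cl],
      mother = pool$meta$id[moms[cl]], father = pool$meta$id[dads[cl]],
      family = pair_key[cl], stringsAsFactors = FALSE)
  }
  tab <- genotype_table(do.call(rbind, metas), do.call(rbind, a1s),
                        do.call(rbind, a2s))
  list(table = tab, pedigree = do.call(rbind, peds))
}

#' Generate a complete synthetic dataset
#'
#' Composes [simulate_pond_freqs()], [simulate_adults()] and
#' [simulate_offspring()], then masks genotypes at `missing_rate`
#' (a genotype is always missing as a whole). When `cfg$seed` is set the
#' whole dataset is a deterministic function of the configuration
#' (R's Mersenne-Twister stream, seeded once).
#'
#' @param cfg a [sim_config()].
#' @return list with `table` (all individuals, stages and family labels),
#'   `ponds` (data.frame `pond, x, y`), and `truth` (ancestral and pond
#'   frequencies, base covariance, pedigree, config).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  pf <- simulate_pond_freqs(cfg)
  adults <- simulate_adults(pf, cfg)
  off <- simulate_offspring(adults, cfg)
  tab <- bind_genotypes(adults, off$table)
  if (cfg$missing_rate > 0) {
    mask <- matrix(stats::runif(nrow(tab$meta) * length(tab$loci)) <
                     cfg$missing_rate, nrow(tab$meta))
    tab$a1[mask] <- NA_integer_
    tab$a2[mask] <- NA_integer_
  }
  validate_genotype_table(tab)
  list(table = tab, ponds = pf$ponds,
       truth = c(pf$truth, list(pedigree = off$pedigree,
                                breeders = attr(adults, "breeders"),
                                config = cfg)))
}
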