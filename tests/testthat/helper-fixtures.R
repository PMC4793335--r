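# Fixture builders and independent oracles used across the suite.

# Random genotype table: ponds x n individuals, HWE draws from independent
# Dirichlet frequencies per pond (no shared structure unless shared_freqs).
random_table <- function(n_per_pond = 8, ponds = c("P1", "P2"), n_loci = 3,
                         max_alleles = 4, missing_rate = 0,
                         shared_freqs = FALSE, stage = "adult") {
  loci <- sprintf("L%02d", seq_len(n_loci))
  metas <- a1s <- a2s <- list()
  freqs <- lapply(seq_len(n_loci), function(l) {
    k <- sample(2:max_alleles, 1)
    p <- rgamma(k, 1); p / sum(p)
  })
  for (pond in ponds) {
    if (!shared_freqs)
      freqs <- lapply(seq_len(n_loci), function(l) {
        k <- sample(2:max_alleles, 1)
        p <- rgamma(k, 1); p / sum(p)
      })
    a1 <- sapply(freqs, function(p)
      sample(seq_along(p), n_per_pond, replace = TRUE, prob = p))
    a2 <- sapply(freqs, function(p)
      sample(seq_along(p), n_per_pond, replace = TRUE, prob = p))
    if (n_per_pond == 1) { a1 <- rbind(a1); a2 <- rbind(a2) }
    colnames(a1) <- colnames(a2) <- loci
    if (missing_rate > 0) {
      mask <- matrix(runif(n_per_pond * n_loci) < missing_rate, n_per_pond)
      a1[mask] <- NA_integer_; a2[mask] <- NA_integer_
    }
    metas[[pond]] <- data.frame(
      id = sprintf("%s_i%03d", pond, seq_len(n_per_pond)), pond = pond,
      stage = stage, family = sprintf("%s_f%03d", pond, seq_len(n_per_pond)),
      stringsAsFactors = FALSE)
    a1s[[pond]] <- a1; a2s[[pond]] <- a2
  }
  genotype_table(do.call(rbind, metas), do.call(rbind, a1s),
                 do.call(rbind, a2s))
}

# Build a genotype table from an explicit list of populations, each a list
# of c(a, b) allele pairs per locus:
# pops = list(P1 = list(ind1 = list(c(1,2), c(3,3)), ...), ...)
table_from_genotypes <- function(pops, loci = NULL) {
  inds <- unlist(pops, recursive = FALSE)
  L <- length(inds[[1]])
  loci <- loci %||% sprintf("L%02d", seq_len(L))
  a1 <- matrix(unlist(lapply(inds, function(g) sapply(g, `[`, 1))),
               ncol = L, byrow = TRUE)
  a2 <- matrix(unlist(lapply(inds, function(g) sapply(g, `[`, 2))),
               ncol = L, byrow = TRUE)
  colnames(a1) <- colnames(a2) <- loci
  pond <- rep(names(pops), vapply(pops, length, 0L))
  genotype_table(
    data.frame(id = sprintf("i%03d", seq_along(inds)), pond = pond,
               stringsAsFactors = FALSE),
    a1, a2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# Independent Weir & Cockerham (1984) theta oracle: a deliberately plain,
# loop-per-allele transcription of the textbook variance components, sharing
# no code with the package implementation.
wc_fst_oracle <- function(x, grouping = "pond") {
  g <- as.character(if (length(grouping) == 1) x$meta[[grouping]] else grouping)
  pops <- sort(unique(g))
  r <- length(pops)
  num <- 0; den <- 0
  for (locus in x$loci) {
    A1 <- x$a1[, locus]; A2 <- x$a2[, locus]
    alleles <- sort(unique(na.omit(c(A1, A2))))
    n <- sapply(pops, function(p) sum(!is.na(A1[g == p])))
    if (any(n == 0)) next
    nbar <- mean(n)
    if (nbar <= 1) next
    nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
    for (al in alleles) {
      p_i <- sapply(pops, function(p) {
        rows <- g == p & !is.na(A1)
        (sum(A1[rows] == al) + sum(A2[rows] == al)) / (2 * sum(rows))
      })
      h_i <- sapply(pops, function(p) {
        rows <- g == p & !is.na(A1)
        sum(A1[rows] != A2[rows] &
              (A1[rows] == al | A2[rows] == al)) / sum(rows)
      })
      pbar <- sum(n * p_i) / (r * nbar)
      s2 <- sum(n * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(n * h_i) / (r * nbar)
      a <- (nbar / nc) *
        (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 -
           (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      num <- num + a
      den <- den + a + b + cc
    }
  }
  num / den
}

# Brute-force Mantel r (double loop over upper triangle).
mantel_r_oracle <- function(gm, dm) {
  n <- nrow(gm)
  gs <- ds <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    gs <- c(gs, gm[i, j]); ds <- c(ds, dm[i, j])
  }
  cor(gs, ds)
}

# Monte-Carlo rarefaction oracle: mean distinct alleles over random
# g-subsets of the gene-copy pool implied by an allele count vector.
ar_mc_oracle <- function(counts, g, n_mc = 20000) {
  pool <- rep(seq_along(counts), counts)
  draws <- replicate(n_mc, length(unique(pool[sample.int(length(pool), g)])))
  c(mean = mean(draws), se = sd(draws) / sqrt(n_mc))
}

# Random labelled symmetric distance matrix with zero diagonal.
random_dist <- function(n, labels = sprintf("S%d", seq_len(n))) {
  m <- as.matrix(dist(matrix(runif(n * 2), n)))
  dimnames(m) <- list(labels, labels)
  m
}
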