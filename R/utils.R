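# Small internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Round half away from zero
#'
#' Deterministic rounding used when converting a mixture proportion into an
#' integer number of juveniles per pond: 0.5 rounds to 1, -0.5 to -1
#' (base `round()` rounds half to even, which would make the composition rule
#' depend on parity).
#'
#' @param x numeric vector.
#' @return numeric vector of rounded values.
#' @export
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Symmetric/general Dirichlet draws, one row per draw.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = alpha, rate = 1),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}

# All n! permutations of 1..n as an (n! x n) integer matrix. Guarded by the
# callers (n <= 8).
all_perms <- function(n) {
  n <- as.integer(n)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  ns <- nrow(sub)
  out <- matrix(0L, n * ns, n)
  for (k in seq_len(n)) {
    rows <- (k - 1L) * ns + seq_len(ns)
    out[rows, 1L] <- k
    out[rows, -1L] <- sub + (sub >= k)
  }
  out
}

upper_vec <- function(m) m[upper.tri(m)]

# Labels "A:B" for the upper-triangle pairs of a labelled square matrix.
pair_labels <- function(labels) {
  n <- length(labels)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  paste(labels[idx[, 1L]], labels[idx[, 2L]], sep = ":")
}

# Fast two-way count table for integer-coded factors: G x A matrix.
tab2 <- function(gi, ai, G, A) {
  if (length(gi) == 0L) return(matrix(0L, G, A))
  matrix(tabulate((ai - 1L) * G + gi, nbins = G * A), G, A)
}
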