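#' Configuration for the synthetic pond-metapopulation generator
#'
#' Bundles and validates all generator parameters. The defaults emulate the
#' study design the package targets: five fishless ponds within a ~4 km
#' extent, 15 polymorphic microsatellite loci, 25 adults and 25
#' single-embryo-per-clutch samples per pond, 30 larvae in all but two ponds,
#' adult differentiation of F_ST ~ 0.01 decaying with distance, juvenile
#' cohorts whose drift and sib structure arise mechanistically from a finite
#' number of clutches, and <0.5% missing genotypes.
#'
#' @param n_ponds number of ponds.
#' @param coords optional data.frame `pond, x, y` (metres); when `NULL`,
#'   coordinates are drawn uniformly over an `extent_m` x `extent_m` square.
#' @param extent_m side of the square within which ponds are placed.
#' @param n_loci number of microsatellite loci.
#' @param alleles_min,alleles_max range of allele counts per locus (drawn
#'   uniformly).
#' @param dirichlet_conc concentration of the symmetric Dirichlet from which
#'   ancestral allele frequencies are drawn.
#' @param drift_F per-pond drift variance scale (the F in the
#'   frequency-covariance model); expected pairwise F_ST at distance d is
#'   `drift_F * (1 - exp(-d / ibd_range_m))` up to the attenuation caused by
#'   clipping/renormalising frequencies onto the simplex (about 0.6 at these
#'   settings). The default 0.02 puts the realized mean pairwise adult F_ST
#'   at ~0.01, the scale observed for breeding adults in the target system.
#' @param ibd_range_m decay length (metres) of the exponential covariance of
#'   pond frequency deviations -- the isolation-by-distance range.
#' @param n_breeders breeding adults present in each pond; clutch parents are
#'   drawn from this pool, of which the `n_adults` sampled (trapped) adults
#'   are a subset. Governs how often a sampled juvenile's parent is itself in
#'   the adult sample. Default 250 (robust breeding aggregations of a few
#'   hundred).
#' @param n_adults adults sampled per pond.
#' @param adult_sib_fraction fraction of sampled adults that are redundant
#'   full sibs (share a family label with another adult). Default 0:
#'   sampling adult full sibs is unlikely for a long-lived breeder; set to
#'   ~0.13 to emulate the adult removals of the target design.
#' @param n_clutches egg clutches laid per pond; parent pairs are drawn from
#'   the sampled adults with replacement across clutches.
#' @param clutch_size eggs per clutch (an upper bound on per-clutch sampling;
#'   far above any sampling intensity used here).
#' @param n_embryo_samples embryos sampled per pond, one per distinct clutch.
#' @param n_larvae_samples larvae sampled per pond (ponds with larvae).
#' @param larval_clumping Dirichlet concentration of per-clutch
#'   survival/sampling weights for larvae; small values mean few families
#'   dominate the larval sample. The default (1.0, with 60 clutches) puts the
#'   expected proportion of redundant larval sibs at ~0.33.
#' @param ponds_without_larvae number of ponds yielding no larvae (the last
#'   ponds in pond order); default 2, capped at `n_ponds - 1`.
#' @param missing_rate per-genotype missingness probability, in `[0, 0.05]`.
#' @param seed optional integer seed used by [generate_dataset()].
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_ponds = 5L, coords = NULL, extent_m = 4000,
                       n_loci = 15L, alleles_min = 2L, alleles_max = 10L,
                       dirichlet_conc = 1.0, drift_F = 0.02,
                       ibd_range_m = 1500, n_breeders = 250L,
                       n_adults = 25L,
                       adult_sib_fraction = 0, n_clutches = 60L,
                       clutch_size = 100L, n_embryo_samples = 25L,
                       n_larvae_samples = 30L, larval_clumping = 1.0,
                       ponds_without_larvae = min(2L, n_ponds - 1L),
                       missing_rate = 0.005, seed = NULL) {
  cfg <- list(n_ponds = as.integer(n_ponds), coords = coords,
              extent_m = extent_m, n_loci = as.integer(n_loci),
              alleles_min = as.integer(alleles_min),
              alleles_max = as.integer(alleles_max),
              dirichlet_conc = dirichlet_conc, drift_F = drift_F,
              ibd_range_m = ibd_range_m, n_breeders = as.integer(n_breeders),
              n_adults = as.integer(n_adults),
              adult_sib_fraction = adult_sib_fraction,
              n_clutches = as.integer(n_clutches),
              clutch_size = as.integer(clutch_size),
              n_embryo_samples = as.integer(n_embryo_samples),
              n_larvae_samples = as.integer(n_larvae_samples),
              larval_clumping = larval_clumping,
              ponds_without_larvae = as.integer(ponds_without_larvae),
              missing_rate = missing_rate, seed = seed)
  with(cfg, {
    if (n_ponds < 2L) stopf("need at least 2 ponds")
    if (any(c(n_loci, alleles_min, n_adults, n_clutches, clutch_size,
              n_embryo_samples, n_larvae_samples) < 1L))
      stopf("all counts must be positive")
    if (alleles_max < alleles_min) stopf("alleles_max < alleles_min")
    if (drift_F <= 0 || drift_F >= 1) stopf("drift_F must be in (0, 1)")
    if (larval_clumping <= 0) stopf("larval_clumping must be > 0")
    if (missing_rate < 0 || missing_rate > 0.05)
      stopf("missing_rate must be in [0, 0.05]")
    if (ibd_range_m <= 0) stopf("ibd_range_m must be > 0")
    if (n_embryo_samples > n_clutches)
      stopf("n_embryo_samples (%d) exceeds n_clutches (%d)",
            n_embryo_samples, n_clutches)
    if (ponds_without_larvae < 0L || ponds_without_larvae >= n_ponds)
      stopf("ponds_without_larvae must be in [0, n_ponds)")
    if (adult_sib_fraction < 0 || adult_sib_fraction > 0.5)
      stopf("adult_sib_fraction must be in [0, 0.5]")
    if (n_breeders < max(2L, n_adults))
      stopf("n_breeders must be at least max(2, n_adults)")
  })
  if (!is.null(coords)) {
    if (!is.data.frame(coords) || !all(c("pond", "x", "y") %in% names(coords)))
      stopf("coords must be a data.frame with columns pond, x, y")
    if (nrow(coords) != cfg$n_ponds)
      stopf("coords has %d rows, expected n_ponds = %d", nrow(coords),
            cfg$n_ponds)
  }
  structure(cfg, class = "sim_config")
}

#' Read a simulation configuration from YAML or JSON
#'
#' The file holds a mapping of [sim_config()] argument names to values
#' (unknown keys are an error). `coords` may be given as a list of
#' `{pond, x, y}` records.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
          else yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(sim_config)))
  if (length(unknown))
    stopf("unknown sim_config field(s): %s", paste(unknown, collapse = ", "))
  if (!is.null(vals$coords)) vals$coords <- as.data.frame(vals$coords)
  do.call(sim_config, vals)
}
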