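#' Run the full life-stage analysis pipeline
#'
#' End-to-end driver composing the package: obtain data (simulate or load),
#' screen loci, prune siblings, compute per-stage summary statistics and
#' pairwise distances, bootstrap the mixed-tissue pools, test
#' isolation-by-distance per stage, and (optionally) sweep the
#' juvenile-proportion x locus-count mixture grid. All outputs are written
#' as CSV (plus a JSON run manifest recording the seed, settings and chosen
#' conventions) into `out_dir`.
#'
#' @param config a list, or the path of a YAML/JSON file, with elements:
#'   * `seed`: integer, single seed for the whole run;
#'   * `simulate`: list of [sim_config()] arguments (used when no `input`);
#'   * `input`: list with `genotypes_csv` and `ponds_csv` paths;
#'   * `fidelity`: `"test"` (default; n_boot = 200, grid n_boot = 100) or
#'     `"full"` (n_boot = 1000, Mantel permutations 100000);
#'   * `gdist_kind`, `variant`, `run_mixture_grid` (logical),
#'     `mixture_proportions`, `loci_counts`, `n_per_pond`, `n_sample`.
#' @param out_dir output directory (created if absent).
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config, out_dir = "stagemix-run") {
  if (is.character(config)) {
    path <- config
    if (!file.exists(path)) stopf("config file not found: %s", path)
    config <- if (grepl("\\.json$", path))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
  }
  fidelity <- config$fidelity %||% "test"
  if (!fidelity %in% c("test", "full"))
    stopf("fidelity must be 'test' or 'full'")
  n_boot <- if (fidelity == "full") 1000L else 200L
  grid_boot <- if (fidelity == "full") 1000L else 100L
  seed <- as.integer(config$seed %||% 1L)
  gdist_kind <- config$gdist_kind %||% "dc"
  variant <- config$variant %||% "angular"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  set.seed(seed)
  if (!is.null(config$input)) {
    gp <- config$input$genotypes_csv
    pp <- config$input$ponds_csv
    for (f in c(gp, pp)) if (!file.exists(f)) stopf("input file not found: %s", f)
    tab <- read_csv_genotypes(gp)
    ponds <- utils::read.csv(pp, stringsAsFactors = FALSE)
    pedigree <- NULL
  } else {
    sim_args <- config$simulate %||% list()
    sim_args$seed <- sim_args$seed %||% seed
    ds <- do.call(sim_config, sim_args)
    ds <- generate_dataset(ds)
    tab <- ds$table; ponds <- ds$ponds; pedigree <- ds$truth$pedigree
    write_csv_genotypes(tab, file.path(out_dir, "genotypes.csv"))
    utils::write.csv(ponds, file.path(out_dir, "ponds.csv"), row.names = FALSE)
  }

  fl <- filter_loci(tab)
  tab <- fl$table
  utils::write.csv(fl$report, file.path(out_dir, "locus_filter_report.csv"),
                   row.names = FALSE)

  pruned <- prune_siblings(tab, scope = "within_stage")
  utils::write.csv(pruned$report, file.path(out_dir, "sibling_removal.csv"),
                   row.names = FALSE)
  pooled <- prune_siblings(tab, scope = "pooled", pedigree = pedigree)

  ddist <- euclidean_distances(ponds)
  write_dist_matrix(ddist, file.path(out_dir, "geographic_distances.csv"))

  stages <- intersect(STAGES, unique(tab$meta$stage))
  variants <- list(with_sibs = tab, no_sibs = pruned$table)
  summary_rows <- list(); mantel_rows <- list()
  for (vn in names(variants)) {
    vt <- variants[[vn]]
    for (stg in stages) {
      sub <- vt[vt$meta$stage == stg, ]
      ho <- observed_heterozygosity(sub)
      ar <- rarefied_allelic_richness(sub)
      summary_rows[[paste(vn, stg)]] <- data.frame(
        dataset = vn, stage = stg, pond = names(ho$mean),
        n = as.integer(table(factor(sub$meta$pond, levels = names(ho$mean)))),
        ho = ho$mean, ar = ar$mean, ar_g = ar$g, stringsAsFactors = FALSE)
      fst <- wc_fst(sub, pairwise = TRUE)
      dc <- chord_distance(sub, variant = variant)
      gd <- if (gdist_kind == "dc") dc else fst
      write_dist_matrix(fst, file.path(out_dir,
        sprintf("fst_%s_%s.csv", vn, stg)))
      write_dist_matrix(dc, file.path(out_dir,
        sprintf("dc_%s_%s.csv", vn, stg)))
      if (nrow(gd) >= 3L) {
        labs <- rownames(gd)   # some stages cover a subset of ponds
        mt <- mantel_exact(gd, ddist[labs, labs])
        mantel_rows[[paste(vn, stg)]] <- data.frame(
          dataset = vn, stage = stg, gdist = gdist_kind, r = mt$r, p = mt$p,
          method = "exact", n_arrangements = mt$n_perm,
          stringsAsFactors = FALSE)
      }
    }
  }
  utils::write.csv(do.call(rbind, summary_rows),
                   file.path(out_dir, "summary_stats.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, mantel_rows),
                   file.path(out_dir, "ibd_mantel.csv"), row.names = FALSE)

  n_sample <- as.integer(config$n_sample %||% 25L)
  mb <- bootstrap_mixed(pooled$table, n_sample = n_sample, n_boot = n_boot,
                        variant = variant)
  utils::write.csv(rbind(mb$per_pond, mb$per_pair),
                   file.path(out_dir, "mixed_bootstrap.csv"),
                   row.names = FALSE)

  grid_file <- NULL
  if (isTRUE(config$run_mixture_grid %||% FALSE)) {
    ad <- pooled$table[pooled$table$meta$stage == "adult", ]
    ju <- pooled$table[pooled$table$meta$stage %in% c("embryo", "larva"), ]
    mg <- mixture_grid(
      ad, ju, ddist,
      n_per_pond = as.integer(config$n_per_pond %||% 18L),
      proportions = config$mixture_proportions %||% seq(0, 1, by = 0.05),
      loci_counts = as.integer(config$loci_counts %||%
                                 c(5L, 10L, min(15L, length(tab$loci)))),
      n_boot = grid_boot, gdist_kind = gdist_kind, variant = variant)
    grid_file <- file.path(out_dir, "mixture_curve.csv")
    utils::write.csv(as.data.frame(mg), grid_file, row.names = FALSE)
  }

  manifest <- list(
    seed = seed, fidelity = fidelity, n_boot = n_boot,
    gdist_kind = gdist_kind, chord_variant = variant,
    sd_denominator = "n", mantel_tail = "greater",
    resampling = "without replacement",
    loci_kept = tab$loci, stages = stages,
    package_version = as.character(utils::packageVersion("stagemix")),
    outputs = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
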