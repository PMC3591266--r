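# End-to-end pipeline: collate -> complex stats -> enrichment ->
# signal integration -> PTMi spots -> overlay, with all stage tables
# written to an output directory. The numbered scripts under analysis/
# are thin drivers over this function and the stage functions.

#' Pipeline run configuration
#'
#' Bundles input paths and stage parameters. Every parameter defaults to
#' the analysis defaults (20AA windows, 10AA step, density threshold 0.3,
#' confidence 99%/95%, R = 100 permutations, S = 1000 resamples,
#' mutation cutoff kappa = 2).
#'
#' @param site_table,fasta,complex_table required input paths.
#' @param domain_table,disorder_table,mutation_table optional annotation
#'   paths; the overlay stage is skipped when any is missing.
#' @param out_dir output directory for stage tables.
#' @param config a [scan_config()].
#' @param confidence per-type confidence cutoffs.
#' @param R permutation replicates for the complex null.
#' @param S resampling draws for signal Z-scores.
#' @param kappa mutation-count cutoff.
#' @param seed master seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(site_table, fasta, complex_table,
                       domain_table = NULL, disorder_table = NULL,
                       mutation_table = NULL, out_dir = tempfile("ptmscape_"),
                       config = scan_config(),
                       confidence = DEFAULT_CONFIDENCE,
                       R = 100L, S = 1000L, kappa = 2L, seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full PTM coordination pipeline
#'
#' Executes collation, complex statistics, permutation-null enrichment,
#' overlap analysis, signal-integration Z-scores for each enriched group,
#' PTMi spot calling with degron/PY-NLS annotation, and (when annotation
#' inputs are provided) the domain/disorder/mutation overlay. All stage
#' tables are written under `rc$out_dir`; a summary report is returned
#' and written as JSON.
#'
#' @param rc a [run_config()].
#' @return Invisible list with the stage objects and the `summary` list.
#' @export
run_pipeline <- function(rc) {
  stopifnot(inherits(rc, "run_config"))
  dir.create(rc$out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, name) {
    utils::write.table(x, file.path(rc$out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  ## collation
  ds <- collate(parse_site_table(rc$site_table, rc$fasta))
  write_site_table(ds, file.path(rc$out_dir, "collated_sites.tsv"))
  writeLines(ds$log, file.path(rc$out_dir, "collation_log.txt"))
  tsv(ptm_profile_table(ds), "protein_profiles.tsv")

  ## complexes + enrichment
  cx <- filter_and_collapse(parse_complexes(rc$complex_table), ds)
  stats <- complex_ptm_stats(cx, ds)
  tsv(stats, "complex_stats.tsv")
  scheme <- assign_bins(ds, cx)
  null <- build_null(ds, cx, scheme, R = rc$R, seed = derive_seed(rc$seed, 10L))
  enr <- select_enriched(stats, null, rc$confidence)
  enr_path <- file.path(rc$out_dir, "enrichment.tsv")
  writeLines(sprintf("# R=%d seed=%s", rc$R, rc$seed), enr_path)
  suppressWarnings(utils::write.table(enr, enr_path, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  ov <- overlap_enriched(enr)
  tsv(ov$membership, "enrichment_overlap.tsv")

  ## signal integration per enriched group
  zs <- list()
  for (g in names(ov$groups)) {
    ids <- ov$groups[[g]]
    if (length(ids) == 0L) next
    zs[[g]] <- signal_matrix_analysis(ids, cx, ds, S = rc$S,
                                      seed = derive_seed(rc$seed, 20L))
    tsv(data.frame(group = g, multiplicity = rep(1:4, 4),
                   ptm_type = rep(PTM_TYPES, each = 4),
                   observed = as.vector(zs[[g]]$observed),
                   null_mean = as.vector(zs[[g]]$null_mean),
                   null_sd = as.vector(zs[[g]]$null_sd),
                   z = as.vector(zs[[g]]$z)),
        sprintf("signal_matrix_%s.tsv", g))
  }

  ## PTMi spots
  spots <- call_spots_all(ds, rc$config)
  if (nrow(spots) > 0L)
    write_spots_bed(spots, file.path(rc$out_dir, "ptmi_spots.bed"))
  degrons <- find_hyperphospho_degrons(spots, ds)
  tsv(degrons, "degron_candidates.tsv")
  nls <- do.call(rbind, lapply(unique(spots$protein_id),
                               function(p) find_py_nls(ds, p)))
  if (!is.null(nls) && nrow(nls) > 0L) tsv(nls, "py_nls_candidates.tsv")

  ## overlay (optional)
  overlay <- NULL
  if (!is.null(rc$domain_table) && !is.null(rc$disorder_table) &&
      !is.null(rc$mutation_table)) {
    dom <- parse_domain_table(rc$domain_table, ds)
    dis <- parse_disorder_tracks(rc$disorder_table, ds)
    mut <- parse_mutation_table(rc$mutation_table, ds)
    overlay <- overlay_windows(ds, dom, dis, mut, rc$config, rc$kappa)
    tsv(overlay, "overlay_windows.tsv")
    tsv(mutated_fraction_table(overlay), "mutated_fractions.tsv")
  }

  summary <- list(
    n_modifications = n_sites(ds),
    n_proteins = length(ds$sequences),
    n_complexes = length(cx$members),
    n_enriched_per_type = as.list(
      table(factor(enr$ptm_type[enr$selected], levels = PTM_TYPES))),
    n_ge3 = length(ov$groups$ge3),
    n_spots = nrow(spots),
    n_spots_multi = sum(spots$classification == "multi"),
    n_degron_candidates = nrow(degrons),
    seed = rc$seed
  )
  jsonlite::write_json(summary, file.path(rc$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(dataset = ds, complexes = cx, stats = stats,
                 enrichment = enr, overlap = ov, signal = zs,
                 spots = spots, degrons = degrons, py_nls = nls,
                 overlay = overlay, summary = summary))
}
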