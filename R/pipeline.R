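# End-to-end orchestration: simulate (or read) a cohort, apply QC filters,
# compute diversity and distances, cluster into community state types,
# run the statistical screens and the movement analysis, and write a
# result bundle.  Stages are ordinary package functions so each is
# independently scriptable; this file only wires them together.

#' Pipeline configuration
#'
#' @param seed global seed; per-stage seeds are derived from it so stages
#'   are reproducible in isolation
#' @param min_copies qPCR low-load threshold (samples with fewer copies
#'   are removed)
#' @param min_reads library-size floor applied after the load filter
#' @param rarefaction_depth `"min"` (rarefy to the minimum post-QC library
#'   size) or a fixed integer depth
#' @param metrics distance metrics to compute, subset of
#'   `c("bray_curtis", "aitchison")`; the first is used for clustering
#' @param pseudocount CLR pseudocount for the Aitchison metric
#' @param k_range candidate cluster numbers for silhouette selection
#' @param silhouette_space `"distance"` or `"pcoa"`
#' @param abundance_cut,prevalence_cut dominant-taxon labelling thresholds
#' @param alpha significance level for screens and flags
#' @param n_permutations permutations for the community tests
#' @param yates apply continuity correction in 2x2 tests
#' @return validated `pipeline_config` list
#' @export
pipeline_config <- function(seed = 1L,
                            min_copies = 1e3,
                            min_reads = 1268,
                            rarefaction_depth = "min",
                            metrics = c("bray_curtis", "aitchison"),
                            pseudocount = 1,
                            k_range = 2:20,
                            silhouette_space = "distance",
                            abundance_cut = 0.35,
                            prevalence_cut = 0.70,
                            alpha = 0.05,
                            n_permutations = 999,
                            yates = TRUE) {
  cfg <- as.list(environment())
  stopifnot(all(metrics %in% c("bray_curtis", "aitchison")),
            length(metrics) >= 1,
            silhouette_space %in% c("distance", "pcoa"),
            min_copies > 0, min_reads >= 0,
            identical(rarefaction_depth, "min") ||
              (is.numeric(rarefaction_depth) && rarefaction_depth > 0),
            abundance_cut > 0, abundance_cut < 1,
            prevalence_cut > 0, prevalence_cut < 1,
            alpha > 0, alpha < 1, n_permutations >= 1)
  structure(cfg, class = "pipeline_config")
}

# derive a stable per-stage seed from the global one
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) %% 100000L) * 7919L + as.integer(h %% 7919L)
}

#' Run the full community-state-type analysis
#'
#' Stages: QC (qPCR load then minimum-read filters), alpha diversity,
#' rarefaction + Bray-Curtis (and optionally Aitchison on unrarefied
#' counts), silhouette-guided complete-linkage clustering with singleton
#' exclusion and dominant-taxon labels, cluster validation (PERMANOVA,
#' ANOSIM, PERMDISP), metadata screening and per-variable PERMANOVA, and
#' the movement analysis (trajectories, categories, frequency tests,
#' transition counts).
#'
#' @param ds a [study_dataset()] (e.g. from [simulate_cohort()])
#' @param cfg a [pipeline_config()]
#' @param outdir optional directory; when given, tables and a JSON summary
#'   are written there
#' @return result bundle (list) with elements qc, shannon, distances,
#'   clustering, labels, cluster_tests, metadata, movement, summary
#' @export
run_full_pipeline <- function(ds, cfg = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(ds, "study_dataset"), inherits(cfg, "pipeline_config"))
  t0 <- Sys.time()
  log_stage <- function(stage)
    message(sprintf("[%s] %-10s elapsed=%.1fs seed=%d", "cstmove", stage,
                    as.numeric(Sys.time() - t0, units = "secs"), cfg$seed))

  log_stage("qc")
  qc1 <- if (is.null(ds$qpcr)) list(dataset = ds, removed = character()) else
    filter_low_load(ds, min_copies = cfg$min_copies)
  fr <- filter_min_reads(qc1$dataset$feature_table, cfg$min_reads)
  ds2 <- subset_dataset(qc1$dataset, rownames(fr$feature_table))
  qc <- list(removed_low_load = qc1$removed, removed_low_reads = fr$removed,
             n_samples = nrow(ds2$feature_table))

  log_stage("diversity")
  sh <- shannon_samples(ds2$feature_table)
  depth <- if (identical(cfg$rarefaction_depth, "min"))
    min(library_sizes(ds2$feature_table)) else as.integer(cfg$rarefaction_depth)
  rare <- rarefy_counts(ds2$feature_table, depth = depth,
                        seed = stage_seed(cfg$seed, "rarefy"))
  distances <- list()
  if ("bray_curtis" %in% cfg$metrics)
    distances$bray_curtis <- bray_curtis_matrix(rare)
  if ("aitchison" %in% cfg$metrics)
    distances$aitchison <- aitchison_matrix(ds2$feature_table, cfg$pseudocount)
  dm <- distances[[cfg$metrics[1]]]

  log_stage("cluster")
  sel <- silhouette_k_selection(dm, k_range = cfg$k_range,
                                space = cfg$silhouette_space)
  assignment <- exclude_singletons(cut_tree(sel$tree, sel$k),
                                   mean_silhouette_by_k = sel$mean_silhouette)
  genus_ft <- aggregate_by_genus(ds2$feature_table, ds2$taxonomy)
  genus_prop <- relative_abundance(genus_ft)
  labels <- dominant_taxon_labels(assignment, genus_prop,
                                  abundance_cut = cfg$abundance_cut,
                                  prevalence_cut = cfg$prevalence_cut)
  summary_tab <- cluster_summary(assignment, labels, genus_prop,
                                 shannon = sh, qpcr = ds2$qpcr)

  log_stage("stats")
  keep <- names(assignment$clusters)
  dsub <- as.matrix(dm)[keep, keep]
  grp <- factor(assignment$clusters[keep])
  st_seed <- stage_seed(cfg$seed, "stats")
  cluster_tests <- list(
    permanova = permanova(dsub, grp, cfg$n_permutations, seed = st_seed),
    anosim = anosim(dsub, grp, cfg$n_permutations, seed = st_seed),
    permdisp = permdisp(dsub, grp, cfg$n_permutations, seed = st_seed))
  screen <- metadata_screen(ds2$metadata)
  assoc <- metadata_association_matrix(ds2$metadata, screen, alpha = cfg$alpha)
  pvar <- permanova_screen(dm, ds2$metadata, screen,
                           n_permutations = cfg$n_permutations, seed = st_seed)

  log_stage("movement")
  traj <- suppressWarnings(build_trajectories(assignment, ds2$metadata))
  categories <- classify_movements(traj)
  freq_ili <- movement_frequency_test(categories, "ili_status")
  freq_arm <- tryCatch(movement_frequency_test(categories, "arm"),
                       error = function(e) NULL)
  trans <- transition_counts(traj)
  wsd <- within_subject_distance(traj, dm, categories)

  summary <- list(
    n_samples = qc$n_samples,
    n_subjects = length(unique(ds2$metadata$subject_id)),
    rarefaction_depth = depth,
    k_selected = assignment$k_selected,
    n_excluded_singletons = length(assignment$excluded),
    cluster_labels = stats::setNames(labels$label, labels$cluster_id),
    cluster_permanova_p = cluster_tests$permanova$p_value,
    cluster_anosim_R = cluster_tests$anosim$observed,
    movement = list(
      percent_moved_by_ili = as.list(freq_ili$percent_moved),
      ili_vs_no_ili_p = freq_ili$test$p_value,
      arm_comparison_p = if (is.null(freq_arm)) NA else freq_arm$test$p_value,
      category_counts = as.list(table(categories$category[categories$ili_status &
                                        categories$category != "UNCLASSIFIABLE"]))),
    config_hash = config_hash(unclass(cfg)))

  bundle <- list(qc = qc, shannon = sh, rarefied = rare, distances = distances,
                 selection = sel, assignment = assignment, labels = labels,
                 cluster_summary = summary_tab, cluster_tests = cluster_tests,
                 metadata_screen = screen, metadata_associations = assoc,
                 permanova_by_variable = pvar, trajectories = traj,
                 categories = categories, frequency_tests = list(
                   ili = freq_ili, arm = freq_arm),
                 transitions = trans, within_subject = wsd,
                 summary = summary, config = cfg)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    cfgl <- unclass(cfg)
    write_feature_table(rare, file.path(outdir, "rarefied_counts.tsv"), cfgl)
    for (mname in names(distances))
      write_distance_matrix(distances[[mname]],
                            file.path(outdir, paste0(mname, "_distances.tsv")),
                            cfgl)
    write_cluster_assignment(assignment, labels,
                             file.path(outdir, "clusters.tsv"),
                             file.path(outdir, "clusters.json"), cfgl)
    write_movement(categories, trans,
                   file.path(outdir, "movement_categories.tsv"),
                   file.path(outdir, "transition_counts.tsv"), cfgl)
    utils::write.table(pvar, file.path(outdir, "permanova_by_variable.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  log_stage("done")
  invisible(bundle)
}

#' Generate a small on-disk fixture cohort
#'
#' Writes a ~30-subject simulated cohort (feature table, taxonomy,
#' metadata + covariate-type sidecar, qPCR, ground truth) in the package's
#' TSV dialects, sized for fast tests.
#'
#' @param outdir output directory (created if needed)
#' @param seed integer seed
#' @param n_subjects cohort size (default 30)
#' @return (invisibly) named list of file paths
#' @export
generate_fixtures <- function(outdir, seed = 1L, n_subjects = 30) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- cohort_config(n_subjects = n_subjects, seed = seed)
  sim <- simulate_cohort(cfg)
  paths <- list(
    feature_table = file.path(outdir, "feature_table.tsv"),
    taxonomy = file.path(outdir, "taxonomy.tsv"),
    metadata = file.path(outdir, "metadata.tsv"),
    qpcr = file.path(outdir, "qpcr.tsv"),
    truth = file.path(outdir, "truth.tsv"))
  cfgl <- unclass(cfg)
  write_feature_table(sim$dataset$feature_table, paths$feature_table, cfgl)
  write_taxonomy(sim$dataset$taxonomy, paths$taxonomy, cfgl)
  write_sample_metadata(sim$dataset$metadata, paths$metadata, cfgl)
  write_qpcr(sim$dataset$qpcr, paths$qpcr, cfgl)
  write_truth(sim$truth, paths$truth)
  invisible(paths)
}

#' Read a fixture directory back into a study dataset
#' @param dir directory written by [generate_fixtures()]
#' @return list: dataset, truth
#' @export
read_fixture_dataset <- function(dir) {
  ft <- read_feature_table(file.path(dir, "feature_table.tsv"))
  tax <- read_taxonomy(file.path(dir, "taxonomy.tsv"))
  md <- read_sample_metadata(file.path(dir, "metadata.tsv"))
  qp <- read_qpcr(file.path(dir, "qpcr.tsv"))
  truth <- read_truth(file.path(dir, "truth.tsv"))
  list(dataset = study_dataset(ft, tax, md, qp), truth = truth)
}
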