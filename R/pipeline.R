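# End-to-end orchestration: simulate (or load) -> preprocess -> differential
# expression -> per-phenotype networks -> canonical filter -> comparison ->
# genomic annotation -> persistent-miR tracking, with every artifact written
# to an output directory and a deterministic reproducibility manifest.
# Wall-clock timestamps go to run.log, never into manifest.json, so reruns
# with identical inputs are byte-identical.

#' Run the full stage-network pipeline
#'
#' @param data either `NULL` (simulate from `config`) or a list with
#'   elements `genes`, `mirs`, `samples`, `annotation` (and optionally
#'   `truth`).
#' @param config a [simulation_config()]; used when `data` is `NULL`.
#' @param out_dir output directory (created if needed).
#' @param k top-K edges retained per phenotype network.
#' @param mi_cfg an [mi_config()].
#' @param gene_thresholds,mir_thresholds DE significance rules.
#' @param max_zero_fraction,min_mean feature-filter thresholds.
#' @param compare_level level at which networks are compared
#'   (`"topk"` or `"canonical"`).
#' @return Invisibly, a list with the stage series, comparison tables,
#'   co-location summary, trajectories and the manifest.
#' @export
run_pipeline <- function(data = NULL, config = default_study(),
                         out_dir, k = 336, mi_cfg = mi_config(),
                         gene_thresholds = gene_de_thresholds(),
                         mir_thresholds = mir_de_thresholds(),
                         max_zero_fraction = 0.5, min_mean = 10,
                         compare_level = "topk") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "INFO", sprintf(...), "\n",
        file = log_path, append = TRUE)
  }

  simulated <- is.null(data)
  if (simulated) {
    logf("simulating dataset (seed %d)", config$seed)
    data <- generate_synthetic(config)
    write_expression(data$genes, file.path(out_dir, "genes_raw.tsv"))
    write_expression(data$mirs, file.path(out_dir, "mirs_raw.tsv"))
    utils::write.table(data$samples, file.path(out_dir, "samples.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_annotation(data$annotation, file.path(out_dir, "annotation.tsv"))
    utils::write.table(data$truth$couplings,
                       file.path(out_dir, "truth_couplings.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data$truth$effects,
                       file.path(out_dir, "truth_effects.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # Preprocess: annotation filter + zero-fraction + low-mean, both kinds.
  fg <- filter_features(data$genes, data$annotation, max_zero_fraction, min_mean)
  fm <- filter_features(data$mirs, data$annotation, max_zero_fraction, min_mean)
  logf("gene filter: %d -> %d", fg$report$n_input, fg$report$n_kept)
  logf("miR filter: %d -> %d", fm$report$n_input, fm$report$n_kept)
  write_json_summary(filter_report_json(fg$report),
                     file.path(out_dir, "filter_report_genes.json"))
  write_json_summary(filter_report_json(fm$report),
                     file.path(out_dir, "filter_report_mirs.json"))

  series <- build_stage_series(fg$matrix, fm$matrix, data$samples,
                               cfg = mi_cfg, k = k,
                               gene_thresholds = gene_thresholds,
                               mir_thresholds = mir_thresholds)
  for (ph in names(series$topk)) {
    write_edges(series$topk[[ph]],
                file.path(out_dir, sprintf("network_%s_topk.tsv", ph)))
    write_graphml(series$topk[[ph]],
                  file.path(out_dir, sprintf("network_%s_topk.graphml", ph)))
  }
  for (st in names(series$canonical)) {
    write_edges(series$canonical[[st]],
                file.path(out_dir, sprintf("network_%s_canonical.tsv", st)))
    logf("stage %s canonical network: %d edges", st,
         nrow(series$canonical[[st]]))
  }

  # DE tables: contiguous (from the series) plus NT-vs-stage.
  for (lbl in names(series$de_genes)) {
    write_de_table(series$de_genes[[lbl]],
                   file.path(out_dir, sprintf("de_genes_%s.tsv", lbl)))
    write_de_table(series$de_mirs[[lbl]],
                   file.path(out_dir, sprintf("de_mirs_%s.tsv", lbl)))
  }
  nt_gene <- run_differential(fg$matrix, data$samples, nt_vs_stage_contrasts(),
                              gene_thresholds)
  nt_mir <- run_differential(fm$matrix, data$samples, nt_vs_stage_contrasts(),
                             mir_thresholds)
  for (lbl in setdiff(names(nt_gene), names(series$de_genes))) {
    write_de_table(nt_gene[[lbl]], file.path(out_dir, sprintf("de_genes_%s.tsv", lbl)))
    write_de_table(nt_mir[[lbl]], file.path(out_dir, sprintf("de_mirs_%s.tsv", lbl)))
  }

  # Cross-network comparison.
  nets <- if (compare_level == "topk") series$topk else
    c(series$topk["NT"], series$canonical)
  itab <- intersection_counts(nets)
  utils::write.table(as.data.frame(itab),
                     file.path(out_dir, "intersection_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  uniq <- vapply(names(nets), function(lbl)
    uniqueness_fraction(nets[[lbl]], nets[names(nets) != lbl]), numeric(1))
  shared <- tumor_shared_not_control(series, level = compare_level)
  utils::write.table(shared, file.path(out_dir, "tumor_shared_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logf("tumor-shared-not-control edges: %d", nrow(shared))

  # Genomic co-location of the tumor-shared set.
  ann_edges <- annotate_edges(shared, data$annotation)
  coloc <- if (nrow(ann_edges)) colocation_summary(ann_edges)
           else list(frac_same_chromosome = 0, frac_same_cytoband = 0,
                     n_unannotated = 0L, n_annotated = 0L)
  write_json_summary(coloc, file.path(out_dir, "colocation_summary.json"))

  # Persistent miRs and their stage-specific targets.
  trajectories <- persistent_de_mirs(series)
  traj_tab <- trajectory_table(trajectories)
  utils::write.table(traj_tab, file.path(out_dir, "mir_trajectories.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_json_summary(
    lapply(trajectories, function(tr) list(
      mir_id = tr$mir_id,
      contrasts = tr$contrasts,
      turnover = target_turnover(tr))),
    file.path(out_dir, "mir_trajectories.json"))
  logf("persistent miRs: %d", length(trajectories))

  manifest <- list(
    package_version = as.character(utils::packageVersion("mirstagenet")),
    seed = if (simulated) config$seed else NA,
    simulated = simulated,
    parameters = list(
      k = k, compare_level = compare_level,
      max_zero_fraction = max_zero_fraction, min_mean = min_mean,
      mi = mi_cfg[c("n_bins", "bias_correction", "rank_transform")],
      gene_thresholds = gene_thresholds, mir_thresholds = mir_thresholds),
    input_checksums = input_checksums(out_dir, simulated),
    counts = list(
      genes_kept = fg$report$n_kept, mirs_kept = fm$report$n_kept,
      topk_edges = lapply(series$topk, nrow),
      canonical_edges = lapply(series$canonical, nrow),
      tumor_shared = nrow(shared),
      persistent_mirs = length(trajectories)),
    uniqueness_fraction = as.list(uniq))
  write_json_summary(manifest, file.path(out_dir, "manifest.json"))
  logf("pipeline complete")

  invisible(list(data = data, series = series, intersections = itab,
                 uniqueness = uniq, tumor_shared = shared,
                 colocation = coloc, trajectories = trajectories,
                 manifest = manifest))
}

filter_report_json <- function(report) {
  list(n_input = report$n_input,
       n_removed_unannotated = report$n_removed_unannotated,
       n_removed_zeros = report$n_removed_zeros,
       n_removed_low_mean = report$n_removed_low_mean,
       n_kept = report$n_kept,
       removed = report$removed_ids)
}

input_checksums <- function(out_dir, simulated) {
  if (!simulated) return(list())
  files <- c("genes_raw.tsv", "mirs_raw.tsv", "samples.tsv", "annotation.tsv")
  sums <- tools::md5sum(file.path(out_dir, files))
  stats::setNames(as.list(unname(sums)), files)
}
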