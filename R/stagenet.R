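# Assembly of the five per-phenotype networks and the opposite-sign
# (canonical regulation) filter keyed to each stage's contiguous contrast.

#' Keep edges whose miR and gene are differentially expressed with opposite sign
#'
#' An edge survives iff its miRNA is `over` and its gene `under`, or vice
#' versa — the canonical miR-mediated repression pattern. Features missing
#' from the DE tables are treated as `ns`. MI scores pass through
#' unchanged; an empty result is legal.
#'
#' @param net a top-K `bipartite_network`.
#' @param de_genes,de_mirs classified `de_result`s (with `status`).
#' @return A `bipartite_network` with `filtered = "canonical"` and the DE
#'   contrast recorded in attribute `contrast`.
#' @export
opposite_sign_filter <- function(net, de_genes, de_mirs) {
  stopifnot(inherits(net, "bipartite_network"))
  if (is.null(de_genes$status) || is.null(de_mirs$status)) {
    stop("DE results must be classified (run classify_de first)")
  }
  gs <- stats::setNames(as.character(de_genes$status), de_genes$feature_id)
  ms <- stats::setNames(as.character(de_mirs$status), de_mirs$feature_id)
  g <- gs[net$gene_id]; g[is.na(g)] <- "ns"
  m <- ms[net$mir_id]; m[is.na(m)] <- "ns"
  keep <- (m == "over" & g == "under") | (m == "under" & g == "over")
  out <- bipartite_network(net$mir_id[keep], net$gene_id[keep], net$mi[keep],
                           phenotype = attr(net, "phenotype"),
                           k = attr(net, "k"), filtered = "canonical")
  attr(out, "contrast") <- attr(de_genes, "contrast")
  out
}

#' Build the full stage series: top-K networks plus canonical stage networks
#'
#' For each of the five phenotypes the samples are subset, all miR-gene MI
#' values computed, and the K highest kept. Each tumor stage's top-K
#' network is then filtered by the opposite-sign rule using the DE results
#' of the contiguous contrast that leads into that stage (NT-I for stage I,
#' I-II for stage II, ...). The NT network has no preceding contrast and is
#' kept at top-K level only.
#'
#' MI is computed on normalized counts (size factors over all samples);
#' DE tests run on the raw counts of each contrast's two groups.
#'
#' @param gene_mat,mir_mat filtered raw-count `expr_matrix` objects.
#' @param samples a `sample_table`.
#' @param cfg an [mi_config()].
#' @param k top-K retention per phenotype network.
#' @param gene_thresholds,mir_thresholds significance rules (see
#'   [gene_de_thresholds()]).
#' @param dispersion_mode passed to [nb_test()].
#' @param min_samples minimum samples required per phenotype.
#' @return A list of class `stage_series` with elements `topk` (5 networks),
#'   `canonical` (4 networks, stages I-IV), `de_genes`, `de_mirs` (per
#'   contiguous contrast), `contrasts`, `k`.
#' @export
build_stage_series <- function(gene_mat, mir_mat, samples, cfg = mi_config(),
                               k = 100000,
                               gene_thresholds = gene_de_thresholds(),
                               mir_thresholds = mir_de_thresholds(),
                               dispersion_mode = "per_feature",
                               min_samples = 4) {
  stopifnot(inherits(samples, "sample_table"))
  shared <- intersect(sample_ids(gene_mat), samples$sample_id)
  samples <- samples[samples$sample_id %in% shared, , drop = FALSE]
  counts <- table(factor(samples$phenotype, levels = PHENOTYPE_LEVELS))
  low <- names(counts)[counts < min_samples]
  if (length(low)) {
    stop("phenotype(s) below the ", min_samples, "-sample minimum: ",
         paste(low, collapse = ", "))
  }

  sf_gene <- size_factors(gene_mat)
  sf_mir <- size_factors(mir_mat)
  gene_norm <- normalize_counts(gene_mat, sf_gene)
  mir_norm <- normalize_counts(mir_mat, sf_mir)

  topk <- stats::setNames(vector("list", 5L), PHENOTYPE_LEVELS)
  for (ph in PHENOTYPE_LEVELS) {
    ids <- samples_of(samples, ph)
    raw_net <- all_pairs_mi(subset_samples(mir_norm, ids),
                            subset_samples(gene_norm, ids),
                            cfg = cfg, phenotype = ph)
    topk[[ph]] <- top_k(raw_net, k)
  }

  contrasts <- contiguous_contrasts()
  de_genes <- run_differential(gene_mat, samples, contrasts,
                               gene_thresholds, dispersion_mode)
  de_mirs <- run_differential(mir_mat, samples, contrasts,
                              mir_thresholds, dispersion_mode)

  canonical <- stats::setNames(vector("list", 4L), contrasts$test)
  for (i in seq_len(nrow(contrasts))) {
    stage <- contrasts$test[i]
    canonical[[stage]] <- opposite_sign_filter(topk[[stage]],
                                               de_genes[[contrasts$label[i]]],
                                               de_mirs[[contrasts$label[i]]])
  }

  structure(list(topk = topk, canonical = canonical, de_genes = de_genes,
                 de_mirs = de_mirs, contrasts = contrasts,
                 k = as.integer(k)),
            class = "stage_series")
}

#' @export
print.stage_series <- function(x, ...) {
  cat("<stage_series>\n topk edges:     ",
      paste(sprintf("%s=%d", names(x$topk), vapply(x$topk, nrow, 0L)),
            collapse = " "), "\n canonical edges:",
      paste(sprintf("%s=%d", names(x$canonical),
                    vapply(x$canonical, nrow, 0L)), collapse = " "), "\n")
  invisible(x)
}
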