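# Genomic co-location of co-expressed miR-gene pairs: chromosome and
# cytoband agreement plus start-position distance.

#' Annotate network edges with genomic loci and co-location flags
#'
#' Each edge gains the chromosome, cytoband and start position of both
#' endpoints, `same_chromosome` / `same_cytoband` flags (cytoband equality
#' requires chromosome equality plus band-string equality), and the
#' absolute start-position distance in base pairs, defined only when both
#' endpoints share a chromosome. Edges with an unannotated endpoint pass
#' through with `NA` loci and are counted.
#'
#' @param edges a `bipartite_network` or data.frame with `mir_id`, `gene_id`
#'   (and optionally `mi`).
#' @param annot a `feature_annotation`.
#' @return A data.frame of class `annotated_edges` with attribute
#'   `n_unannotated`.
#' @export
annotate_edges <- function(edges, annot) {
  stopifnot(inherits(annot, "feature_annotation"))
  idx_m <- match(edges$mir_id, annot$feature_id)
  idx_g <- match(edges$gene_id, annot$feature_id)
  out <- data.frame(
    mir_id = edges$mir_id, gene_id = edges$gene_id,
    mi = if ("mi" %in% names(edges)) edges$mi else NA_real_,
    mir_chromosome = annot$chromosome[idx_m],
    mir_cytoband = annot$cytoband[idx_m],
    mir_start = annot$start[idx_m],
    gene_chromosome = annot$chromosome[idx_g],
    gene_cytoband = annot$cytoband[idx_g],
    gene_start = annot$start[idx_g],
    stringsAsFactors = FALSE)
  annotated <- !is.na(idx_m) & !is.na(idx_g)
  out$same_chromosome <- ifelse(annotated,
                                out$mir_chromosome == out$gene_chromosome, NA)
  out$same_cytoband <- ifelse(annotated,
                              out$same_chromosome &
                                out$mir_cytoband == out$gene_cytoband, NA)
  out$start_distance <- ifelse(annotated & out$same_chromosome %in% TRUE,
                               abs(out$gene_start - out$mir_start), NA_integer_)
  class(out) <- c("annotated_edges", "data.frame")
  attr(out, "n_unannotated") <- sum(!annotated)
  out
}

#' Summarize chromosome / cytoband co-location of annotated edges
#'
#' Fractions are computed over edges with both endpoints annotated; an
#' empty (or fully unannotated) edge list yields zero fractions with a
#' warning.
#'
#' @param annotated an `annotated_edges` data.frame.
#' @return A list with `frac_same_chromosome`, `frac_same_cytoband`,
#'   `n_unannotated`, `n_annotated`.
#' @export
colocation_summary <- function(annotated) {
  stopifnot(inherits(annotated, "annotated_edges"))
  ok <- !is.na(annotated$same_chromosome)
  n <- sum(ok)
  if (n == 0) {
    warning("no fully annotated edges; co-location fractions set to 0")
    return(list(frac_same_chromosome = 0, frac_same_cytoband = 0,
                n_unannotated = attr(annotated, "n_unannotated") %||% 0L,
                n_annotated = 0L))
  }
  list(frac_same_chromosome = sum(annotated$same_chromosome[ok]) / n,
       frac_same_cytoband = sum(annotated$same_cytoband[ok]) / n,
       n_unannotated = attr(annotated, "n_unannotated") %||% 0L,
       n_annotated = n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
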