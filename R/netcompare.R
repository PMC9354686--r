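# Set-algebra comparison of the per-phenotype networks: UpSet-style
# exclusive intersections, uniqueness fractions, and the edge set shared
# by all tumor stages but absent from the non-tumor network.

#' Exclusive intersection counts over a collection of networks
#'
#' Edges are keyed by (mir_id, gene_id), ignoring MI scores. For every
#' non-empty subset S of the network labels, the exclusive count is the
#' number of edges present in exactly the networks of S — the quantities an
#' UpSet plot displays. Exclusive counts over all subsets sum to the size
#' of the union, and each network's total is the sum of exclusive counts
#' over the subsets containing it.
#'
#' @param nets named list of 2 to 12 `bipartite_network`s.
#' @return A data.frame of class `intersection_table` with columns
#'   `subset` (labels joined by `&`), `n_networks`, `count`, ordered by
#'   subset size then label order; per-network totals in attribute
#'   `totals`.
#' @export
intersection_counts <- function(nets) {
  if (length(nets) < 2) stop("need at least 2 networks")
  if (length(nets) > 12) stop("more than 12 networks; subsets not enumerable")
  labels <- names(nets)
  if (is.null(labels) || any(!nzchar(labels))) stop("networks must be named")
  if (anyDuplicated(labels)) stop("duplicate network labels")

  keysets <- lapply(nets, edge_keys)
  all_keys <- unique(unlist(keysets, use.names = FALSE))
  member <- vapply(keysets, function(k) all_keys %in% k,
                   logical(length(all_keys)))
  if (length(all_keys) == 1L) member <- matrix(member, nrow = 1L)
  sig <- member %*% (2^(seq_along(nets) - 1))

  n <- length(nets)
  masks <- seq_len(2^n - 1)
  in_mask <- vapply(seq_len(n), function(i) bitwAnd(masks, 2^(i - 1)) > 0,
                    logical(length(masks)))
  if (length(masks) == 1L) in_mask <- matrix(in_mask, nrow = 1L)
  subset_label <- apply(in_mask, 1L, function(z) paste(labels[z], collapse = "&"))
  subset_size <- rowSums(in_mask)
  cnt <- tabulate(match(as.vector(sig), masks), nbins = length(masks))

  ord <- order(subset_size, match(subset_label, subset_label))
  out <- data.frame(subset = subset_label[ord],
                    n_networks = subset_size[ord],
                    count = cnt[ord], stringsAsFactors = FALSE)
  class(out) <- c("intersection_table", "data.frame")
  totals <- vapply(nets, nrow, 0L)
  attr(out, "totals") <- totals
  attr(out, "labels") <- labels
  out
}

#' Edges shared by all four tumor stages but absent from the NT network
#'
#' Returns the intersection of the stage I-IV edge sets minus the NT edge
#' set. At `level = "canonical"` the stage networks are the canonical
#' (opposite-sign filtered) ones while NT — which is never canonically
#' filtered — contributes its top-K edge set.
#'
#' @param series a `stage_series`.
#' @param level `"topk"` or `"canonical"`.
#' @return A data.frame with columns `mir_id`, `gene_id`.
#' @export
tumor_shared_not_control <- function(series, level = c("topk", "canonical")) {
  level <- match.arg(level)
  stopifnot(inherits(series, "stage_series"))
  stage_nets <- if (level == "topk") series$topk[c("I", "II", "III", "IV")]
                else series$canonical
  keys <- lapply(stage_nets, edge_keys)
  shared <- Reduce(intersect, keys)
  shared <- setdiff(shared, edge_keys(series$topk$NT))
  if (!length(shared)) {
    return(data.frame(mir_id = character(0), gene_id = character(0),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(shared, "\r", fixed = TRUE)
  data.frame(mir_id = vapply(parts, `[[`, character(1), 1L),
             gene_id = vapply(parts, `[[`, character(1), 2L),
             stringsAsFactors = FALSE)
}

#' Fraction of a network's edges found in no other network
#'
#' @param net a `bipartite_network`.
#' @param others list of `bipartite_network`s to compare against.
#' @return Proportion in \[0, 1\]; an empty network yields 0 with a warning.
#' @export
uniqueness_fraction <- function(net, others) {
  stopifnot(inherits(net, "bipartite_network"))
  if (!nrow(net)) {
    warning("uniqueness of an empty network is undefined; returning 0")
    return(0)
  }
  other_keys <- unique(unlist(lapply(others, edge_keys), use.names = FALSE))
  sum(!(edge_keys(net) %in% other_keys)) / nrow(net)
}
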