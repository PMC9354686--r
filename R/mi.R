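# Bipartite mutual-information network inference.
#
# Estimator: average-tie rank transform, equal-frequency binning into B
# bins (B = max(2, floor(n^(1/3))) when "auto"), plugin entropy estimate
# over the joint histogram, and an optional Miller-Madow small-sample
# correction. The estimator is deterministic, symmetric in its arguments,
# and invariant under strictly monotone transforms of either input when
# the rank transform is on.

#' Mutual-information estimator configuration
#'
#' @param n_bins number of equal-frequency bins, or `"auto"` for
#'   `max(2, floor(n^(1/3)))`.
#' @param bias_correction apply the Miller-Madow correction
#'   `(m_occ - r_occ - c_occ + 1) / (2n)` (result floored at 0).
#' @param rank_transform replace each vector by its average-tie ranks
#'   before binning.
#' @return A list of class `mi_config`.
#' @export
mi_config <- function(n_bins = "auto", bias_correction = TRUE,
                      rank_transform = TRUE) {
  if (!identical(n_bins, "auto")) {
    if (!is.numeric(n_bins) || length(n_bins) != 1 || n_bins < 2) {
      stop("n_bins must be \"auto\" or a single number >= 2")
    }
    n_bins <- as.integer(n_bins)
  }
  structure(list(n_bins = n_bins,
                 bias_correction = isTRUE(bias_correction),
                 rank_transform = isTRUE(rank_transform)),
            class = "mi_config")
}

#' @rdname mi_config
#' @param n_samples number of samples.
#' @param cfg an `mi_config`.
#' @return `resolve_bins`: the integer bin count for `n_samples`.
#' @export
resolve_bins <- function(cfg, n_samples) {
  if (identical(cfg$n_bins, "auto")) {
    max(2L, as.integer(floor(n_samples^(1 / 3) + 1e-9)))
  } else {
    cfg$n_bins
  }
}

# Equal-frequency discretization. With the rank transform, bin(i) =
# ceiling(rank_i * B / n), so that n divisible by B with distinct values
# gives exactly n/B points per bin. Without it, bins come from quantile
# breaks with boundary ties assigned to the lower bin.
discretize_ef <- function(v, B, rank_transform = TRUE) {
  n <- length(v)
  if (rank_transform) {
    r <- rank(v, ties.method = "average")
    b <- as.integer(ceiling(r * B / n - 1e-9))
  } else {
    br <- stats::quantile(v, probs = seq(0, 1, length.out = B + 1),
                          names = FALSE, type = 7)
    inner <- br[-c(1, B + 1)]
    b <- findInterval(v, sort(unique(inner)), left.open = TRUE) + 1L
  }
  b[b < 1L] <- 1L
  b[b > B] <- as.integer(B)
  b
}

#' Plugin mutual information between two vectors (nats)
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @param cfg an [mi_config()].
#' @return Non-negative MI estimate in nats.
#' @export
mutual_information <- function(x, y, cfg = mi_config()) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 4) stop("need at least 4 paired observations")
  B <- resolve_bins(cfg, n)
  bx <- discretize_ef(x, B, cfg$rank_transform)
  by <- discretize_ef(y, B, cfg$rank_transform)
  cnt <- tabulate((bx - 1L) * B + by, nbins = B * B)
  px <- tabulate(bx, nbins = B) / n
  py <- tabulate(by, nbins = B) / n
  pxy <- cnt / n
  denom <- rep(px, each = B) * rep.int(py, B)
  occ <- pxy > 0
  mi <- sum(pxy[occ] * log(pxy[occ] / denom[occ]))
  if (cfg$bias_correction) {
    mm <- (sum(occ) - sum(px > 0) - sum(py > 0) + 1) / (2 * n)
    mi <- mi + mm
  }
  max(mi, 0)
}

#' Number of candidate miR-gene pairs
#'
#' @param n_mirs,n_genes feature counts.
#' @return `n_mirs * n_genes` as a double.
#' @export
n_candidate_pairs <- function(n_mirs, n_genes) {
  as.numeric(n_mirs) * as.numeric(n_genes)
}

#' Mutual information for every miR-gene pair within one phenotype
#'
#' Both matrices must cover the same sample set; if the sample orderings
#' differ, the gene matrix is reordered to the miRNA ordering (MI is
#' invariant to a common permutation of samples). The result has exactly
#' `n_mirs * n_genes` edges and is deterministic given inputs and config.
#'
#' @param mirs,genes `expr_matrix` objects over the same samples.
#' @param cfg an [mi_config()].
#' @param phenotype label recorded on the network.
#' @return A `bipartite_network` with `filtered = "raw"`.
#' @export
all_pairs_mi <- function(mirs, genes, cfg = mi_config(),
                         phenotype = NA_character_) {
  stopifnot(inherits(mirs, "expr_matrix"), inherits(genes, "expr_matrix"))
  sm <- sample_ids(mirs); sg <- sample_ids(genes)
  if (!setequal(sm, sg)) {
    stop("sample sets differ; offending samples: ",
         paste(union(setdiff(sm, sg), setdiff(sg, sm)), collapse = ", "))
  }
  if (!identical(sm, sg)) genes <- subset_samples(genes, sm)
  n <- length(sm)
  if (n < 4) stop("need at least 4 samples per phenotype")
  B <- resolve_bins(cfg, n)
  B2 <- B * B

  mir_bins <- t(apply(mirs$values, 1L, discretize_ef, B = B,
                      rank_transform = cfg$rank_transform))
  gene_bins <- t(apply(genes$values, 1L, discretize_ef, B = B,
                       rank_transform = cfg$rank_transform))
  n_mir <- nrow(mirs$values); n_gene <- nrow(genes$values)

  # Per-feature marginal bin probabilities (ties can make them unequal).
  pm <- t(apply(mir_bins, 1L, tabulate, nbins = B)) / n
  pg <- t(apply(gene_bins, 1L, tabulate, nbins = B)) / n
  gene_occ_bins <- rowSums(pg > 0)
  mir_occ_bins <- rowSums(pm > 0)

  # Joint cell index layout: cell c corresponds to miR bin
  # ((c-1) %/% B) + 1 and gene bin ((c-1) %% B) + 1.
  cell_mir_bin <- rep(seq_len(B), each = B)
  cell_gene_bin <- rep.int(seq_len(B), B)

  mi_mat <- matrix(0, nrow = n_mir, ncol = n_gene)
  for (i in seq_len(n_mir)) {
    offs <- (mir_bins[i, ] - 1L) * B
    codes <- sweep(gene_bins, 2L, offs, `+`) # n_gene x n, values in 1..B^2
    counts <- matrix(0L, nrow = n_gene, ncol = B2)
    for (cc in seq_len(B2)) counts[, cc] <- rowSums(codes == cc)
    pxy <- counts / n
    denom <- sweep(pg[, cell_gene_bin, drop = FALSE], 2L,
                   pm[i, cell_mir_bin], `*`)
    term <- pxy * log(pxy / denom)
    term[pxy == 0] <- 0
    mi_i <- rowSums(term)
    if (cfg$bias_correction) {
      mm <- (rowSums(counts > 0) - mir_occ_bins[i] - gene_occ_bins + 1) / (2 * n)
      mi_i <- mi_i + mm
    }
    mi_mat[i, ] <- pmax(mi_i, 0)
  }

  bipartite_network(
    mir_id = rep(feature_ids(mirs), each = n_gene),
    gene_id = rep.int(feature_ids(genes), n_mir),
    mi = as.vector(t(mi_mat)),
    phenotype = phenotype, k = NA_integer_, filtered = "raw")
}

#' Retain the K highest-MI edges
#'
#' Edges are ordered by MI descending with ties broken by miR id then gene
#' id ascending (C-locale radix order), so the retained set is reproducible
#' across platforms and invariant to the input edge ordering.
#'
#' @param net a raw `bipartite_network`.
#' @param k number of edges to keep.
#' @return A `bipartite_network` with `filtered = "topk"`.
#' @export
top_k <- function(net, k = 100000) {
  stopifnot(inherits(net, "bipartite_network"))
  if (!identical(attr(net, "filtered"), "raw")) {
    stop("top_k expects a raw (unfiltered) network")
  }
  if (!is.numeric(k) || length(k) != 1 || k <= 0) stop("k must be > 0")
  ord <- order(-net$mi, net$mir_id, net$gene_id, method = "radix")
  keep <- ord[seq_len(min(as.integer(k), nrow(net)))]
  bipartite_network(net$mir_id[keep], net$gene_id[keep], net$mi[keep],
                    phenotype = attr(net, "phenotype"),
                    k = as.integer(k), filtered = "topk")
}
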