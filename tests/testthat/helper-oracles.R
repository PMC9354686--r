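# Independent brute-force oracles, written separately from the package
# implementations they check.

# Plugin MI by explicit joint-histogram construction with nested loops.
# Discretization re-derived from first principles: equal-frequency bins of
# the average-tie ranks, bin = ceiling(rank * B / n).
oracle_mi <- function(x, y, B, bias_correction = FALSE) {
  n <- length(x)
  bin_of <- function(v) {
    r <- rank(v, ties.method = "average")
    pmin(pmax(as.integer(ceiling(r * B / n - 1e-9)), 1L), as.integer(B))
  }
  bx <- bin_of(x); by <- bin_of(y)
  joint <- matrix(0, B, B)
  for (i in seq_len(n)) joint[bx[i], by[i]] <- joint[bx[i], by[i]] + 1
  px <- rowSums(joint) / n
  py <- colSums(joint) / n
  mi <- 0
  for (a in seq_len(B)) for (b in seq_len(B)) {
    p <- joint[a, b] / n
    if (p > 0) mi <- mi + p * log(p / (px[a] * py[b]))
  }
  if (bias_correction) {
    mi <- mi + (sum(joint > 0) - sum(px > 0) - sum(py > 0) + 1) / (2 * n)
  }
  max(mi, 0)
}

# Benjamini-Hochberg step-up applied literally: sort, take p * m / rank,
# enforce monotonicity from the largest rank down, cap at 1.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Exclusive intersection counts by explicit subset enumeration: for every
# non-empty subset of networks, count keys present in all of its members
# and in none of the others.
oracle_intersections <- function(keysets) {
  labels <- names(keysets)
  n <- length(keysets)
  out <- list()
  for (mask in seq_len(2^n - 1)) {
    inset <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    keys <- Reduce(intersect, keysets[inset])
    for (j in which(!inset)) keys <- setdiff(keys, keysets[[j]])
    out[[paste(labels[inset], collapse = "&")]] <- length(keys)
  }
  out
}

# Small random bipartite network for set-algebra tests.
random_network <- function(n_edges, phenotype = "I", mir_pool = 6, gene_pool = 8) {
  pairs <- expand.grid(mir = sprintf("m%d", seq_len(mir_pool)),
                       gene = sprintf("g%d", seq_len(gene_pool)),
                       stringsAsFactors = FALSE)
  pick <- sample(nrow(pairs), min(n_edges, nrow(pairs)))
  bipartite_network(pairs$mir[pick], pairs$gene[pick],
                    stats::runif(length(pick)), phenotype = phenotype)
}

# NB count matrix helper for DE tests.
nb_matrix <- function(n_features, n_samples, mu, dispersion = 0.1,
                      prefix = "s") {
  m <- matrix(stats::rnbinom(n_features * n_samples, mu = rep(mu, n_samples),
                             size = 1 / dispersion),
              nrow = n_features,
              dimnames = list(sprintf("f%04d", seq_len(n_features)),
                              sprintf("%s%03d", prefix, seq_len(n_samples))))
  expression_matrix(m, "gene")
}

# Classified DE table built directly (bypasses the test machinery) for
# filter-logic tests.
manual_de <- function(ids, status, log2fc = NULL, contrast = "NT-I") {
  df <- data.frame(feature_id = ids,
                   base_mean_ref = 100, base_mean_test = 100,
                   log2fc = if (is.null(log2fc))
                     ifelse(status == "over", 2, ifelse(status == "under", -2, 0))
                   else log2fc,
                   se = 0.1, p_raw = ifelse(status == "ns", 0.5, 1e-10),
                   p_adj = ifelse(status == "ns", 0.9, 1e-8),
                   stringsAsFactors = FALSE)
  df$status <- factor(status, levels = c("over", "under", "ns"))
  class(df) <- c("de_result", "data.frame")
  attr(df, "contrast") <- contrast
  df
}
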