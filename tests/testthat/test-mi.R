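test_that("MI of a constant vector is zero", {
  cfg <- mi_config(n_bins = 3)
  expect_equal(mutual_information(rnorm(20), rep(1, 20), cfg), 0)
})

test_that("MI(x, x) equals ln(B) when B divides n", {
  for (B in c(2, 3, 5)) {
    for (n in c(B * 4, B * 10)) {
      x <- sample(seq_len(n)) # n distinct values
      cfg <- mi_config(n_bins = B, bias_correction = FALSE)
      expect_equal(mutual_information(x, x, cfg), log(B), tolerance = 1e-12)
    }
  }
})

test_that("hand-computed 2x2 diagonal joint gives ln 2", {
  # four points on a diagonal, two bins: joint counts [[2,0],[0,2]]
  cfg <- mi_config(n_bins = 2, bias_correction = FALSE)
  expect_equal(mutual_information(c(1, 2, 3, 4), c(10, 20, 30, 40), cfg),
               log(2), tolerance = 1e-12)
})

test_that("MI is symmetric, non-negative and monotone-invariant", {
  set.seed(17)
  cfg <- mi_config()
  for (rep in 1:20) {
    n <- sample(8:80, 1)
    x <- rnorm(n); y <- x * runif(1, -2, 2) + rnorm(n)
    expect_equal(mutual_information(x, y, cfg),
                 mutual_information(y, x, cfg), tolerance = 1e-12)
    expect_gte(mutual_information(x, y, cfg), 0)
    # strictly increasing transforms leave rank-based MI unchanged
    expect_equal(mutual_information(exp(x), y, cfg),
                 mutual_information(x, y, cfg), tolerance = 1e-12)
    expect_equal(mutual_information(x, 1 / (1 + exp(-y)), cfg),
                 mutual_information(x, y, cfg), tolerance = 1e-12)
    expect_equal(mutual_information(x^3, y^3, cfg),
                 mutual_information(x, y, cfg), tolerance = 1e-12)
  }
  expect_error(mutual_information(1:5, 1:4, cfg), "equal length")
  expect_error(mutual_information(1:3, 1:3, cfg), "at least 4")
})

test_that("plugin MI matches the brute-force oracle", {
  set.seed(23)
  for (rep in 1:100) {
    n <- sample(4:100, 1)
    B <- sample(2:6, 1)
    x <- rnorm(n); y <- rnorm(n) + sample(c(-1, 0, 1), 1) * x
    for (bc in c(FALSE, TRUE)) {
      cfg <- mi_config(n_bins = B, bias_correction = bc)
      expect_equal(mutual_information(x, y, cfg), oracle_mi(x, y, B, bc),
                   tolerance = 1e-12)
    }
  }
})

test_that("auto bin rule is max(2, floor(n^(1/3)))", {
  cfg <- mi_config()
  expect_equal(resolve_bins(cfg, 7), 2L)
  expect_equal(resolve_bins(cfg, 27), 3L)
  expect_equal(resolve_bins(cfg, 40), 3L)
  expect_equal(resolve_bins(cfg, 64), 4L)
  expect_equal(resolve_bins(cfg, 1000), 10L)
})

test_that("all-pairs MI agrees with the scalar estimator and is order-free", {
  set.seed(29)
  n <- 20
  mirs <- expression_matrix(
    matrix(rnorm(5 * n, 100, 20), nrow = 5,
           dimnames = list(sprintf("m%d", 1:5), sprintf("s%02d", 1:n))),
    "miR")
  genes <- expression_matrix(
    matrix(rnorm(7 * n, 100, 20), nrow = 7,
           dimnames = list(sprintf("g%d", 1:7), sprintf("s%02d", 1:n))),
    "gene")
  cfg <- mi_config()
  net <- all_pairs_mi(mirs, genes, cfg, phenotype = "NT")
  expect_equal(nrow(net), 35L)
  for (i in sample(nrow(net), 10)) {
    expect_equal(net$mi[i],
                 mutual_information(mirs$values[net$mir_id[i], ],
                                    genes$values[net$gene_id[i], ], cfg),
                 tolerance = 1e-12)
  }
  # permuting samples identically in both matrices leaves MI unchanged
  perm <- sample(n)
  net2 <- all_pairs_mi(subset_samples(mirs, sample_ids(mirs)[perm]),
                       subset_samples(genes, sample_ids(genes)[perm]),
                       cfg, phenotype = "NT")
  expect_equal(net2$mi, net$mi, tolerance = 1e-12)
  # mismatched sample sets are a hard error naming the offenders
  bad <- expression_matrix(
    matrix(1:14, nrow = 7,
           dimnames = list(sprintf("g%d", 1:7), c("sX", "sY"))), "gene")
  expect_error(all_pairs_mi(mirs, bad), "sX")
})

test_that("candidate pair count matches the bipartite product", {
  expect_equal(n_candidate_pairs(2, 3), 6)
  expect_equal(n_candidate_pairs(275, 16227), 4462425)
})

test_that("top_k keeps the K best edges with deterministic tie-breaks", {
  net <- bipartite_network(c("m2", "m1", "m1", "m3", "m2"),
                           c("gB", "gC", "gA", "gA", "gA"),
                           c(3, 2, 2, 1, 0), phenotype = "I")
  kept <- top_k(net, 2)
  # score 3 first, then the lexicographically smaller of the two score-2 edges
  expect_equal(kept$mir_id, c("m2", "m1"))
  expect_equal(kept$gene_id, c("gB", "gA"))
  expect_equal(attr(kept, "filtered"), "topk")

  # k >= |edges|: unchanged content, only the filtered flag moves
  all_kept <- top_k(net, 10)
  expect_equal(nrow(all_kept), 5L)
  expect_setequal(paste(all_kept$mir_id, all_kept$gene_id),
                  paste(net$mir_id, net$gene_id))

  # invariance to input ordering
  perm <- sample(5)
  shuffled <- bipartite_network(net$mir_id[perm], net$gene_id[perm],
                                net$mi[perm], phenotype = "I")
  expect_equal(as.data.frame(top_k(shuffled, 3)), as.data.frame(top_k(net, 3)))

  expect_error(top_k(net, 0), "k must be > 0")
  expect_error(top_k(kept, 2), "raw")
})
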