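make_mat <- function(values, ids = sprintf("g%d", seq_len(nrow(values)))) {
  dimnames(values) <- list(ids, sprintf("s%d", seq_len(ncol(values))))
  expression_matrix(values, "gene")
}

full_annot <- function(ids) {
  feature_annotation(ids, "1", "p11.1", seq_along(ids) * 1000,
                     seq_along(ids) * 1000 + 100)
}

test_that("feature filters apply the zero-fraction and mean rules strictly", {
  m <- make_mat(rbind(c(0, 0, 0, 10),    # zero fraction 0.75 -> removed
                      c(12, 8, 15, 9),   # mean 11 -> kept
                      c(3, 2, 4, 2),     # mean 2.75 -> removed
                      c(0, 0, 20, 20)))  # zero fraction exactly 0.5 -> kept
  res <- filter_features(m, full_annot(feature_ids(m)))
  expect_setequal(feature_ids(res$matrix), c("g2", "g4"))
  rem <- res$report$removed_ids
  expect_equal(rem$reason[rem$feature_id == "g1"], "zeros")
  expect_equal(rem$reason[rem$feature_id == "g3"], "low_mean")
})

test_that("unannotated features are removed first", {
  m <- make_mat(rbind(c(0, 0, 0, 0), c(100, 100, 100, 100)))
  annot <- full_annot("g2")
  res <- filter_features(m, annot)
  # g1 fails both the annotation and zero filters; the annotation reason wins
  expect_equal(res$report$removed_ids$reason, "unannotated")
  expect_equal(res$report$n_removed_zeros, 0L)
})

test_that("filter report accounting identity holds on random matrices", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    m <- make_mat(matrix(rnbinom(n * 6, mu = 2^runif(n * 6, 0, 8), size = 5),
                         nrow = n))
    annot <- full_annot(sample(feature_ids(m), ceiling(0.8 * n)))
    res <- tryCatch(filter_features(m, annot), error = function(e) NULL)
    if (is.null(res)) next # everything filtered out is a legal hard error
    rep_ <- res$report
    expect_equal(rep_$n_input, rep_$n_kept + rep_$n_removed_unannotated +
                   rep_$n_removed_zeros + rep_$n_removed_low_mean)
    expect_equal(nrow(rep_$removed_ids), rep_$n_input - rep_$n_kept)
    expect_false(anyDuplicated(rep_$removed_ids$feature_id) > 0)
    # idempotence
    res2 <- filter_features(res$matrix, annot)
    expect_identical(res2$matrix$values, res$matrix$values)
    expect_equal(res2$report$n_kept, res2$report$n_input)
  }
})

test_that("filtering everything is a hard error", {
  m <- make_mat(rbind(c(1, 0, 0, 0)))
  expect_error(filter_features(m, full_annot("g1")), "no features left")
})

test_that("median-of-ratios size factors have their closed-form values", {
  m <- make_mat(rbind(c(10, 10), c(50, 50), c(7, 7)))
  expect_equal(unname(size_factors(m)), c(1, 1))

  set.seed(7)
  a <- sample(5:100, 12)
  m2 <- make_mat(cbind(a, 2 * a))
  f <- size_factors(m2)
  expect_equal(unname(f[2] / f[1]), 2, tolerance = 1e-12)

  single <- make_mat(matrix(c(4, 9, 25), ncol = 1))
  expect_equal(unname(size_factors(single)), 1)
})

test_that("size factors require an all-positive reference feature", {
  m <- make_mat(rbind(c(0, 5), c(5, 0)))
  expect_error(size_factors(m), "positive in every sample")
})

test_that("normalization divides columns and preserves within-sample ranks", {
  set.seed(13)
  m <- make_mat(matrix(rnbinom(60, mu = 50, size = 5) + 1, nrow = 10))
  f <- c(1, 2, 0.5, 1, 4, 1)
  norm <- normalize_counts(m, f)
  expect_equal(norm$values[, 2], m$values[, 2] / 2)
  expect_equal(norm$units, "normalized")
  for (j in seq_len(ncol(m$values))) {
    expect_equal(rank(norm$values[, j]), rank(m$values[, j]))
  }
  expect_error(normalize_counts(m, f[-1]), "length")
  expect_error(normalize_counts(m, replace(f, 1, 0)), "positive")
})

test_that("covariate correction equalizes bin medians", {
  # two bins with medians m and 2m: after correction both match the global median
  vals <- rbind(c(10, 10, 10, 10), c(10, 10, 10, 10),
                c(20, 20, 20, 20), c(20, 20, 20, 20))
  m <- make_mat(vals)
  corrected <- covariate_correct(m, c(1, 2, 10, 11), n_bins = 2)
  med1 <- median(corrected$values[1:2, ])
  med2 <- median(corrected$values[3:4, ])
  expect_equal(med1, med2)
  expect_equal(med1, median(m$values))

  # constant covariate: single effective bin, values unchanged up to the
  # global-median rescale of 1
  same <- covariate_correct(m, rep(1, 4), n_bins = 1)
  expect_equal(same$values, m$values)

  expect_warning(covariate_correct(m, c(1, 2, 3, 4), n_bins = 10), "reduced")
  expect_error(covariate_correct(m, c(1, 2)), "length")
})
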