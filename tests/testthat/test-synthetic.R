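test_that("the default study configuration validates and is reproducible", {
  cfg <- default_study(seed = 9)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_genes, 300L)
  expect_equal(cfg$n_mirs, 50L)
  expect_equal(unname(cfg$samples_per_phenotype),
               c(40, 60, 40, 40, 40)) # NT smaller than stage I
  expect_lt(cfg$samples_per_phenotype[["NT"]], cfg$samples_per_phenotype[["I"]])
  expect_equal(nrow(cfg$coupling_plan), 30L)
  expect_equal(sum(cfg$coupling_plan$sign == -1), 25L)
  neg_de <- cfg$coupling_plan$group %in% c("persistent_mir", "stage_specific")
  expect_equal(sum(neg_de), 20L)
  expect_true(all(cfg$coupling_plan$strength[neg_de] == 0.8))
})

test_that("identical config and seed give identical outputs", {
  a <- generate_synthetic(default_study(seed = 123))
  b <- generate_synthetic(default_study(seed = 123))
  expect_identical(a$genes$values, b$genes$values)
  expect_identical(a$mirs$values, b$mirs$values)
  expect_identical(as.data.frame(a$annotation), as.data.frame(b$annotation))
  expect_identical(a$truth$couplings, b$truth$couplings)
  c <- generate_synthetic(default_study(seed = 124))
  expect_false(identical(a$genes$values, c$genes$values))
})

test_that("planted fold changes are realized within sampling error", {
  set.seed(201)
  cfg <- simulation_config(
    n_genes = 50, n_mirs = 5,
    samples_per_phenotype = c(NT = 60, I = 60, II = 10, III = 10, IV = 10),
    de_plan = data.frame(contrast = "NT-I", kind = "gene",
                         feature_id = "gene001", log2_effect = 2,
                         stringsAsFactors = FALSE),
    seed = 201)
  data <- generate_synthetic(cfg)
  sf <- size_factors(data$genes)
  norm <- normalize_counts(data$genes, sf)
  nt <- samples_of(data$samples, "NT"); st1 <- samples_of(data$samples, "I")
  ratio <- log2(mean(norm$values["gene001", st1]) /
                mean(norm$values["gene001", nt]))
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.4)
})

test_that("negative couplings induce negative rank correlation near rho", {
  data <- generate_synthetic(default_study(seed = 7))
  cp <- data$truth$couplings
  neg <- cp[cp$group == "stage_specific", ]
  rc <- vapply(seq_len(nrow(neg)), function(i) {
    ids <- samples_of(data$samples, neg$phenotypes[i])
    cor(data$mirs$values[neg$mir[i], ids], data$genes$values[neg$gene[i], ids],
        method = "spearman")
  }, numeric(1))
  expect_true(all(rc > -0.95 & rc < -0.5))

  # uncoupled pairs center on zero
  set.seed(7)
  unc_m <- setdiff(feature_ids(data$mirs), cp$mir)[1:10]
  unc_g <- setdiff(feature_ids(data$genes), cp$gene)[1:10]
  ids <- samples_of(data$samples, "II")
  rc0 <- mapply(function(m, g)
    cor(data$mirs$values[m, ids], data$genes$values[g, ids],
        method = "spearman"), unc_m, unc_g)
  expect_lt(abs(median(rc0)), 0.2)
})

test_that("NB marginals match their moments for unplanted features", {
  cfg <- simulation_config(n_genes = 200, n_mirs = 5,
                           samples_per_phenotype = c(NT = 200, I = 5, II = 5,
                                                     III = 5, IV = 5),
                           dispersion = 0.2, library_size_cv = 0,
                           seed = 31)
  data <- generate_synthetic(cfg)
  ids <- samples_of(data$samples, "NT")
  v <- data$genes$values[, ids]
  mu_hat <- rowMeans(v)
  var_hat <- apply(v, 1, var)
  # var = mu + phi mu^2; regress the quadratic excess on mu^2
  phi_hat <- sum((var_hat - mu_hat) * mu_hat^2) / sum(mu_hat^4)
  expect_gt(phi_hat, 0.12)
  expect_lt(phi_hat, 0.30)
})

test_that("infeasible plans and bad couplings are rejected", {
  base <- list(n_genes = 10, n_mirs = 3,
               samples_per_phenotype = c(NT = 5, I = 5, II = 5, III = 5, IV = 5))
  expect_error(simulation_config(
    n_genes = 2, n_mirs = 3,
    samples_per_phenotype = base$samples_per_phenotype,
    de_plan = data.frame(contrast = "NT-I", kind = "gene",
                         feature_id = c("gene001", "gene002", "gene003"),
                         log2_effect = 2)), "unknown feature")
  expect_error(simulation_config(
    n_genes = 10, n_mirs = 3,
    samples_per_phenotype = base$samples_per_phenotype,
    coupling_plan = data.frame(mir = "mir01", gene = "gene001", sign = -1L,
                               strength = 1.5, phenotypes = "I",
                               group = "x")), "strength")
  expect_error(simulation_config(
    n_genes = 10, n_mirs = 3,
    samples_per_phenotype = base$samples_per_phenotype,
    de_plan = data.frame(contrast = "NT-I", kind = "gene",
                         feature_id = "gene001", log2_effect = 0)),
    "non-zero")
})
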