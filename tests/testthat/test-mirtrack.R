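# Build a minimal stage_series by hand so persistence logic can be tested
# against known inputs without running the whole pipeline.
manual_series <- function(mir_status_per_contrast, mir_lfc_per_contrast,
                          stage_targets) {
  contrasts <- contiguous_contrasts()
  de_mirs <- setNames(lapply(seq_len(4), function(i) {
    manual_de(names(mir_status_per_contrast[[i]]),
              unname(mir_status_per_contrast[[i]]),
              log2fc = unname(mir_lfc_per_contrast[[i]]),
              contrast = contrasts$label[i])
  }), contrasts$label)
  de_genes <- setNames(lapply(seq_len(4), function(i) {
    genes <- unique(unlist(stage_targets))
    if (!length(genes)) genes <- "placeholder"
    manual_de(genes, rep("over", length(genes)), contrast = contrasts$label[i])
  }), contrasts$label)
  canonical <- setNames(lapply(seq_len(4), function(i) {
    tg <- stage_targets[[i]]
    if (!length(tg)) return(bipartite_network(phenotype = contrasts$test[i],
                                              filtered = "canonical"))
    bipartite_network(rep("mirP", length(tg)), tg, seq_along(tg) / 10,
                      phenotype = contrasts$test[i], filtered = "canonical")
  }), contrasts$test)
  structure(list(topk = list(), canonical = canonical, de_genes = de_genes,
                 de_mirs = de_mirs, contrasts = contrasts, k = 10L),
            class = "stage_series")
}

test_that("a miR significant in all four contrasts is persistent, sign flips allowed", {
  # trajectory shaped like the motivating exemplar: under, under, over, under
  lfc <- c(-1.322, -0.5326, 0.9033, -0.7065)
  series <- manual_series(
    lapply(1:4, function(i) c(mirP = ifelse(lfc[i] > 0, "over", "under"),
                              mirQ = "ns")),
    lapply(1:4, function(i) c(mirP = lfc[i], mirQ = 0)),
    list(c("g1", "g2"), "g2", "g3", character(0)))
  trajs <- persistent_de_mirs(series)
  expect_named(trajs, "mirP")
  expect_equal(trajs$mirP$contrasts$log2fc, lfc)
  expect_equal(as.character(trajs$mirP$contrasts$status),
               c("under", "under", "over", "under"))
})

test_that("one ns contrast breaks persistence", {
  series <- manual_series(
    list(c(mirP = "over"), c(mirP = "over"), c(mirP = "ns"), c(mirP = "over")),
    list(c(mirP = 2), c(mirP = 2), c(mirP = 0.1), c(mirP = 2)),
    list(character(0), character(0), character(0), character(0)))
  expect_length(persistent_de_mirs(series), 0L)
})

test_that("persistent miRs with empty canonical networks keep empty target sets", {
  series <- manual_series(
    lapply(1:4, function(i) c(mirP = "over")),
    lapply(1:4, function(i) c(mirP = 2)),
    list(character(0), character(0), character(0), character(0)))
  trajs <- persistent_de_mirs(series)
  expect_named(trajs, "mirP")
  expect_equal(vapply(trajs$mirP$targets, nrow, 0L),
               c(I = 0L, II = 0L, III = 0L, IV = 0L))
})

test_that("target turnover computes gains and losses by set difference", {
  series <- manual_series(
    lapply(1:4, function(i) c(mirP = "over")),
    lapply(1:4, function(i) c(mirP = 2)),
    list(c("g1", "g2"), "g2", "g3", character(0)))
  tt <- target_turnover(persistent_de_mirs(series)$mirP)
  expect_equal(tt$n_targets, c(2L, 1L, 1L, 0L))
  expect_equal(tt$n_gained, c(2L, 0L, 1L, 0L))
  expect_equal(tt$n_lost, c(0L, 1L, 1L, 1L))

  # identical target sets: zero turnover after the first stage
  same <- manual_series(
    lapply(1:4, function(i) c(mirP = "over")),
    lapply(1:4, function(i) c(mirP = 2)),
    rep(list(c("g1", "g2")), 4))
  tt2 <- target_turnover(persistent_de_mirs(same)$mirP)
  expect_equal(tt2$n_gained, c(2L, 0L, 0L, 0L))
  expect_equal(tt2$n_lost, rep(0L, 4))
})

test_that("a many-then-one target profile is reported faithfully", {
  # 60 targets in stage I, then a single distinct target per later stage
  series <- manual_series(
    lapply(1:4, function(i) c(mirP = "under")),
    lapply(1:4, function(i) c(mirP = -1)),
    list(sprintf("g%02d", 1:60), "GALNTL6", "WNK2", "IGF2BP2"))
  tt <- target_turnover(persistent_de_mirs(series)$mirP)
  expect_equal(tt$n_targets, c(60L, 1L, 1L, 1L))
})

test_that("reported targets always come from the stage canonical networks", {
  set.seed(81)
  data <- generate_synthetic(default_study(seed = 81))
  series <- build_stage_series(data$genes, data$mirs, data$samples, k = 336)
  trajs <- persistent_de_mirs(series)
  for (traj in trajs) {
    for (st in names(traj$targets)) {
      net <- series$canonical[[st]]
      expect_true(all(traj$targets[[st]]$gene_id %in%
                        net$gene_id[net$mir_id == traj$mir_id]))
    }
  }
})

test_that("the planted persistent miR and its stage-varying targets are recovered", {
  set.seed(3)
  data <- generate_synthetic(default_study(seed = 3))
  series <- build_stage_series(data$genes, data$mirs, data$samples, k = 336)
  trajs <- persistent_de_mirs(series)
  expect_named(trajs, "mir01")
  planted <- data$truth$couplings[data$truth$couplings$group == "persistent_mir", ]
  for (i in seq_len(nrow(planted))) {
    st <- planted$phenotypes[i]
    expect_true(planted$gene[i] %in% trajs$mir01$targets[[st]]$gene_id)
  }
  # trajectory table is flat and covers all four stages
  tab <- trajectory_table(trajs)
  expect_setequal(unique(tab$stage), c("I", "II", "III", "IV"))
})
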