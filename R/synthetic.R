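# Synthetic paired gene/miR count data across the five ordered phenotypes
# (NT, I, II, III, IV) with planted stage-wise differential expression,
# planted coupled miR-gene pairs (shared latent factor with sign-controlled
# loadings), planted genomic coordinates, and a complete truth table.
#
# Counts are negative binomial with log-normal library-size variation.
# Stage effects are multiplicative on the mean and cumulative along the
# stage order, so a transition effect planted for contrast (s-1, s)
# persists into all later stages. A coupled pair shares a per-sample
# latent z ~ N(0,1) in its active phenotypes: the gene mean is scaled by
# exp(+lambda*z - lambda^2/2) and the miR mean by
# exp(sign*lambda*z - lambda^2/2), with lambda = COUPLING_KAPPA * rho.
# The mean-correction term keeps planted fold changes unbiased.

# Latent-loading calibration: lambda = 0.85 * rho makes the induced rank
# correlation magnitude approximately rho for NB dispersion ~0.1 at the
# planted mean scale (shared variance lambda^2 against ~0.11 residual
# log-scale variance).
COUPLING_KAPPA <- 0.85

#' Simulation configuration
#'
#' @param n_genes,n_mirs feature counts (ids `gene001`..., `mir01`...).
#' @param samples_per_phenotype named integer vector over NT, I, II, III, IV.
#' @param baseline_log2_range log2 range of baseline mean counts for
#'   unplanted features.
#' @param planted_baseline_log2_range log2 range for features referenced by
#'   the DE or coupling plan (kept away from the filtering floor).
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param library_size_cv log-normal sigma of per-sample library factors.
#' @param de_plan data.frame with columns `contrast` (contiguous label),
#'   `kind` (`gene`/`miR`), `feature_id`, `log2_effect` (non-zero).
#' @param coupling_plan data.frame with columns `mir`, `gene`, `sign`
#'   (+1/-1), `strength` (rho in (0,1)), `phenotypes` (comma-joined active
#'   phenotype labels), `group` (free-text class label).
#' @param same_cytoband_fraction fraction of coupled pairs placed on the
#'   same cytoband; honored exactly (to rounding) within each coupling
#'   `group`.
#' @param n_chromosomes chromosomes available for placement.
#' @param seed integer RNG seed; fixed seed gives byte-identical output.
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(n_genes, n_mirs, samples_per_phenotype,
                              baseline_log2_range = c(4, 10),
                              planted_baseline_log2_range = c(6, 9),
                              dispersion = 0.1, library_size_cv = 0.15,
                              de_plan = NULL, coupling_plan = NULL,
                              same_cytoband_fraction = 0.5,
                              n_chromosomes = 22, seed = 1L) {
  stopifnot(n_genes > 0, n_mirs > 0, dispersion > 0, library_size_cv >= 0,
            n_chromosomes >= 1,
            same_cytoband_fraction >= 0, same_cytoband_fraction <= 1)
  if (!all(PHENOTYPE_LEVELS %in% names(samples_per_phenotype))) {
    stop("samples_per_phenotype must name all of: ",
         paste(PHENOTYPE_LEVELS, collapse = ", "))
  }
  if (any(samples_per_phenotype <= 0)) stop("sample counts must be > 0")
  gene_ids <- sprintf("gene%03d", seq_len(n_genes))
  mir_ids <- sprintf("mir%02d", seq_len(n_mirs))

  if (is.null(de_plan)) {
    de_plan <- data.frame(contrast = character(0), kind = character(0),
                          feature_id = character(0), log2_effect = numeric(0),
                          stringsAsFactors = FALSE)
  }
  if (nrow(de_plan)) {
    if (any(de_plan$log2_effect == 0)) stop("DE effect sizes must be non-zero")
    if (!all(de_plan$contrast %in% contiguous_contrasts()$label)) {
      stop("de_plan contrasts must be contiguous contrast labels")
    }
    pool <- ifelse(de_plan$kind == "gene", list(gene_ids), list(mir_ids))
    ok <- mapply(function(id, p) id %in% p, de_plan$feature_id, pool)
    if (!all(ok)) {
      stop("de_plan references unknown feature(s): ",
           paste(de_plan$feature_id[!ok], collapse = ", "))
    }
    for (kind in c("gene", "miR")) {
      n_avail <- if (kind == "gene") n_genes else n_mirs
      tab <- table(de_plan$contrast[de_plan$kind == kind])
      if (any(tab > n_avail)) {
        stop("infeasible plan: more DE ", kind, "s than features")
      }
    }
  }
  if (is.null(coupling_plan)) {
    coupling_plan <- data.frame(mir = character(0), gene = character(0),
                                sign = integer(0), strength = numeric(0),
                                phenotypes = character(0), group = character(0),
                                stringsAsFactors = FALSE)
  }
  if (nrow(coupling_plan)) {
    if (!all(coupling_plan$mir %in% mir_ids) ||
        !all(coupling_plan$gene %in% gene_ids)) {
      stop("coupling_plan references unknown feature(s)")
    }
    if (!all(coupling_plan$sign %in% c(-1L, 1L))) stop("coupling sign must be +1 or -1")
    if (any(coupling_plan$strength <= 0) || any(coupling_plan$strength >= 1)) {
      stop("coupling strength must lie in (0, 1)")
    }
    phs <- strsplit(coupling_plan$phenotypes, ",", fixed = TRUE)
    if (!all(unlist(phs) %in% PHENOTYPE_LEVELS)) {
      stop("coupling_plan active phenotypes must be NT, I, II, III or IV")
    }
    if (is.null(coupling_plan$group)) coupling_plan$group <- "coupling"
  }

  structure(list(
    n_genes = as.integer(n_genes), n_mirs = as.integer(n_mirs),
    gene_ids = gene_ids, mir_ids = mir_ids,
    samples_per_phenotype = samples_per_phenotype[PHENOTYPE_LEVELS],
    baseline_log2_range = baseline_log2_range,
    planted_baseline_log2_range = planted_baseline_log2_range,
    dispersion = dispersion, library_size_cv = library_size_cv,
    de_plan = de_plan, coupling_plan = coupling_plan,
    same_cytoband_fraction = same_cytoband_fraction,
    n_chromosomes = as.integer(n_chromosomes),
    seed = as.integer(seed)), class = "sim_config")
}

#' The canonical desk-scale study configuration
#'
#' 300 genes x 50 miRNAs over phenotype sample sizes
#' NT=40, I=60, II=40, III=40, IV=40 (stage I largest, echoing the
#' imbalance of tumor-stage cohorts), NB dispersion 0.1. Planted structure:
#'
#' * one persistent miR (`mir01`), differentially expressed in all four
#'   contiguous contrasts with sign pattern under/under/over/under, coupled
#'   to a different target gene in each stage (negative coupling, active in
#'   that stage only);
#' * 16 further stage-specific negative couplings (4 per stage, two per
#'   orientation) whose endpoints are planted DE with opposite signs in
#'   the matching contiguous contrast;
#' * per contrast, 2 free DE miRs and 4 free DE genes without couplings;
#' * 5 tumor-only persistent negative couplings active in stages I-IV but
#'   not NT (endpoints not DE);
#' * 5 positive couplings active in every phenotype;
#' * 50% of coupled pairs placed on the same cytoband.
#'
#' @param seed RNG seed carried in the config.
#' @return A `sim_config`.
#' @export
default_study <- function(seed = 1L) {
  labels <- contiguous_contrasts()$label # NT-I, I-II, II-III, III-IV

  de <- list()
  cp <- list()

  # Persistent miR mir01: DE in every contiguous contrast, one fresh target
  # gene per stage (gene001..gene004), negative coupling active in that
  # stage only. Target DE sign is opposite to the miR's transition sign.
  # Effects large enough that the Wald test clears p < 1e-5 in all four
  # contrasts despite the extra variance the miR's own couplings induce.
  mir_eff <- c(-2.5, -2.0, 2.0, -2.0)
  for (i in 1:4) {
    tgt <- sprintf("gene%03d", i)
    de[[length(de) + 1L]] <- data.frame(
      contrast = labels[i], kind = c("miR", "gene"),
      feature_id = c("mir01", tgt),
      log2_effect = c(mir_eff[i], ifelse(mir_eff[i] < 0, 2, -2)),
      stringsAsFactors = FALSE)
    cp[[length(cp) + 1L]] <- data.frame(
      mir = "mir01", gene = tgt, sign = -1L, strength = 0.8,
      phenotypes = PHENOTYPE_LEVELS[i + 1], group = "persistent_mir",
      stringsAsFactors = FALSE)
  }

  # Stage-specific negative couplings: 4 per stage, miRs mir02..mir17,
  # genes gene005..gene020; two miR-over/gene-under and two
  # miR-under/gene-over per stage.
  for (i in 1:4) {
    for (j in 1:4) {
      mir <- sprintf("mir%02d", 1 + (i - 1) * 4 + j)
      gene <- sprintf("gene%03d", 4 + (i - 1) * 4 + j)
      mir_sign <- if (j <= 2) 1 else -1
      de[[length(de) + 1L]] <- data.frame(
        contrast = labels[i], kind = c("miR", "gene"),
        feature_id = c(mir, gene),
        log2_effect = c(1.5 * mir_sign, -2 * mir_sign),
        stringsAsFactors = FALSE)
      cp[[length(cp) + 1L]] <- data.frame(
        mir = mir, gene = gene, sign = -1L, strength = 0.8,
        phenotypes = PHENOTYPE_LEVELS[i + 1], group = "stage_specific",
        stringsAsFactors = FALSE)
    }
  }

  # Free (uncoupled) DE features: per contrast 1 miR up + 1 miR down
  # (mir18..mir25) and 2 genes up + 2 genes down (gene021..gene036).
  for (i in 1:4) {
    mirs <- sprintf("mir%02d", 17 + (i - 1) * 2 + 1:2)
    genes <- sprintf("gene%03d", 20 + (i - 1) * 4 + 1:4)
    de[[length(de) + 1L]] <- data.frame(
      contrast = labels[i], kind = c("miR", "miR", rep("gene", 4)),
      feature_id = c(mirs, genes),
      log2_effect = c(1.5, -1.5, 2, 2, -2, -2),
      stringsAsFactors = FALSE)
  }

  # Tumor-only persistent couplings: present in all four stages, absent in
  # NT; endpoints deliberately not DE.
  for (j in 1:5) {
    cp[[length(cp) + 1L]] <- data.frame(
      mir = sprintf("mir%02d", 25 + j), gene = sprintf("gene%03d", 36 + j),
      sign = -1L, strength = 0.9, phenotypes = "I,II,III,IV",
      group = "tumor_persistent", stringsAsFactors = FALSE)
  }
  # Positive couplings, active everywhere.
  for (j in 1:5) {
    cp[[length(cp) + 1L]] <- data.frame(
      mir = sprintf("mir%02d", 30 + j), gene = sprintf("gene%03d", 41 + j),
      sign = 1L, strength = 0.9, phenotypes = "NT,I,II,III,IV",
      group = "positive", stringsAsFactors = FALSE)
  }

  simulation_config(
    n_genes = 300, n_mirs = 50,
    samples_per_phenotype = c(NT = 40, I = 60, II = 40, III = 40, IV = 40),
    dispersion = 0.1, library_size_cv = 0.15,
    de_plan = do.call(rbind, de), coupling_plan = do.call(rbind, cp),
    same_cytoband_fraction = 0.5, seed = seed)
}

#' Generate a synthetic dataset from a configuration
#'
#' @param config a `sim_config`.
#' @return A list with elements `genes`, `mirs` (raw-count `expr_matrix`),
#'   `samples` (`sample_table`), `annotation` (`feature_annotation`), and
#'   `truth` (class `synthetic_truth`: planted per-contrast effects,
#'   coupling table with a `same_cytoband` flag, baselines).
#' @export
generate_synthetic <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  nspp <- config$samples_per_phenotype
  phenos <- rep(PHENOTYPE_LEVELS, times = nspp)
  sample_id <- unlist(lapply(PHENOTYPE_LEVELS, function(ph)
    sprintf("%s_%03d", ph, seq_len(nspp[[ph]]))), use.names = FALSE)
  samples <- sample_table(sample_id, phenos)
  n_samp <- length(sample_id)
  ph_idx <- match(phenos, PHENOTYPE_LEVELS)

  planted <- unique(c(config$de_plan$feature_id, config$coupling_plan$mir,
                      config$coupling_plan$gene))
  draw_baseline <- function(ids) {
    b <- stats::runif(length(ids), config$baseline_log2_range[1],
                      config$baseline_log2_range[2])
    names(b) <- ids
    pl <- intersect(ids, planted)
    b[pl] <- stats::runif(length(pl), config$planted_baseline_log2_range[1],
                          config$planted_baseline_log2_range[2])
    b
  }
  base_gene <- draw_baseline(config$gene_ids)
  base_mir <- draw_baseline(config$mir_ids)

  # Cumulative stage multipliers: an effect planted for contrast (ref,
  # test) applies from the test phenotype onward.
  mult <- function(ids, kind) {
    m <- matrix(1, nrow = length(ids), ncol = 5,
                dimnames = list(ids, PHENOTYPE_LEVELS))
    plan <- config$de_plan[config$de_plan$kind == kind, , drop = FALSE]
    for (r in seq_len(nrow(plan))) {
      test <- parse_contrast_label(plan$contrast[r])$test
      from <- match(test, PHENOTYPE_LEVELS)
      m[plan$feature_id[r], from:5] <-
        m[plan$feature_id[r], from:5] * 2^plan$log2_effect[r]
    }
    m
  }
  mult_gene <- mult(config$gene_ids, "gene")
  mult_mir <- mult(config$mir_ids, "miR")

  # Keep planted features away from the count floor in every phenotype:
  # raise the baseline by the feature's worst-case cumulative depletion, so
  # its per-phenotype mean never drops below the planted baseline range and
  # latent couplings are not drowned in Poisson noise at low counts.
  lift <- function(base, m, ids) {
    pl <- intersect(ids, planted)
    depl <- pmin(0, log2(apply(m[pl, , drop = FALSE], 1L, min)))
    base[pl] <- base[pl] - depl
    base
  }
  base_gene <- lift(base_gene, mult_gene, config$gene_ids)
  base_mir <- lift(base_mir, mult_mir, config$mir_ids)

  lf_gene <- exp(stats::rnorm(n_samp, 0, config$library_size_cv))
  lf_mir <- exp(stats::rnorm(n_samp, 0, config$library_size_cv))

  mu_gene <- outer(2^base_gene, lf_gene) * mult_gene[, ph_idx]
  mu_mir <- outer(2^base_mir, lf_mir) * mult_mir[, ph_idx]

  cpl <- config$coupling_plan
  for (r in seq_len(nrow(cpl))) {
    active <- phenos %in% strsplit(cpl$phenotypes[r], ",", fixed = TRUE)[[1]]
    z <- stats::rnorm(sum(active))
    lambda <- COUPLING_KAPPA * cpl$strength[r]
    mu_gene[cpl$gene[r], active] <- mu_gene[cpl$gene[r], active] *
      exp(lambda * z - lambda^2 / 2)
    mu_mir[cpl$mir[r], active] <- mu_mir[cpl$mir[r], active] *
      exp(cpl$sign[r] * lambda * z - lambda^2 / 2)
  }

  size <- 1 / config$dispersion
  counts_gene <- matrix(stats::rnbinom(length(mu_gene), mu = mu_gene, size = size),
                        nrow = nrow(mu_gene), dimnames = dimnames(mu_gene))
  counts_mir <- matrix(stats::rnbinom(length(mu_mir), mu = mu_mir, size = size),
                       nrow = nrow(mu_mir), dimnames = dimnames(mu_mir))
  colnames(counts_gene) <- colnames(counts_mir) <- sample_id

  annotation <- make_annotation(config)
  same_cb <- annotation$same_cytoband_pairs
  cpl$same_cytoband <- paste(cpl$mir, cpl$gene) %in% same_cb

  truth <- structure(list(
    effects = config$de_plan,
    couplings = cpl,
    baseline_log2_gene = base_gene,
    baseline_log2_mir = base_mir,
    annotation = annotation$table), class = "synthetic_truth")

  list(genes = expression_matrix(counts_gene, "gene", "raw counts"),
       mirs = expression_matrix(counts_mir, "miR", "raw counts"),
       samples = samples, annotation = annotation$table, truth = truth)
}

# Random genomic placement; coupled pairs are forced onto the same cytoband
# for an exact (rounded) fraction within each coupling group, with nearby
# start positions.
make_annotation <- function(config) {
  chrs <- as.character(seq_len(config$n_chromosomes))
  rand_band <- function(n) {
    sprintf("%s%d.%d", sample(c("p", "q"), n, replace = TRUE),
            sample(11:36, n, replace = TRUE), sample(1:3, n, replace = TRUE))
  }
  ids <- c(config$gene_ids, config$mir_ids)
  n <- length(ids)
  chromosome <- sample(chrs, n, replace = TRUE)
  cytoband <- rand_band(n)
  start <- sample.int(2e8, n)
  len <- ifelse(ids %in% config$gene_ids,
                sample.int(1e5, n, replace = TRUE) + 1000L,
                sample.int(60, n, replace = TRUE) + 60L)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  names(chromosome) <- names(cytoband) <- names(start) <- ids

  same_pairs <- character(0)
  cpl <- config$coupling_plan
  if (nrow(cpl) && config$same_cytoband_fraction > 0) {
    for (grp in unique(cpl$group)) {
      rows <- which(cpl$group == grp)
      n_same <- round(config$same_cytoband_fraction * length(rows))
      if (n_same == 0) next
      chosen <- sample(rows, n_same)
      for (r in chosen) {
        chromosome[cpl$gene[r]] <- chromosome[cpl$mir[r]]
        cytoband[cpl$gene[r]] <- cytoband[cpl$mir[r]]
        start[cpl$gene[r]] <- pmax(1L, start[cpl$mir[r]] +
                                     sample(-50000:50000, 1))
        same_pairs <- c(same_pairs, paste(cpl$mir[r], cpl$gene[r]))
      }
    }
  }

  tab <- feature_annotation(
    feature_id = ids, chromosome = unname(chromosome),
    cytoband = unname(cytoband), start = unname(start),
    end = unname(start) + len,
    strand = strand,
    biotype = ifelse(ids %in% config$gene_ids, "protein_coding", "miRNA"))
  list(table = tab, same_cytoband_pairs = same_pairs)
}
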