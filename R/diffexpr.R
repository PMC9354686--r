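# Negative-binomial Wald differential expression over ordered phenotype
# contrasts, Benjamini-Hochberg adjustment, and threshold classification.
#
# The test works on raw counts: size factors are estimated jointly over the
# two groups (median-of-ratios), per-feature dispersions by method of
# moments on the normalized scale, and the Wald statistic is the log2 fold
# change divided by its delta-method standard error.

#' Ordered phenotype contrasts
#'
#' `contiguous_contrasts()` returns the four progression contrasts
#' (NT-I, I-II, II-III, III-IV); `nt_vs_stage_contrasts()` returns the
#' four contrasts of each stage against non-tumor tissue. In every
#' contrast the earlier phenotype is the reference and the later one the
#' test group, so a positive log2 fold change means higher expression in
#' the more advanced phenotype.
#'
#' @return A data.frame with columns `reference`, `test`, `label`.
#' @export
contiguous_contrasts <- function() {
  ref <- PHENOTYPE_LEVELS[1:4]
  tst <- PHENOTYPE_LEVELS[2:5]
  data.frame(reference = ref, test = tst,
             label = contrast_label(ref, tst), stringsAsFactors = FALSE)
}

#' @rdname contiguous_contrasts
#' @export
nt_vs_stage_contrasts <- function() {
  tst <- PHENOTYPE_LEVELS[2:5]
  data.frame(reference = "NT", test = tst,
             label = contrast_label("NT", tst), stringsAsFactors = FALSE)
}

#' @rdname contiguous_contrasts
#' @param reference,test phenotype labels.
#' @export
contrast_label <- function(reference, test) paste(reference, test, sep = "-")

#' @rdname contiguous_contrasts
#' @param label a label produced by [contrast_label()].
#' @export
parse_contrast_label <- function(label) {
  parts <- strsplit(label, "-", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !all(parts %in% PHENOTYPE_LEVELS)) {
    stop("not a contrast label: ", label)
  }
  data.frame(reference = parts[1], test = parts[2], label = label,
             stringsAsFactors = FALSE)
}

#' Negative-binomial Wald test between two sample groups
#'
#' Size factors are computed jointly over both groups by median-of-ratios.
#' Per-feature dispersion is estimated by method of moments on normalized
#' counts, pooled across the two groups and floored at 1e-8; with
#' `dispersion_mode = "trend"` the raw estimate is shrunk 50/50 toward a
#' fitted mean-dispersion trend (a0 + a1/mean). The log2 fold change uses a
#' pseudocount on normalized group means; the two-sided p-value comes from
#' the standard-normal reference for the Wald statistic, and BH adjustment
#' is applied across all features of the matrix.
#'
#' @param mat_ref,mat_test `expr_matrix` objects holding the raw counts of
#'   the reference and test groups (same features, same order).
#' @param dispersion_mode `"per_feature"` or `"trend"`.
#' @param pseudocount added to normalized group means before the log ratio.
#' @param contrast label stored on the result.
#' @return A data.frame of class `de_result` with columns `feature_id`,
#'   `base_mean_ref`, `base_mean_test`, `log2fc`, `se`, `p_raw`, `p_adj`.
#' @export
nb_test <- function(mat_ref, mat_test,
                    dispersion_mode = c("per_feature", "trend"),
                    pseudocount = 0.5, contrast = NA_character_) {
  dispersion_mode <- match.arg(dispersion_mode)
  stopifnot(inherits(mat_ref, "expr_matrix"), inherits(mat_test, "expr_matrix"))
  if (!identical(feature_ids(mat_ref), feature_ids(mat_test))) {
    stop("reference and test matrices must share the same features in order")
  }
  nA <- ncol(mat_ref$values); nB <- ncol(mat_test$values)
  if (nA < 2 || nB < 2) stop("each group needs at least 2 samples")

  joint <- expression_matrix(cbind(mat_ref$values, mat_test$values),
                             mat_ref$feature_kind, mat_ref$units)
  sf <- size_factors(joint)
  norm <- sweep(joint$values, 2L, sf, `/`)
  idxA <- seq_len(nA); idxB <- nA + seq_len(nB)
  sfA <- sf[idxA]; sfB <- sf[idxB]

  muA <- rowMeans(norm[, idxA, drop = FALSE])
  muB <- rowMeans(norm[, idxB, drop = FALSE])

  # Method-of-moments dispersion: on the normalized scale a count has
  # variance approximately mu/s_j + phi * mu^2, so the within-group sample
  # variance minus the Poisson part, divided by mu^2, estimates phi.
  varA <- rowVars(norm[, idxA, drop = FALSE])
  varB <- rowVars(norm[, idxB, drop = FALSE])
  phiA <- (varA - muA * mean(1 / sfA)) / muA^2
  phiB <- (varB - muB * mean(1 / sfB)) / muB^2
  wA <- nA - 1; wB <- nB - 1
  phi <- (wA * phiA + wB * phiB) / (wA + wB)
  phi[!is.finite(phi)] <- 0
  phi <- pmax(phi, 1e-8)

  if (dispersion_mode == "trend") {
    mu0 <- (nA * muA + nB * muB) / (nA + nB)
    ok <- is.finite(phi) & mu0 > 0 & phi > 1e-8
    if (sum(ok) >= 10) {
      fit <- stats::lm(phi[ok] ~ I(1 / mu0[ok]))
      trend <- pmax(stats::coef(fit)[1] + stats::coef(fit)[2] / mu0, 1e-8)
      phi <- pmax(0.5 * phi + 0.5 * trend, 1e-8)
    }
  }

  log2fc <- log2((muB + pseudocount) / (muA + pseudocount))
  varMeanA <- (muA * sum(1 / sfA) + phi * muA^2 * nA) / nA^2
  varMeanB <- (muB * sum(1 / sfB) + phi * muB^2 * nB) / nB^2
  se <- sqrt(varMeanA / (muA + pseudocount)^2 +
             varMeanB / (muB + pseudocount)^2) / log(2)
  z <- ifelse(se > 0, log2fc / se, 0)
  p <- 2 * stats::pnorm(-abs(z))

  allzero <- muA == 0 & muB == 0
  log2fc[allzero] <- 0
  p[allzero] <- 1

  out <- data.frame(feature_id = feature_ids(mat_ref),
                    base_mean_ref = muA, base_mean_test = muB,
                    log2fc = log2fc, se = se, p_raw = p,
                    p_adj = adjust_bh(p), stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("de_result", "data.frame")
  attr(out, "contrast") <- contrast
  attr(out, "dispersion") <- phi
  out
}

rowVars <- function(m) {
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (ncol(m) - 1)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Validating wrapper around the standard step-up procedure.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return Adjusted p-values (monotone in p rank, capped at 1).
#' @export
adjust_bh <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Classify features as over/under/ns at fold-change and p thresholds
#'
#' Both inequalities are strict: a feature is `over` iff
#' `log2fc > lfc_threshold` and its (adjusted or raw) p-value is
#' `< p_threshold`; `under` iff `log2fc < -lfc_threshold` with the same
#' p rule; otherwise `ns`.
#'
#' @param de a `de_result`.
#' @param lfc_threshold positive log2 fold-change cutoff.
#' @param p_threshold p-value cutoff.
#' @param use_adjusted use BH-adjusted p (genes) or raw p (miRs).
#' @return The `de_result` with a `status` column.
#' @export
classify_de <- function(de, lfc_threshold, p_threshold, use_adjusted = TRUE) {
  stopifnot(inherits(de, "de_result"))
  if (lfc_threshold <= 0 || p_threshold <= 0) stop("thresholds must be > 0")
  p <- if (use_adjusted) de$p_adj else de$p_raw
  sig <- p < p_threshold
  status <- rep("ns", nrow(de))
  status[sig & de$log2fc > lfc_threshold] <- "over"
  status[sig & de$log2fc < -lfc_threshold] <- "under"
  de$status <- factor(status, levels = c("over", "under", "ns"))
  de
}

#' Default significance rules
#'
#' Genes: |log2FC| > 1 and BH-adjusted p < 1e-5. miRNAs: |log2FC| > 0.5 and
#' raw p < 1e-5 (the miRNA rule does not use FDR adjustment by default;
#' both rules are configurable).
#'
#' @return A list with `lfc_threshold`, `p_threshold`, `use_adjusted`.
#' @export
gene_de_thresholds <- function() {
  list(lfc_threshold = 1.0, p_threshold = 1e-5, use_adjusted = TRUE)
}

#' @rdname gene_de_thresholds
#' @export
mir_de_thresholds <- function() {
  list(lfc_threshold = 0.5, p_threshold = 1e-5, use_adjusted = FALSE)
}

#' Run classified differential expression for a set of contrasts
#'
#' @param mat an `expr_matrix` of raw counts (post feature filtering).
#' @param samples a `sample_table` covering the matrix columns.
#' @param contrasts data.frame as returned by [contiguous_contrasts()].
#' @param thresholds list from [gene_de_thresholds()] or
#'   [mir_de_thresholds()].
#' @param dispersion_mode passed to [nb_test()].
#' @return Named list of classified `de_result`s, one per contrast label.
#' @export
run_differential <- function(mat, samples, contrasts = contiguous_contrasts(),
                             thresholds = gene_de_thresholds(),
                             dispersion_mode = "per_feature") {
  out <- vector("list", nrow(contrasts))
  names(out) <- contrasts$label
  for (i in seq_len(nrow(contrasts))) {
    ref_ids <- intersect(samples_of(samples, contrasts$reference[i]), sample_ids(mat))
    tst_ids <- intersect(samples_of(samples, contrasts$test[i]), sample_ids(mat))
    de <- nb_test(subset_samples(mat, ref_ids), subset_samples(mat, tst_ids),
                  dispersion_mode = dispersion_mode,
                  contrast = contrasts$label[i])
    out[[i]] <- classify_de(de, thresholds$lfc_threshold,
                            thresholds$p_threshold, thresholds$use_adjusted)
  }
  out
}
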