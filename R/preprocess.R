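# Feature filtering and normalization applied to raw count matrices before
# differential expression and network inference.

#' Filter features by annotation, zero fraction and mean count
#'
#' Filters are applied in order: (1) features absent from the annotation,
#' (2) features with a zero fraction strictly above `max_zero_fraction`,
#' (3) features with mean count strictly below `min_mean`. A feature removed
#' by an earlier filter is not re-counted by a later one.
#'
#' @param mat an `expr_matrix` of raw counts.
#' @param annot a `feature_annotation`, or `NULL` to skip the annotation
#'   filter (useful for pre-harmonized miRNA matrices).
#' @param max_zero_fraction features with zero fraction > this are removed.
#' @param min_mean features with mean count < this are removed.
#' @return A list with elements `matrix` (the filtered `expr_matrix`) and
#'   `report` (a `filter_report`).
#' @export
filter_features <- function(mat, annot, max_zero_fraction = 0.5, min_mean = 10) {
  stopifnot(inherits(mat, "expr_matrix"))
  ids <- feature_ids(mat)
  n_input <- length(ids)
  removed <- data.frame(feature_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)

  keep <- rep(TRUE, n_input)
  if (!is.null(annot)) {
    unann <- !(ids %in% annot$feature_id)
    if (any(unann)) {
      removed <- rbind(removed, data.frame(feature_id = ids[unann],
                                           reason = "unannotated",
                                           stringsAsFactors = FALSE))
      keep[unann] <- FALSE
    }
  }
  zf <- rowMeans(mat$values == 0)
  zero_out <- keep & (zf > max_zero_fraction)
  if (any(zero_out)) {
    removed <- rbind(removed, data.frame(feature_id = ids[zero_out],
                                         reason = "zeros",
                                         stringsAsFactors = FALSE))
    keep[zero_out] <- FALSE
  }
  mu <- rowMeans(mat$values)
  low_out <- keep & (mu < min_mean)
  if (any(low_out)) {
    removed <- rbind(removed, data.frame(feature_id = ids[low_out],
                                         reason = "low_mean",
                                         stringsAsFactors = FALSE))
    keep[low_out] <- FALSE
  }
  if (!any(keep)) stop("no features left after filtering; pipeline cannot proceed")

  report <- structure(list(
    n_input = n_input,
    n_removed_unannotated = sum(removed$reason == "unannotated"),
    n_removed_zeros = sum(removed$reason == "zeros"),
    n_removed_low_mean = sum(removed$reason == "low_mean"),
    n_kept = sum(keep),
    removed_ids = removed), class = "filter_report")
  list(matrix = subset_features(mat, ids[keep]), report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(paste0("<filter_report> %d in; removed: %d unannotated, ",
                     "%d high-zero, %d low-mean; %d kept\n"),
              x$n_input, x$n_removed_unannotated, x$n_removed_zeros,
              x$n_removed_low_mean, x$n_kept))
  invisible(x)
}

#' Median-of-ratios size factors
#'
#' For each sample j, the factor is the median over reference features i of
#' `counts[i, j] / geomean_i`, where the reference set is the features with
#' strictly positive counts in every sample (so the geometric mean is
#' well defined).
#'
#' @param mat an `expr_matrix` of raw counts.
#' @return Numeric vector of strictly positive factors, one per sample,
#'   named by sample id.
#' @export
size_factors <- function(mat) {
  stopifnot(inherits(mat, "expr_matrix"))
  v <- mat$values
  eligible <- rowSums(v == 0) == 0
  if (!any(eligible)) {
    stop(paste("no feature is positive in every sample; median-of-ratios is",
               "undefined (consider a total-count fallback)"))
  }
  lv <- log(v[eligible, , drop = FALSE])
  loggeo <- rowMeans(lv)
  f <- apply(lv, 2L, function(col) exp(stats::median(col - loggeo)))
  stats::setNames(f, sample_ids(mat))
}

#' Divide each sample column by its size factor
#'
#' @param mat an `expr_matrix`.
#' @param factors positive numeric vector, one per sample.
#' @return An `expr_matrix` with units tag `"normalized"`.
#' @export
normalize_counts <- function(mat, factors) {
  stopifnot(inherits(mat, "expr_matrix"))
  if (length(factors) != ncol(mat$values)) {
    stop("length(factors) must equal the number of samples")
  }
  if (any(!is.finite(factors)) || any(factors <= 0)) {
    stop("size factors must be finite and strictly positive")
  }
  expression_matrix(sweep(mat$values, 2L, factors, `/`),
                    mat$feature_kind, "normalized")
}

#' Covariate-level rescaling by equal-frequency bins
#'
#' Optional bias-correction stage: features are stratified into
#' equal-frequency bins of a per-feature covariate (e.g. GC content or
#' length) and each bin's values are rescaled so every bin's median (over
#' all its features and samples) equals the global median. Bins whose
#' median is zero are left unscaled and reported.
#'
#' @param mat an `expr_matrix`.
#' @param covariate numeric vector, one value per feature.
#' @param n_bins number of bins; reduced (with a warning) if it exceeds the
#'   number of features.
#' @return An `expr_matrix` with bin assignments in attribute `bins` and
#'   skipped (zero-median) bins in attribute `degenerate_bins`.
#' @export
covariate_correct <- function(mat, covariate, n_bins = 10) {
  stopifnot(inherits(mat, "expr_matrix"))
  n_feat <- nrow(mat$values)
  if (length(covariate) != n_feat) {
    stop("length(covariate) must equal the number of features")
  }
  if (n_bins > n_feat) {
    warning("n_bins reduced from ", n_bins, " to ", n_feat)
    n_bins <- n_feat
  }
  r <- rank(covariate, ties.method = "average")
  bins <- as.integer(ceiling(r * n_bins / n_feat - 1e-9))
  bins[bins < 1L] <- 1L; bins[bins > n_bins] <- as.integer(n_bins)
  global_med <- stats::median(mat$values)
  if (global_med == 0) {
    warning("global median is zero; covariate correction skipped")
    res <- mat
    attr(res, "bins") <- bins
    attr(res, "degenerate_bins") <- sort(unique(bins))
    return(res)
  }
  out <- mat$values
  degenerate <- integer(0)
  for (b in sort(unique(bins))) {
    sel <- bins == b
    m <- stats::median(mat$values[sel, , drop = FALSE])
    if (m == 0) {
      degenerate <- c(degenerate, b)
      next
    }
    out[sel, ] <- mat$values[sel, , drop = FALSE] * (global_med / m)
  }
  res <- expression_matrix(out, mat$feature_kind, mat$units)
  attr(res, "bins") <- bins
  attr(res, "degenerate_bins") <- degenerate
  res
}
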