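#' Construct an expression matrix
#'
#' Light container for a features x samples abundance matrix. Rows are
#' features (genes or mature miRNAs), columns are samples. Values must be
#' non-negative and finite; raw counts are integers but normalized values
#' are allowed through the `units` tag.
#'
#' @param values numeric matrix with unique rownames (feature ids) and unique
#'   colnames (sample ids).
#' @param feature_kind `"gene"` or `"miR"`.
#' @param units free-text tag, e.g. `"raw counts"` or `"normalized"`.
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `feature_kind`, `units`.
#' @export
expression_matrix <- function(values, feature_kind = c("gene", "miR"),
                              units = "raw counts") {
  feature_kind <- match.arg(feature_kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values))) stop("`values` must have feature ids as rownames")
  if (is.null(colnames(values))) stop("`values` must have sample ids as colnames")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup)) stop("duplicate feature id(s): ", paste(unique(dup), collapse = ", "))
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup)) stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  if (any(!is.finite(values))) stop("all values must be finite")
  if (any(values < 0)) stop("all values must be non-negative")
  structure(list(values = values, feature_kind = feature_kind,
                 units = as.character(units)[1]),
            class = "expr_matrix")
}

#' @rdname expression_matrix
#' @param x an `expr_matrix`.
#' @export
feature_ids <- function(x) rownames(x$values)

#' @rdname expression_matrix
#' @export
sample_ids <- function(x) colnames(x$values)

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d %s features x %d samples [%s]\n",
              nrow(x$values), x$feature_kind, ncol(x$values), x$units))
  invisible(x)
}

#' Subset the samples of an expression matrix
#'
#' @param x an `expr_matrix`.
#' @param samples character vector of sample ids (order preserved as given).
#' @return An `expr_matrix` restricted to `samples`.
#' @export
subset_samples <- function(x, samples) {
  missing <- setdiff(samples, sample_ids(x))
  if (length(missing)) {
    stop("sample(s) not present in matrix: ", paste(missing, collapse = ", "))
  }
  expression_matrix(x$values[, samples, drop = FALSE], x$feature_kind, x$units)
}

#' Subset the features of an expression matrix
#'
#' @param x an `expr_matrix`.
#' @param features character vector of feature ids.
#' @return An `expr_matrix` restricted to `features`.
#' @export
subset_features <- function(x, features) {
  missing <- setdiff(features, feature_ids(x))
  if (length(missing)) {
    stop("feature(s) not present in matrix: ", paste(missing, collapse = ", "))
  }
  expression_matrix(x$values[features, , drop = FALSE], x$feature_kind, x$units)
}
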