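# On-disk formats: everything is tab-separated UTF-8 with a header row and "."
# as the decimal mark. Edge lists are written at full precision so that a
# write/read round trip preserves MI scores to float-text accuracy.

PHENOTYPE_LEVELS <- c("NT", "I", "II", "III", "IV")

#' Read an expression matrix from a TSV file
#'
#' First column holds feature ids, the header row holds sample ids, and the
#' remaining cells are numeric. File order of features and samples is kept.
#'
#' @param path file path.
#' @param feature_kind `"gene"` or `"miR"`.
#' @param units units tag attached to the matrix.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, feature_kind = c("gene", "miR"),
                            units = "raw counts") {
  feature_kind <- match.arg(feature_kind)
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) stop("empty file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  n_col <- length(header)
  if (n_col < 2) stop("header must contain at least one sample id column")
  samples <- header[-1]
  body <- fields[-1]
  widths <- lengths(body)
  if (any(widths != n_col)) {
    bad <- which(widths != n_col)[1]
    stop(sprintf("ragged row at line %d: %d fields, expected %d",
                 bad + 1L, widths[bad], n_col))
  }
  ids <- vapply(body, `[[`, character(1), 1L)
  vals <- matrix(NA_real_, nrow = length(body), ncol = n_col - 1L,
                 dimnames = list(ids, samples))
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]][-1]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      stop(sprintf("non-numeric cell at line %d (feature '%s'), column '%s'",
                   i + 1L, ids[i], samples[j]))
    }
    if (any(v < 0)) {
      j <- which(v < 0)[1]
      stop(sprintf("negative cell at line %d (feature '%s'), column '%s'",
                   i + 1L, ids[i], samples[j]))
    }
    vals[i, ] <- v
  }
  expression_matrix(vals, feature_kind, units)
}

#' Write an expression matrix to a TSV file
#'
#' @param mat an `expr_matrix`.
#' @param path file path.
#' @param id_column name of the first (feature id) column.
#' @export
write_expression <- function(mat, path, id_column = "feature_id") {
  stopifnot(inherits(mat, "expr_matrix"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c(id_column, sample_ids(mat)), collapse = "\t"), con)
  body <- apply(mat$values, 1L, function(v)
    paste(format(v, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = "\t"))
  writeLines(paste(feature_ids(mat), body, sep = "\t"), con)
  invisible(path)
}

# Stage-label dictionary: TCGA-style tumor_stage strings vary, so a small
# normalization map is applied (case-insensitive, trimmed).
.stage_map <- c(
  "nt" = "NT", "normal" = "NT", "control" = "NT", "solid tissue normal" = "NT",
  "stage i" = "I", "i" = "I", "1" = "I",
  "stage ii" = "II", "ii" = "II", "2" = "II",
  "stage iii" = "III", "iii" = "III", "3" = "III",
  "stage iv" = "IV", "iv" = "IV", "4" = "IV"
)

normalize_stage_label <- function(label) {
  key <- tolower(trimws(label))
  unname(.stage_map[key])
}

#' Read a sample table mapping sample ids to phenotypes
#'
#' Two tab-separated columns: sample id and stage label. Rows whose stage is
#' empty or "not reported" (case-insensitive) are dropped silently and the
#' number of drops is recorded in the `n_dropped` attribute. Any other
#' unmappable label is a hard error.
#'
#' @param path file path.
#' @param header whether the file carries a header row.
#' @return A data.frame with columns `sample_id` and `phenotype` (factor with
#'   levels NT, I, II, III, IV), class `sample_table`, attribute `n_dropped`.
#' @export
read_sample_table <- function(path, header = TRUE) {
  lines <- readLines(path, encoding = "UTF-8")
  if (header && length(lines)) lines <- lines[-1]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty sample table: ", path)
    return(sample_table(character(0), character(0), n_dropped = 0L))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(fields)
  if (any(widths < 2L)) {
    stop("malformed sample-table row at line ",
         which(widths < 2L)[1] + if (header) 1L else 0L)
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  labels <- vapply(fields, `[[`, character(1), 2L)
  drop <- !nzchar(trimws(labels)) | tolower(trimws(labels)) == "not reported"
  ids <- ids[!drop]; labels <- labels[!drop]
  stages <- normalize_stage_label(labels)
  if (anyNA(stages)) {
    stop("unmappable stage label(s): ",
         paste(unique(labels[is.na(stages)]), collapse = ", "))
  }
  sample_table(ids, stages, n_dropped = sum(drop))
}

#' Construct a sample table in code
#'
#' @param sample_id character vector of unique sample ids.
#' @param phenotype character vector of phenotype labels (NT, I, II, III, IV).
#' @param n_dropped number of records dropped at read time (bookkeeping).
#' @return A `sample_table` data.frame.
#' @export
sample_table <- function(sample_id, phenotype, n_dropped = 0L) {
  sample_id <- as.character(sample_id)
  phenotype <- as.character(phenotype)
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample id(s): ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  }
  bad <- setdiff(unique(phenotype), PHENOTYPE_LEVELS)
  if (length(bad)) stop("invalid phenotype label(s): ", paste(bad, collapse = ", "))
  out <- data.frame(sample_id = sample_id,
                    phenotype = factor(phenotype, levels = PHENOTYPE_LEVELS),
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_table", "data.frame")
  attr(out, "n_dropped") <- as.integer(n_dropped)
  out
}

#' Samples belonging to one phenotype
#'
#' @param samples a `sample_table`.
#' @param phenotype one of NT, I, II, III, IV.
#' @return Character vector of sample ids.
#' @export
samples_of <- function(samples, phenotype) {
  phenotype <- match.arg(phenotype, PHENOTYPE_LEVELS)
  samples$sample_id[samples$phenotype == phenotype]
}

#' Construct a feature annotation table
#'
#' @param feature_id,chromosome,cytoband,start,end,strand,biotype parallel
#'   vectors; `start` is 1-based, intervals are closed, `start <= end`,
#'   strand is one of `+`, `-`, `.`.
#' @return A data.frame of class `feature_annotation`.
#' @export
feature_annotation <- function(feature_id, chromosome, cytoband, start, end,
                               strand = ".", biotype = "unknown") {
  out <- data.frame(feature_id = as.character(feature_id),
                    chromosome = as.character(chromosome),
                    cytoband = as.character(cytoband),
                    start = as.integer(start), end = as.integer(end),
                    strand = as.character(strand),
                    biotype = as.character(biotype),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$feature_id)) {
    stop("duplicate feature id(s) in annotation: ",
         paste(unique(out$feature_id[duplicated(out$feature_id)]), collapse = ", "))
  }
  if (any(!nzchar(out$chromosome))) stop("chromosome must be non-empty")
  if (any(out$start < 0)) stop("start must be non-negative")
  if (any(out$end < out$start)) stop("end must be >= start")
  if (!all(out$strand %in% c("+", "-", "."))) stop("strand must be one of +, -, .")
  class(out) <- c("feature_annotation", "data.frame")
  out
}

#' Read / write a feature annotation TSV
#'
#' Columns: feature_id, chromosome, cytoband, start, end, strand, biotype.
#'
#' @param path file path.
#' @return `read_annotation`: a `feature_annotation`.
#' @export
read_annotation <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("feature_id", "chromosome", "cytoband", "start", "end",
            "strand", "biotype")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("annotation file lacks column(s): ", paste(missing, collapse = ", "))
  }
  feature_annotation(df$feature_id, df$chromosome, df$cytoband, df$start,
                     df$end, df$strand, df$biotype)
}

#' @rdname read_annotation
#' @param annot a `feature_annotation`.
#' @export
write_annotation <- function(annot, path) {
  utils::write.table(annot, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct a bipartite miR-gene network
#'
#' Edges are directed miR -> gene by convention; the pair (mir_id, gene_id)
#' is the edge identity and must be unique. MI scores are non-negative nats.
#'
#' @param mir_id,gene_id,mi parallel edge vectors.
#' @param phenotype phenotype label the network belongs to.
#' @param k retention parameter (`NA` for "all").
#' @param filtered one of `"raw"`, `"topk"`, `"canonical"`.
#' @return A data.frame of class `bipartite_network` with attributes
#'   `phenotype`, `k`, `filtered`.
#' @export
bipartite_network <- function(mir_id = character(0), gene_id = character(0),
                              mi = numeric(0), phenotype = NA_character_,
                              k = NA_integer_, filtered = c("raw", "topk", "canonical")) {
  filtered <- match.arg(filtered)
  out <- data.frame(mir_id = as.character(mir_id),
                    gene_id = as.character(gene_id),
                    mi = as.numeric(mi), stringsAsFactors = FALSE)
  if (nrow(out)) {
    if (anyDuplicated(paste(out$mir_id, out$gene_id, sep = "\r"))) {
      stop("duplicate (mir_id, gene_id) edge(s)")
    }
    if (any(!is.finite(out$mi)) || any(out$mi < 0)) {
      stop("MI scores must be finite and non-negative")
    }
  }
  class(out) <- c("bipartite_network", "data.frame")
  attr(out, "phenotype") <- phenotype
  attr(out, "k") <- k
  attr(out, "filtered") <- filtered
  out
}

edge_keys <- function(net) paste(net$mir_id, net$gene_id, sep = "\r")

#' Write / read a network edge list TSV
#'
#' Columns mir_id, gene_id, mi_score; scores are written at full precision
#' (`%.17g`) so the round trip is exact to float-text accuracy.
#'
#' @param net a `bipartite_network`.
#' @param path file path.
#' @export
write_edges <- function(net, path) {
  stopifnot(inherits(net, "bipartite_network"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("mir_id\tgene_id\tmi_score", con)
  if (nrow(net)) {
    writeLines(paste(net$mir_id, net$gene_id, sprintf("%.17g", net$mi),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_edges
#' @param phenotype,k,filtered provenance restored onto the read network.
#' @export
read_edges <- function(path, phenotype = NA_character_, k = NA_integer_,
                       filtered = "raw") {
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) stop("empty edge file: ", path)
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (!length(body)) {
    return(bipartite_network(phenotype = phenotype, k = k, filtered = filtered))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  widths <- lengths(fields)
  if (any(widths != 3L)) {
    stop("malformed edge row at line ", which(widths != 3L)[1] + 1L)
  }
  mi <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  if (anyNA(mi)) {
    stop("malformed edge row at line ", which(is.na(mi))[1] + 1L)
  }
  bipartite_network(vapply(fields, `[[`, character(1), 1L),
                    vapply(fields, `[[`, character(1), 2L),
                    mi, phenotype = phenotype, k = k, filtered = filtered)
}

#' Export a bipartite network to GraphML for visualization
#'
#' @param net a `bipartite_network`.
#' @param path output file path.
#' @export
write_graphml <- function(net, path) {
  stopifnot(inherits(net, "bipartite_network"))
  nodes <- data.frame(
    name = c(unique(net$mir_id), unique(net$gene_id)),
    kind = c(rep("miR", length(unique(net$mir_id))),
             rep("gene", length(unique(net$gene_id)))),
    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = net$mir_id, to = net$gene_id, mi = net$mi,
               stringsAsFactors = FALSE),
    directed = TRUE, vertices = nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write a differential-expression table to TSV
#'
#' @param de a `de_result` (see [nb_test()]).
#' @param path file path.
#' @export
write_de_table <- function(de, path) {
  stopifnot(inherits(de, "de_result"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# contrast: ", attr(de, "contrast")), con)
  cols <- c("feature_id", "base_mean_ref", "base_mean_test", "log2fc",
            "p_raw", "p_adj", if ("status" %in% names(de)) "status")
  writeLines(paste(cols, collapse = "\t"), con)
  df <- as.data.frame(de)[, cols, drop = FALSE]
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- sprintf("%.17g", df[[j]])
  writeLines(do.call(paste, c(df, sep = "\t")), con)
  invisible(path)
}

#' @rdname write_de_table
#' @export
read_de_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  contrast <- NA_character_
  if (length(lines) && startsWith(lines[1], "# contrast:")) {
    contrast <- trimws(sub("# contrast:", "", lines[1], fixed = TRUE))
    lines <- lines[-1]
  }
  df <- utils::read.table(text = lines, sep = "\t", header = TRUE,
                          quote = "", stringsAsFactors = FALSE)
  if ("status" %in% names(df)) {
    df$status <- factor(df$status, levels = c("over", "under", "ns"))
  }
  class(df) <- c("de_result", "data.frame")
  attr(df, "contrast") <- contrast
  df
}

#' Write a list (run summary, report) as JSON
#'
#' @param x a list of plain values.
#' @param path file path.
#' @export
write_json_summary <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
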