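# Persistent miRNAs: miRs differentially expressed in every contiguous
# contrast, and their stage-specific canonical targets. Persistence does
# not require a constant sign across contrasts — the motivating exemplar
# flips sign mid-progression.

#' Find miRNAs differentially expressed in all four contiguous contrasts
#'
#' A miR is persistent iff its classified status is `over` or `under` in
#' every contiguous contrast. Each persistent miR's trajectory carries its
#' per-contrast log2 fold change, p-value and status, and its per-stage
#' target genes taken from the stage canonical networks (genes connected
#' to the miR), with the targets' log2 fold changes from the matching
#' contrast.
#'
#' @param series a `stage_series`.
#' @return A list of `mir_trajectory` objects (possibly empty), named by
#'   miR id.
#' @export
persistent_de_mirs <- function(series) {
  stopifnot(inherits(series, "stage_series"))
  contrasts <- series$contrasts
  mir_ids <- sort(unique(unlist(lapply(series$de_mirs, `[[`, "feature_id"))))
  status_tab <- vapply(series$de_mirs, function(de) {
    s <- stats::setNames(as.character(de$status), de$feature_id)[mir_ids]
    s[is.na(s)] <- "ns"
    s
  }, character(length(mir_ids)))
  if (is.null(dim(status_tab))) {
    status_tab <- matrix(status_tab, nrow = length(mir_ids),
                         dimnames = list(mir_ids, names(series$de_mirs)))
  }
  persistent <- mir_ids[rowSums(status_tab != "ns") == ncol(status_tab)]

  lapply(stats::setNames(persistent, persistent), function(mir) {
    traj <- do.call(rbind, lapply(seq_len(nrow(contrasts)), function(i) {
      de <- series$de_mirs[[contrasts$label[i]]]
      row <- de[de$feature_id == mir, , drop = FALSE]
      data.frame(contrast = contrasts$label[i], stage = contrasts$test[i],
                 log2fc = row$log2fc, p = row$p_raw,
                 status = as.character(row$status), stringsAsFactors = FALSE)
    }))
    targets <- lapply(stats::setNames(contrasts$test, contrasts$test),
                      function(stage) {
      net <- series$canonical[[stage]]
      genes <- net$gene_id[net$mir_id == mir]
      de_g <- series$de_genes[[contrast_label(
        contrasts$reference[contrasts$test == stage], stage)]]
      data.frame(gene_id = genes,
                 log2fc = de_g$log2fc[match(genes, de_g$feature_id)],
                 stringsAsFactors = FALSE)
    })
    structure(list(mir_id = mir, contrasts = traj, targets = targets),
              class = "mir_trajectory")
  })
}

#' Per-stage target turnover of a persistent miR
#'
#' Gains and losses are set differences between consecutive stages' target
#' sets; the first stage reports all its targets as gained.
#'
#' @param traj a `mir_trajectory`.
#' @return A data.frame with columns `stage`, `n_targets`, `n_gained`,
#'   `n_lost`, `mean_target_log2fc`.
#' @export
target_turnover <- function(traj) {
  stopifnot(inherits(traj, "mir_trajectory"))
  stages <- names(traj$targets)
  prev <- character(0)
  rows <- lapply(stages, function(stage) {
    cur <- traj$targets[[stage]]$gene_id
    lfc <- traj$targets[[stage]]$log2fc
    r <- data.frame(stage = stage, n_targets = length(cur),
                    n_gained = length(setdiff(cur, prev)),
                    n_lost = length(setdiff(prev, cur)),
                    mean_target_log2fc = if (length(lfc)) mean(lfc) else NA_real_,
                    stringsAsFactors = FALSE)
    prev <<- cur
    r
  })
  do.call(rbind, rows)
}

#' Flat table of all persistent-miR trajectories
#'
#' @param trajectories list from [persistent_de_mirs()].
#' @return A data.frame with one row per (miR, stage, target gene), with
#'   targetless stages carried as `NA` target rows.
#' @export
trajectory_table <- function(trajectories) {
  rows <- lapply(trajectories, function(traj) {
    do.call(rbind, lapply(seq_len(nrow(traj$contrasts)), function(i) {
      stage <- traj$contrasts$stage[i]
      tg <- traj$targets[[stage]]
      if (!nrow(tg)) tg <- data.frame(gene_id = NA_character_,
                                      log2fc = NA_real_,
                                      stringsAsFactors = FALSE)
      data.frame(mir_id = traj$mir_id,
                 contrast = traj$contrasts$contrast[i],
                 mir_log2fc = traj$contrasts$log2fc[i],
                 status = traj$contrasts$status[i],
                 stage = stage, target = tg$gene_id,
                 target_log2fc = tg$log2fc, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(mir_id = character(0), contrast = character(0),
                      mir_log2fc = numeric(0), status = character(0),
                      stage = character(0), target = character(0),
                      target_log2fc = numeric(0), stringsAsFactors = FALSE)
  }
  out
}
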