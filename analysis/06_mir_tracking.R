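#!/usr/bin/env Rscript
# Step 6: persistent-miR tracking. A miR is persistent when it is
# differentially expressed in every contiguous contrast (sign flips
# allowed); its targets are the genes it reaches in each stage's canonical
# network. Reports per-stage target counts and turnover.

library(mirstagenet)

out <- "results"
phenos <- c("NT", "I", "II", "III", "IV")
stages <- c("I", "II", "III", "IV")
contrasts <- contiguous_contrasts()

topk <- setNames(lapply(phenos, function(ph)
  read_edges(file.path(out, sprintf("network_%s_topk.tsv", ph)),
             phenotype = ph, k = 336L, filtered = "topk")), phenos)
canonical <- setNames(lapply(stages, function(st)
  read_edges(file.path(out, sprintf("network_%s_canonical.tsv", st)),
             phenotype = st, k = 336L, filtered = "canonical")), stages)
de_genes <- setNames(lapply(contrasts$label, function(lbl)
  read_de_table(file.path(out, sprintf("de_genes_%s.tsv", lbl)))),
  contrasts$label)
de_mirs <- setNames(lapply(contrasts$label, function(lbl)
  read_de_table(file.path(out, sprintf("de_mirs_%s.tsv", lbl)))),
  contrasts$label)

series <- structure(list(topk = topk, canonical = canonical,
                         de_genes = de_genes, de_mirs = de_mirs,
                         contrasts = contrasts, k = 336L),
                    class = "stage_series")

trajectories <- persistent_de_mirs(series)
message(length(trajectories), " miR(s) differentially expressed in all ",
        "four contiguous contrasts: ",
        paste(names(trajectories), collapse = ", "))

tab <- trajectory_table(trajectories)
write.table(tab, file.path(out, "mir_trajectories.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

for (traj in trajectories) {
  message("\n", traj$mir_id, " trajectory:")
  print(traj$contrasts, row.names = FALSE)
  tt <- target_turnover(traj)
  print(tt, row.names = FALSE)
  message("Stage-specific targets: ",
          paste(vapply(traj$targets, function(t)
            paste(t$gene_id, collapse = "+"), ""), collapse = " | "))
}
write_json_summary(
  lapply(trajectories, function(tr) list(
    mir_id = tr$mir_id, contrasts = tr$contrasts,
    turnover = target_turnover(tr))),
  file.path(out, "mir_trajectories.json"))
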