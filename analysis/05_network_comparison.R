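#!/usr/bin/env Rscript
# Step 5: set-algebra comparison of the five top-K networks — UpSet-style
# exclusive intersection counts, per-network uniqueness fractions, the
# tumor-shared-not-control edge set, and its cytoband co-location profile.

library(mirstagenet)

out <- "results"
phenos <- c("NT", "I", "II", "III", "IV")
topk <- setNames(lapply(phenos, function(ph)
  read_edges(file.path(out, sprintf("network_%s_topk.tsv", ph)),
             phenotype = ph, k = 336L, filtered = "topk")), phenos)

itab <- intersection_counts(topk)
write.table(as.data.frame(itab), file.path(out, "intersection_table.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

uniq <- vapply(phenos, function(ph)
  uniqueness_fraction(topk[[ph]], topk[phenos != ph]), numeric(1))
message("Uniqueness per network: ",
        paste(sprintf("%s=%.1f%%", phenos, 100 * uniq), collapse = ", "))

# Edges shared by all four tumor stages but absent from NT.
series <- structure(list(topk = topk, canonical = NULL,
                         contrasts = contiguous_contrasts(), k = 336L),
                    class = "stage_series")
shared <- tumor_shared_not_control(series, level = "topk")
write.table(shared, file.path(out, "tumor_shared_edges.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(nrow(shared), " interactions are common to the four stages and ",
        "absent from the non-tumor network.")

annot <- read_annotation(file.path(out, "annotation.tsv"))
if (nrow(shared)) {
  ann <- annotate_edges(shared, annot)
  coloc <- colocation_summary(ann)
  write_json_summary(coloc, file.path(out, "colocation_summary.json"))
  message(sprintf(
    "Of these, %.0f%% are intra-chromosomal and %.0f%% intra-cytoband.",
    100 * coloc$frac_same_chromosome, 100 * coloc$frac_same_cytoband))
}
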