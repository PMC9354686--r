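#!/usr/bin/env Rscript
# Step 1: generate the synthetic study — paired gene/miR count matrices over
# five phenotypes (NT, stages I-IV) with planted stage-wise DE, planted
# negatively coupled miR-gene pairs, and genomic coordinates — and write the
# raw inputs plus the truth tables under results/.

library(mirstagenet)

seed <- 20220722L
out <- "results"
dir.create(out, showWarnings = FALSE)

config <- default_study(seed = seed)
data <- generate_synthetic(config)

write_expression(data$genes, file.path(out, "genes_raw.tsv"))
write_expression(data$mirs, file.path(out, "mirs_raw.tsv"))
write.table(data$samples, file.path(out, "samples.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_annotation(data$annotation, file.path(out, "annotation.tsv"))
write.table(data$truth$couplings, file.path(out, "truth_couplings.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data$truth$effects, file.path(out, "truth_effects.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

tab <- table(data$samples$phenotype)
message("Simulated ", nrow(data$genes$values), " genes and ",
        nrow(data$mirs$values), " miRs over ",
        nrow(data$samples), " samples (",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), ")")
message("Planted: ", nrow(config$de_plan), " DE effects, ",
        nrow(config$coupling_plan), " couplings (",
        sum(config$coupling_plan$sign == -1), " negative)")
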