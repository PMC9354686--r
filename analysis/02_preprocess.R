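#!/usr/bin/env Rscript
# Step 2: feature filtering (annotation presence, zero fraction <= 50%,
# mean count >= 10) and median-of-ratios normalization. Writes the filtered
# raw counts (DE works on raw counts) and the normalized matrices used for
# network inference.

library(mirstagenet)

out <- "results"
genes <- read_expression(file.path(out, "genes_raw.tsv"), "gene")
mirs <- read_expression(file.path(out, "mirs_raw.tsv"), "miR")
annot <- read_annotation(file.path(out, "annotation.tsv"))

fg <- filter_features(genes, annot)
fm <- filter_features(mirs, annot)
print(fg$report)
print(fm$report)
write_json_summary(list(genes = fg$report[1:5], mirs = fm$report[1:5]),
                   file.path(out, "filter_report.json"))

write_expression(fg$matrix, file.path(out, "genes_filtered.tsv"))
write_expression(fm$matrix, file.path(out, "mirs_filtered.tsv"))

sf_g <- size_factors(fg$matrix)
sf_m <- size_factors(fm$matrix)
write_expression(normalize_counts(fg$matrix, sf_g),
                 file.path(out, "genes_normalized.tsv"))
write_expression(normalize_counts(fm$matrix, sf_m),
                 file.path(out, "mirs_normalized.tsv"))
message("Size factors (genes): ", paste(round(range(sf_g), 3), collapse = " - "))
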