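#!/usr/bin/env Rscript

# Positional classification of the differential lncRNAs: each is assigned
# one of six categories relative to the coding-gene models (exon
# sense-overlapping, intron sense-overlapping, natural antisense, intronic
# antisense, bidirectional, intergenic) plus its nearest coding gene within
# 300 kb. Depends on 02_differential.R.

library(lnchcc)

data_dir <- file.path("results", "data", "study")
out_dir <- file.path("results", "genomic_context")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

ann <- read_probe_annotation(file.path(data_dir, "annotation.tsv"))
models <- read_gene_models(file.path(data_dir, "genes.bed"))
de <- read_table_skip_comments(
  file.path("results", "differential", "differential.tsv"))

de_lnc <- de$probe_id[de$call != "ns" & de$biotype == "lncRNA"]
calls <- classify_lncrnas(ann[ann$probe_id %in% de_lnc, ], models)
write_table_with_header(calls, file.path(out_dir, "positional_calls.tsv"),
                        config_hash(data_dir))

tab <- table(factor(calls$category,
                    levels = c("exon_sense_overlapping",
                               "intron_sense_overlapping",
                               "natural_antisense", "intronic_antisense",
                               "bidirectional", "intergenic")))
cat(sprintf("%d differential lncRNAs classified:\n", nrow(calls)))
print(tab)
cat(sprintf("%d have a coding gene within 300 kb\n",
            sum(!is.na(calls$nearby_gene_id))))
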