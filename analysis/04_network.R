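#!/usr/bin/env Rscript

# Co-expression couple recovery on the coexpr benchmark: all-pairs Pearson
# correlation across the six pooled arrays between the planted couples and a
# background panel of independent probes, keeping edges with |r| >= 0.99 and
# p < 0.001. At six arrays the r threshold is binding (r = 0.99 gives
# p = 1.5e-4), and its null tail implies an expected ~1.8 chance edges over
# the ~1.2e4 background pairs tested here, so a small nonzero false-edge
# count is the correct behavior of correct code.

library(lnchcc)

data_dir <- file.path("results", "data", "coexpr")
out_dir <- file.path("results", "network")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

dat <- read_expression(file.path(data_dir, "expression.tsv"),
                       file.path(data_dir, "design.csv"))
norm <- quantile_normalize(dat$expression)
couples <- read_table_skip_comments(file.path(data_dir, "truth_couples.tsv"))
probes <- read_table_skip_comments(file.path(data_dir, "truth_probes.tsv"))

bg_lnc <- setdiff(probes$probe_id[probes$biotype == "lncRNA"],
                  couples$lnc_probe_id)[1:100]
bg_mrna <- setdiff(probes$probe_id[probes$biotype == "mRNA"],
                   couples$mrna_probe_id)[1:100]
net <- build_network(norm, c(couples$lnc_probe_id, bg_lnc),
                     c(couples$mrna_probe_id, bg_mrna))

write_table_with_header(net$edges, file.path(out_dir, "edges.tsv"),
                        config_hash(data_dir))
export_network(net$edges,
               graphml_path = file.path(out_dir, "network.graphml"),
               edgelist_path = file.path(out_dir, "edges_plain.tsv"))

key <- paste(net$edges$lnc_probe_id, net$edges$mrna_probe_id)
planted <- paste(couples$lnc_probe_id, couples$mrna_probe_id)
cat(sprintf("edges: %d (%d positive); planted couples recovered: %d/%d; false edges: %d\n",
            net$summary$n_edges, net$summary$n_positive_edges,
            sum(planted %in% key), length(planted), sum(!key %in% planted)))
print(net$extremes)
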