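#!/usr/bin/env Rscript

# qPCR validation of the array calls: 2^-ddCt relative quantification of the
# simulated Ct panel, per-gene paired delta-Ct t-tests, and sign concordance
# of per-patient log2 ratios between the two platforms (majority rule).
# Depends on 01_simulate.R.

library(lnchcc)

data_dir <- file.path("results", "data", "study")
out_dir <- file.path("results", "qpcr")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

ct <- read_ct_table(file.path(data_dir, "qpcr_ct.csv"))
dat <- read_expression(file.path(data_dir, "expression.tsv"),
                       file.path(data_dir, "design.csv"))
array_ratios <- per_pair_log2_ratio(quantile_normalize(dat$expression),
                                    dat$design)

qpcr_ratios <- qpcr_log2_ratios(ct)
shared <- intersect(rownames(qpcr_ratios), rownames(array_ratios))
pats <- intersect(colnames(qpcr_ratios), colnames(array_ratios))

tests <- t(vapply(shared, function(g) {
  fit <- paired_delta_ct_test(ct, g)
  c(t = fit$t, p = fit$p)
}, numeric(2)))
conc <- vapply(shared, function(g) {
  suppressWarnings(concordance(array_ratios[g, pats], qpcr_ratios[g, pats]))
}, logical(1))

out <- data.frame(gene_id = shared,
                  qpcr_mean_log2_ratio = rowMeans(qpcr_ratios[shared, pats]),
                  array_mean_log2_ratio = rowMeans(array_ratios[shared, pats]),
                  t = tests[, "t"], p_value = tests[, "p"],
                  concordant = conc, stringsAsFactors = FALSE)
write_table_with_header(out, file.path(out_dir, "qpcr_validation.tsv"),
                        config_hash(data_dir))

cat(sprintf("%d/%d assayed genes concordant with the arrays (majority rule)\n",
            sum(conc, na.rm = TRUE), length(conc)))
cat(sprintf("%d genes significant in the paired delta-Ct test (p < 0.05)\n",
            sum(tests[, "p"] < 0.05)))
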