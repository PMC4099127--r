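#!/usr/bin/env Rscript

# Simulate the two benchmark studies that the rest of the workflow analyses.
#
# - results/data/study/: the differential-expression benchmark (3 tumor/normal
#   pairs, 160 probes per biotype, 25 up- and 25 down-regulated planted per
#   biotype at |log2 FC| = 3), with annotation, gene models and a qPCR panel.
# - results/data/coexpr/: the co-expression benchmark (no planted
#   differential signal, 10 planted lncRNA-mRNA couples against 1000 probes
#   per biotype of independent background).
#
# The two are kept separate on purpose: a large planted shift distorts the
# pooled intensity distribution that quantile normalization equalizes, which
# would confound the correlation benchmark (see the methods vignette).

library(lnchcc)

seed <- 1L

study <- simulate_study(de_benchmark_config(seed = seed),
                        file.path("results", "data", "study"))
coexpr <- simulate_study(network_benchmark_config(seed = seed),
                         file.path("results", "data", "coexpr"))

cat(sprintf("study:  %d probes x %d arrays, %d planted differential\n",
            nrow(study$expression$expression),
            ncol(study$expression$expression),
            sum(study$expression$truth$probes$de_status != "null")))
cat(sprintf("coexpr: %d probes x %d arrays, %d planted couples\n",
            nrow(coexpr$expression$expression),
            ncol(coexpr$expression$expression),
            nrow(coexpr$expression$truth$couples)))
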