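# lnchcc

Paired lncRNA/mRNA microarray analysis for hepatocellular carcinoma (HCC)
studies — a tested R implementation of the full workflow used when a few
tumor/adjacent-normal tissue pairs are profiled on a combined lncRNA/mRNA
array, together with a synthetic-data generator that makes every stage
verifiable against recorded ground truth.

## The scientific problem

Long noncoding RNAs (lncRNAs) are increasingly implicated in liver cancer,
but a typical discovery study has only a handful of patients: each
contributes one tumor and one matched non-tumor array. The workflow that
turns those arrays into biology has five stages, all implemented here:

1. **Normalization and differential expression.** Arrays are quantile
   normalized; per-patient log2 tumor/normal ratios feed a paired t-test,
   and probes are called differential by the triple criterion *fold change
   ≥ 2.0 or ≤ 0.5* (inclusive) *and p < 0.05 and BH-FDR < 0.05* (exclusive),
   with FDR adjusted within each biotype. Per-patient tallies bin fold
   changes half-open into [2, 4), [4, 6), [6, ∞).
2. **Genomic context.** Each differential lncRNA is classified against
   coding-gene models into one of six positional categories
   (exon sense-overlapping, intron sense-overlapping, natural antisense,
   intronic antisense, bidirectional, intergenic; precedence in that
   order) and linked to its nearest coding gene within 300 kb (strict).
3. **Subgroup filters.** User-supplied lncRNA catalogs (e.g. enhancer-like
   or lincRNA sets) are intersected with the differential calls and with
   differentially expressed nearby genes.
4. **Co-expression network.** All-pairs Pearson correlation between
   differential lncRNAs and mRNAs across every array (tumor and normal
   pooled), keeping edges with |r| ≥ 0.99 and p < 0.001, exported as
   GraphML/edge list with composition summaries.
5. **qPCR validation.** 2^−ΔΔCt relative quantification, per-gene paired
   ΔCt t-tests, and per-patient sign concordance between platforms
   (majority rule by default).

Because public raw data for such studies is not reproducible at desk scale,
the package ships a generator (`synth_config()`, `generate_expression()`,
`generate_annotation()`, `generate_qpcr()`, `simulate_study()`) that plants
known differential probes, positional categories, and near-perfect
lncRNA–mRNA couples, and records the truth for testing. See the methods
vignette (`vignettes/methods.Rmd`) for the model, the parameter rationale,
and what is deliberately not emulated.

## Worked example

Simulate the bundled differential-expression benchmark (3 patients, 160
probes per biotype, 25 up and 25 down planted per biotype at |log2 FC| = 3),
normalize, and call differential probes:

```r
library(lnchcc)

cfg <- de_benchmark_config(seed = 1)
ex  <- generate_expression(cfg)
norm <- quantile_normalize(ex$expression)
de  <- run_differential(norm, ex$design, biotype = ex$truth$probes$biotype)
table(de$biotype, de$call)
#>
#>          down  ns  up
#>   lncRNA   26 109  25
#>   mRNA     21 116  23
head(de[de$call != "ns",
        c("probe_id", "biotype", "fold_change", "p_value", "q_value", "call")], 4)
#>    probe_id biotype fold_change  p_value q_value call
#> 2   LNC0002  lncRNA      0.0928 0.001149 0.01108 down
#> 6   LNC0006  lncRNA      0.1634 0.012117 0.03590 down
#> 7   LNC0007  lncRNA     10.0737 0.004383 0.01765   up
#> 14  LNC0014  lncRNA      7.9131 0.000458 0.00789   up
```

Classify lncRNAs positionally against the generated gene models:

```r
ann <- generate_annotation(synth_config(n_lnc_probes = 70,
                                        n_mrna_probes = 70, seed = 1))
calls <- classify_lncrnas(ann$annotation[ann$annotation$biotype == "lncRNA", ],
                          ann$genes)
head(calls, 4)
#>   probe_id transcript_id                 category nearby_gene_id distance_bp
#> 1  LNC0001      TLNC0001   exon_sense_overlapping       GENE0001           0
#> 2  LNC0002      TLNC0002 intron_sense_overlapping       GENE0002           0
#> 3  LNC0003      TLNC0003        natural_antisense       GENE0003           0
#> 4  LNC0004      TLNC0004       intronic_antisense       GENE0004           0
```

Quantify a qPCR measurement by 2^−ΔΔCt:

```r
ct <- data.frame(patient_id = c("P1", "P1"), condition = c("tumor", "normal"),
                 gene_id = "G1", ct_target = c(20, 23), ct_reference = c(15, 15))
ddct_fold(ct, "P1", "G1")
#> $delta_delta_ct
#> [1] -3
#> $fold
#> [1] 8
#> $log2_ratio
#> [1] 3
```

Or run everything at once from files via
`run_pipeline(pipeline_config(...))`, which writes the normalized matrix,
differential table, fold-change bins, positional calls, network files, qPCR
results and a run manifest, each stamped with the configuration hash.

## The analysis workflow

`analysis/` contains numbered scripts that drive the package over the
simulated benchmarks, writing everything under `results/`:

```sh
Rscript analysis/01_simulate.R          # simulate both benchmark datasets
Rscript analysis/02_differential.R      # normalize + differential calling
Rscript analysis/03_genomic_context.R   # positional classification
Rscript analysis/04_network.R           # co-expression couple recovery
Rscript analysis/05_qpcr_validation.R   # qPCR concordance
```

Sample output:

```
study:  320 probes x 6 arrays, 100 planted differential
recall 0.940, precision 0.989 against the planted truth
edges: 11 (11 positive); planted couples recovered: 10/10; false edges: 1
97/100 assayed genes concordant with the arrays (majority rule)
```

The single false network edge is expected behavior, not a bug: at six
pooled arrays the null tail P(|r| ≥ 0.99) ≈ 1.5×10⁻⁴ per pair, so the
~1.2×10⁴ background pairs tested carry an expected ~1.8 chance edges (see
the vignette).

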