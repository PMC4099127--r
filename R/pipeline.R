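#' Pipeline configuration
#'
#' Collects input paths and analysis thresholds for an end-to-end run. The
#' defaults are the study thresholds: fold change >= 2.0 (or <= 0.5),
#' paired t-test p < 0.05, FDR < 0.05, co-expression |r| >= 0.99 with
#' p < 0.001, a 300 kb nearest-gene window and a 1 kb bidirectional TSS
#' distance. The configuration round-trips losslessly through YAML.
#'
#' @param expression,design,annotation,gene_models input paths (expression
#'   TSV, design CSV, probe annotation TSV, BED12/GFF3 gene models).
#' @param ct optional qPCR Ct CSV.
#' @param catalogs optional named list of gene-set file paths.
#' @param out_dir output directory.
#' @param fc_min,p_max,q_max differential thresholds.
#' @param r_min,cor_p_max network thresholds.
#' @param window,bidir_tss positional-classification parameters (bp).
#' @param bins linear fold bin edges.
#' @param concordance_rule "majority" or "all-signs".
#' @param seed integer seed (stages are deterministic; the seed is recorded
#'   in the manifest and seeds any optional resampling).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, design, annotation, gene_models,
                            ct = NULL, catalogs = NULL, out_dir = "results",
                            fc_min = 2, p_max = 0.05, q_max = 0.05,
                            r_min = 0.99, cor_p_max = 0.001,
                            window = 3e5, bidir_tss = 1000,
                            bins = c(2, 4, 6),
                            concordance_rule = "majority", seed = 1L) {
  if (any(c(fc_min, p_max, q_max, r_min, cor_p_max, window, bidir_tss) <= 0)) {
    abort_lnchcc("thresholds must be positive", "bad_threshold")
  }
  cfg <- list(expression = expression, design = design,
              annotation = annotation, gene_models = gene_models, ct = ct,
              catalogs = catalogs, out_dir = out_dir, fc_min = fc_min,
              p_max = p_max, q_max = q_max, r_min = r_min,
              cor_p_max = cor_p_max, window = window, bidir_tss = bidir_tss,
              bins = bins, concordance_rule = concordance_rule,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param path YAML file.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$bins <- as.numeric(x$bins)
  do.call(pipeline_config, x)
}

.stage <- function(name, fmt, ...) {
  message(sprintf("[%s] %s", name, sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Fixed stage order: import and quantile-normalize the arrays, call
#' differential probes per biotype, summarize per-patient fold-change bins,
#' classify lncRNA genomic positions with nearest-gene assignment, build the
#' lncRNA-mRNA co-expression network over the differential probes (all
#' arrays pooled), score qPCR concordance if Ct data are provided, and write
#' every result table (stamped with the configuration hash) plus a run
#' manifest. Any stage failure aborts with the stage name attached.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with every in-memory result.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  hash <- config_hash(unclass(config))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(errorCondition(
        sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
        class = c("lnchcc_stage_failure", "lnchcc_error"),
        stage = name))
    })
  }

  imported <- run_stage("import", {
    dat <- read_expression(config$expression, config$design)
    ann <- read_probe_annotation(config$annotation)
    genes <- read_gene_models(config$gene_models)
    missing <- setdiff(rownames(dat$expression), ann$probe_id)
    if (length(missing) > 0) {
      abort_lnchcc(sprintf("%d probes lack annotation", length(missing)),
                   "bad_annotation")
    }
    list(dat = dat, ann = ann, genes = genes)
  })
  ann <- imported$ann[match(rownames(imported$dat$expression),
                            imported$ann$probe_id), ]
  .stage("import", "%d probes, %d samples, %d pairs, %d genes",
         nrow(imported$dat$expression), ncol(imported$dat$expression),
         nrow(imported$dat$design), nrow(imported$genes$genes))

  norm <- run_stage("normalize",
                    quantile_normalize(imported$dat$expression))
  .stage("normalize", "quantile-normalized %d arrays", ncol(norm))

  de <- run_stage("differential", {
    run_differential(norm, imported$dat$design, biotype = ann$biotype,
                     fc_min = config$fc_min, p_max = config$p_max,
                     q_max = config$q_max)
  })
  ratios <- per_pair_log2_ratio(norm, imported$dat$design)
  bins_lnc <- fc_bin_summary(ratios[ann$biotype == "lncRNA", , drop = FALSE],
                             bins = config$bins)
  bins_mrna <- fc_bin_summary(ratios[ann$biotype == "mRNA", , drop = FALSE],
                              bins = config$bins)
  .stage("differential", "%d lncRNA and %d mRNA probes called",
         sum(de$call != "ns" & de$biotype == "lncRNA"),
         sum(de$call != "ns" & de$biotype == "mRNA"))

  de_lnc <- de$probe_id[de$call != "ns" & de$biotype == "lncRNA"]
  de_mrna <- de$probe_id[de$call != "ns" & de$biotype == "mRNA"]

  calls <- run_stage("classify", {
    lnc_ann <- ann[ann$biotype == "lncRNA" &
                     de$call[match(ann$probe_id, de$probe_id)] != "ns", ,
                   drop = FALSE]
    if (nrow(lnc_ann) == 0) NULL else {
      classify_lncrnas(lnc_ann, imported$genes, window = config$window,
                       bidir_tss = config$bidir_tss)
    }
  })
  .stage("classify", "%d differential lncRNAs classified",
         if (is.null(calls)) 0L else nrow(calls))

  subgroups <- NULL
  if (!is.null(config$catalogs) && !is.null(calls)) {
    subgroups <- run_stage("subgroups", {
      lapply(config$catalogs, function(p) {
        subgroup_filter(calls, de, read_gene_set(p), ann)
      })
    })
  }

  net <- run_stage("network",
                   build_network(norm, de_lnc, de_mrna,
                                 r_min = config$r_min,
                                 p_max = config$cor_p_max))
  .stage("network", "%d edges over %d lncRNA and %d mRNA nodes",
         net$summary$n_edges, net$summary$n_lnc_nodes,
         net$summary$n_mrna_nodes)

  qpcr <- NULL
  if (!is.null(config$ct)) {
    qpcr <- run_stage("qpcr", {
      ct <- read_ct_table(config$ct)
      qr <- qpcr_log2_ratios(ct)
      shared <- intersect(rownames(qr), rownames(ratios))
      # NA when no patient has a nonzero ratio on both platforms
      conc <- vapply(shared, function(g) {
        pats <- intersect(colnames(qr), colnames(ratios))
        suppressWarnings(concordance(ratios[g, pats], qr[g, pats],
                                     rule = config$concordance_rule))
      }, logical(1))
      tests <- lapply(rownames(qr), function(g) paired_delta_ct_test(ct, g))
      list(log2_ratios = qr,
           tests = data.frame(gene_id = rownames(qr),
                              t = vapply(tests, `[[`, numeric(1), "t"),
                              p_value = vapply(tests, `[[`, numeric(1), "p"),
                              stringsAsFactors = FALSE),
           concordant = conc)
    })
    .stage("qpcr", "%d/%d assayed genes concordant with the arrays",
           sum(qpcr$concordant, na.rm = TRUE), length(qpcr$concordant))
  }

  run_stage("write", {
    out <- function(f) file.path(config$out_dir, f)
    write_expression(norm, out("normalized_expression.tsv"), hash)
    write_table_with_header(de, out("differential.tsv"), hash)
    write_table_with_header(rbind(cbind(biotype = "lncRNA", bins_lnc),
                                  cbind(biotype = "mRNA", bins_mrna)),
                            out("fold_change_bins.tsv"), hash)
    if (!is.null(calls)) {
      write_table_with_header(calls, out("positional_calls.tsv"), hash)
    }
    write_table_with_header(net$edges, out("network_edges.tsv"), hash)
    export_network(net$edges, graphml_path = out("network.graphml"))
    if (!is.null(qpcr)) {
      write_table_with_header(qpcr$tests, out("qpcr_tests.tsv"), hash)
      write_table_with_header(
        data.frame(gene_id = names(qpcr$concordant),
                   concordant = unname(qpcr$concordant)),
        out("qpcr_concordance.tsv"), hash)
    }
    manifest <- c(sprintf("package_version: %s",
                          as.character(utils::packageVersion("lnchcc"))),
                  sprintf("config_hash: %s", hash),
                  sprintf("seed: %d", config$seed))
    writeLines(manifest, out("manifest.txt"))
  })

  invisible(list(normalized = norm, differential = de,
                 bins = list(lncRNA = bins_lnc, mRNA = bins_mrna),
                 positional = calls, subgroups = subgroups, network = net,
                 qpcr = qpcr, hash = hash))
}
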