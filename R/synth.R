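#' Synthetic study configuration
#'
#' Parameters of the synthetic paired tumor/normal expression study. The
#' generator emulates a small two-channel-style microarray design: a handful
#' of patients each contributing one tumor and one matched normal array,
#' log-normal probe intensities, a planted fraction of up/down-regulated
#' probes, and planted near-perfectly correlated lncRNA-mRNA couples driven
#' by a shared per-sample latent factor.
#'
#' Intensities are generated on the log2 scale and exponentiated, which
#' guarantees positivity. The noise model is iid Gaussian per probe and
#' sample on the log2 scale, plus a per-array offset that quantile
#' normalization removes; per-patient probe-level baselines are deliberately
#' not modelled (see the methods vignette for why).
#'
#' @param n_patients number of tumor/normal pairs (default 3).
#' @param n_lnc_probes,n_mrna_probes probe counts per biotype.
#' @param frac_up,frac_down fractions of each biotype planted as up-/down-
#'   regulated. `frac_up + frac_down` must not exceed 1.
#' @param effect_log2_range interval from which planted |log2 fold changes|
#'   are drawn uniformly; the default spans the 2-4, 4-6 and >6 linear fold
#'   bins.
#' @param noise_sd residual standard deviation on the log2 scale.
#' @param n_coexpr_pairs number of planted lncRNA-mRNA couples whose members
#'   share a per-sample latent factor (target correlation above 0.995).
#' @param baseline_mean,baseline_sd mean and spread of per-probe log2
#'   baseline intensities.
#' @param array_offset_sd standard deviation of the per-array global log2
#'   offset (removed by quantile normalization).
#' @param couple_latent_sd,couple_noise_sd,couple_baseline_sd latent-factor
#'   spread, member-specific noise, and baseline spread of planted couples.
#'   Couple baselines sit mid-dynamic-range, where array quantification (and
#'   any qPCR follow-up) is reliable.
#' @param qpcr_ct_noise_sd cycle-threshold noise for the qPCR generator.
#' @param genome_length length in bp of the toy chromosome, or `NULL` to
#'   size it automatically from the number of features.
#' @param seed integer seed fixing the entire dataset.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_patients = 3L,
                         n_lnc_probes = 1000L,
                         n_mrna_probes = 1000L,
                         frac_up = 0.025,
                         frac_down = 0.025,
                         effect_log2_range = c(1, 3.5),
                         noise_sd = 0.2,
                         n_coexpr_pairs = 10L,
                         baseline_mean = 10,
                         baseline_sd = 2.5,
                         array_offset_sd = 0.25,
                         couple_latent_sd = 1.5,
                         couple_noise_sd = 0.02,
                         couple_baseline_sd = 1,
                         qpcr_ct_noise_sd = 0.1,
                         genome_length = NULL,
                         seed = 1L) {
  counts <- c(n_patients = n_patients, n_lnc_probes = n_lnc_probes,
              n_mrna_probes = n_mrna_probes)
  if (any(counts <= 0)) {
    abort_lnchcc("all counts (patients, probes) must be > 0", "bad_count")
  }
  if (frac_up < 0 || frac_down < 0 || frac_up + frac_down > 1) {
    abort_lnchcc("frac_up and frac_down must be >= 0 with frac_up + frac_down <= 1",
                 "bad_fraction")
  }
  if (noise_sd <= 0) abort_lnchcc("noise_sd must be > 0", "bad_noise")
  if (length(effect_log2_range) != 2 || any(effect_log2_range <= 0) ||
      diff(effect_log2_range) < 0) {
    abort_lnchcc("effect_log2_range must be an increasing positive interval",
                 "bad_effect_range")
  }
  if (n_coexpr_pairs < 0 ||
      n_coexpr_pairs > min(n_lnc_probes, n_mrna_probes)) {
    abort_lnchcc("n_coexpr_pairs must fit within both biotypes", "bad_count")
  }
  cfg <- list(n_patients = as.integer(n_patients),
              n_lnc_probes = as.integer(n_lnc_probes),
              n_mrna_probes = as.integer(n_mrna_probes),
              frac_up = frac_up, frac_down = frac_down,
              effect_log2_range = effect_log2_range,
              noise_sd = noise_sd,
              n_coexpr_pairs = as.integer(n_coexpr_pairs),
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              array_offset_sd = array_offset_sd,
              couple_latent_sd = couple_latent_sd,
              couple_noise_sd = couple_noise_sd,
              couple_baseline_sd = couple_baseline_sd,
              qpcr_ct_noise_sd = qpcr_ct_noise_sd,
              genome_length = genome_length,
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  cfg
}

#' Bundled benchmark configurations
#'
#' Two standard study designs exercised throughout the test suite and the
#' analysis scripts. `de_benchmark_config()` is the differential-expression
#' recovery benchmark: 3 patients, 160 probes per biotype, 25 up and 25 down
#' planted per biotype (100 differential probes in all) at |log2 FC| = 3 with
#' noise 0.2. `network_benchmark_config()` is the co-expression benchmark:
#' no planted differential signal, 10 planted couples against 1000 probes per
#' biotype of independent background noise, so pooled-array correlations can
#' be evaluated against a clean null. `null_benchmark_config()` plants
#' nothing and is used for type-I error calibration.
#'
#' The two signal benchmarks are deliberately separate: a large planted
#' shift moves the tumor-array intensity distributions, and the systematic
#' warp quantile normalization then applies both attenuates planted couples
#' and correlates the background, confounding a correlation-threshold check.
#'
#' @param seed integer seed.
#' @return a `synth_config`.
#' @export
de_benchmark_config <- function(seed = 1L) {
  synth_config(n_patients = 3L, n_lnc_probes = 160L, n_mrna_probes = 160L,
               frac_up = 25 / 160, frac_down = 25 / 160,
               effect_log2_range = c(3, 3), noise_sd = 0.2,
               n_coexpr_pairs = 0L, baseline_sd = 5, seed = seed)
}

#' @rdname de_benchmark_config
#' @export
network_benchmark_config <- function(seed = 1L) {
  synth_config(n_patients = 3L, n_lnc_probes = 1000L, n_mrna_probes = 1000L,
               frac_up = 0, frac_down = 0, n_coexpr_pairs = 10L,
               baseline_sd = 2.5, seed = seed)
}

#' @rdname de_benchmark_config
#' @export
null_benchmark_config <- function(seed = 1L) {
  synth_config(n_patients = 3L, n_lnc_probes = 250L, n_mrna_probes = 250L,
               frac_up = 0, frac_down = 0, n_coexpr_pairs = 0L, seed = seed)
}

probe_ids <- function(config) {
  c(sprintf("LNC%04d", seq_len(config$n_lnc_probes)),
    sprintf("MRNA%04d", seq_len(config$n_mrna_probes)))
}

#' Generate a synthetic paired expression study
#'
#' Draws probe baselines, plants up/down log2 effects on a random subset of
#' each biotype, plants co-expression couples sharing a per-sample latent
#' factor, adds iid log2 noise and per-array offsets, and exponentiates.
#' Regenerating with the same configuration (including seed) is bit
#' identical.
#'
#' @param config a [synth_config()].
#' @return a list with components:
#'   \describe{
#'     \item{expression}{probe x sample intensity matrix (linear scale).}
#'     \item{design}{data frame of (patient_id, tumor_sample_id,
#'       normal_sample_id).}
#'     \item{truth}{ground-truth list: `probes` (per-probe de_status
#'       up/down/null, planted log2 effect, biotype), `couples` (planted
#'       lncRNA-mRNA couple table).}
#'   }
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n_pat <- config$n_patients
  ids <- probe_ids(config)
  n_lnc <- config$n_lnc_probes
  n_mrna <- config$n_mrna_probes
  n_probe <- n_lnc + n_mrna
  biotype <- rep(c("lncRNA", "mRNA"), c(n_lnc, n_mrna))

  samples <- c(sprintf("T%d", seq_len(n_pat)), sprintf("N%d", seq_len(n_pat)))
  design <- data.frame(patient_id = sprintf("P%d", seq_len(n_pat)),
                       tumor_sample_id = sprintf("T%d", seq_len(n_pat)),
                       normal_sample_id = sprintf("N%d", seq_len(n_pat)),
                       stringsAsFactors = FALSE)
  tumor_ind <- rep(c(1, 0), each = n_pat)

  de_status <- rep("null", n_probe)
  effect <- numeric(n_probe)
  for (bt in c("lncRNA", "mRNA")) {
    idx <- which(biotype == bt)
    n_up <- round(config$frac_up * length(idx))
    n_dn <- round(config$frac_down * length(idx))
    pick <- sample(idx, n_up + n_dn)
    if (n_up > 0) {
      up <- pick[seq_len(n_up)]
      de_status[up] <- "up"
      effect[up] <- stats::runif(n_up, config$effect_log2_range[1],
                                 config$effect_log2_range[2])
    }
    if (n_dn > 0) {
      dn <- pick[n_up + seq_len(n_dn)]
      de_status[dn] <- "down"
      effect[dn] <- -stats::runif(n_dn, config$effect_log2_range[1],
                                  config$effect_log2_range[2])
    }
  }

  mu <- stats::rnorm(n_probe, config$baseline_mean, config$baseline_sd)
  log2x <- mu + outer(effect, tumor_ind) +
    matrix(stats::rnorm(n_probe * 2 * n_pat, 0, config$noise_sd),
           n_probe, 2 * n_pat)

  # couples: pick null probes of each biotype, overwrite with a shared latent
  k <- config$n_coexpr_pairs
  couples <- data.frame(pair_id = character(0), lnc_probe_id = character(0),
                        mrna_probe_id = character(0), stringsAsFactors = FALSE)
  if (k > 0) {
    lnc_null <- which(biotype == "lncRNA" & de_status == "null")
    mrna_null <- which(biotype == "mRNA" & de_status == "null")
    if (length(lnc_null) < k || length(mrna_null) < k) {
      abort_lnchcc("not enough null probes to host the requested couples",
                   "bad_count")
    }
    cl <- sample(lnc_null, k)
    cm <- sample(mrna_null, k)
    for (i in seq_len(k)) {
      base <- stats::rnorm(2, config$baseline_mean, config$couple_baseline_sd)
      latent <- stats::rnorm(2 * n_pat, 0, config$couple_latent_sd)
      log2x[cl[i], ] <- base[1] + latent +
        stats::rnorm(2 * n_pat, 0, config$couple_noise_sd)
      log2x[cm[i], ] <- base[2] + latent +
        stats::rnorm(2 * n_pat, 0, config$couple_noise_sd)
    }
    couples <- data.frame(pair_id = sprintf("CP%02d", seq_len(k)),
                          lnc_probe_id = ids[cl], mrna_probe_id = ids[cm],
                          stringsAsFactors = FALSE)
  }

  log2x <- sweep(log2x, 2, stats::rnorm(2 * n_pat, 0, config$array_offset_sd),
                 "+")
  expr <- 2 ^ log2x
  dimnames(expr) <- list(ids, samples)

  truth_probes <- data.frame(probe_id = ids, biotype = biotype,
                             de_status = de_status, effect_log2 = effect,
                             stringsAsFactors = FALSE)
  list(expression = expr, design = design,
       truth = list(probes = truth_probes, couples = couples))
}

# Positional categories in classifier vocabulary; the seventh slot places a
# lncRNA farther than the nearest-gene window from every gene (truth category
# intergenic with no nearby gene).
.category_cycle <- c("exon_sense_overlapping", "intron_sense_overlapping",
                     "natural_antisense", "intronic_antisense",
                     "bidirectional", "intergenic", "intergenic_far")

#' Generate toy genome annotation with known positional categories
#'
#' Lays lncRNAs and three-exon coding genes out on a single synthetic
#' chromosome so that every lncRNA realizes a known positional relationship
#' to its host gene: categories cycle through exon sense-overlapping, intron
#' sense-overlapping, natural antisense, intronic antisense, bidirectional
#' and intergenic, plus an isolated intergenic variant placed farther than
#' the nearest-gene window from every gene. Positional categories depend
#' only on relative geometry, so one chromosome suffices.
#'
#' Each feature cassette occupies its own `spacing`-bp stretch; host genes
#' are the first `n_mrna_probes` genes (probed as mRNAs), with unprobed
#' filler genes appended if more hosts than mRNA probes are needed.
#'
#' @param config a [synth_config()].
#' @param spacing bp between consecutive cassettes; must exceed twice the
#'   nearest-gene window for the isolated variant to stay isolated.
#' @return list with `annotation` (probe annotation data frame),
#'   `genes` (gene models, see [read_gene_models()] for the layout) and
#'   `truth` (per-lncRNA planted category, host gene and gap in bp;
#'   0-based half-open coordinates throughout).
#' @export
generate_annotation <- function(config, spacing = 7e5) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 104729L)  # decouple from the expression stream
  n_lnc <- config$n_lnc_probes
  n_mrna <- config$n_mrna_probes
  ids <- probe_ids(config)
  lnc_ids <- ids[seq_len(n_lnc)]
  mrna_ids <- ids[n_lnc + seq_len(n_mrna)]

  cats <- .category_cycle[(seq_len(n_lnc) - 1L) %% 7L + 1L]
  needs_gene <- cats != "intergenic_far"
  n_genes <- max(n_mrna, sum(needs_gene))
  n_cassettes <- n_lnc + max(0L, n_genes - sum(needs_gene))
  required <- (n_cassettes + 1) * spacing
  genome_length <- config$genome_length %||% required
  if (genome_length < required) {
    abort_lnchcc(sprintf(
      "genome_length %g too short: %d cassettes at %g bp need %g bp",
      genome_length, n_cassettes, spacing, required), "genome_too_short")
  }

  gene_id <- character(n_genes)
  gene_start <- numeric(n_genes); gene_end <- numeric(n_genes)
  gene_strand <- character(n_genes)
  exon_list <- vector("list", n_genes)
  lnc_start <- numeric(n_lnc); lnc_end <- numeric(n_lnc)
  lnc_strand <- character(n_lnc)
  truth_gene <- rep(NA_character_, n_lnc)
  truth_gap <- rep(NA_real_, n_lnc)

  g <- 0L  # gene counter
  cassette <- 0L
  new_gene <- function(offset) {
    # three 500-bp exons separated by 1000-bp introns, + strand
    list(start = offset, end = offset + 3500,
         exons = cbind(start = offset + c(0, 1500, 3000),
                       end = offset + c(500, 2000, 3500)))
  }
  for (i in seq_len(n_lnc)) {
    cassette <- cassette + 1L
    offset <- cassette * spacing
    cat_i <- cats[i]
    if (cat_i == "intergenic_far") {
      lnc_start[i] <- offset; lnc_end[i] <- offset + 800
      lnc_strand[i] <- "+"
      next
    }
    g <- g + 1L
    gm <- new_gene(offset)
    gene_id[g] <- sprintf("GENE%04d", g)
    gene_start[g] <- gm$start; gene_end[g] <- gm$end
    gene_strand[g] <- "+"
    exon_list[[g]] <- gm$exons
    truth_gene[i] <- gene_id[g]
    co <- switch(cat_i,
      exon_sense_overlapping  = list(s = offset + 100,   e = offset + 700,   st = "+", gap = 0),
      intron_sense_overlapping = list(s = offset + 600,  e = offset + 1400,  st = "+", gap = 0),
      natural_antisense       = list(s = offset + 1600,  e = offset + 2600,  st = "-", gap = 0),
      intronic_antisense      = list(s = offset + 2100,  e = offset + 2900,  st = "-", gap = 0),
      bidirectional           = list(s = offset - 800,   e = offset - 200,   st = "-", gap = 200),
      intergenic              = list(s = offset + 10000, e = offset + 11000, st = "+", gap = 6500))
    lnc_start[i] <- co$s; lnc_end[i] <- co$e
    lnc_strand[i] <- co$st
    truth_gap[i] <- co$gap
  }
  while (g < n_genes) {  # filler genes for remaining mRNA probes
    cassette <- cassette + 1L
    g <- g + 1L
    gm <- new_gene(cassette * spacing)
    gene_id[g] <- sprintf("GENE%04d", g)
    gene_start[g] <- gm$start; gene_end[g] <- gm$end
    gene_strand[g] <- "+"
    exon_list[[g]] <- gm$exons
  }

  exons <- do.call(rbind, lapply(seq_len(n_genes), function(j) {
    data.frame(gene_id = gene_id[j], start = exon_list[[j]][, "start"],
               end = exon_list[[j]][, "end"], stringsAsFactors = FALSE)
  }))
  genes <- list(
    genes = data.frame(gene_id = gene_id, chrom = "chrS", strand = gene_strand,
                       start = gene_start, end = gene_end,
                       tss = ifelse(gene_strand == "+", gene_start, gene_end),
                       stringsAsFactors = FALSE),
    exons = exons)

  annotation <- data.frame(
    probe_id = ids,
    transcript_id = c(sprintf("TLNC%04d", seq_len(n_lnc)), gene_id[seq_len(n_mrna)]),
    biotype = rep(c("lncRNA", "mRNA"), c(n_lnc, n_mrna)),
    chrom = "chrS",
    start = c(lnc_start, gene_start[seq_len(n_mrna)]),
    end = c(lnc_end, gene_end[seq_len(n_mrna)]),
    strand = c(lnc_strand, gene_strand[seq_len(n_mrna)]),
    category_source = "synthetic",
    stringsAsFactors = FALSE)

  truth <- data.frame(
    probe_id = lnc_ids,
    category = ifelse(cats == "intergenic_far", "intergenic", cats),
    nearby_gene_id = ifelse(cats == "intergenic_far", NA_character_, truth_gene),
    distance_bp = ifelse(cats == "intergenic_far", NA_real_, truth_gap),
    stringsAsFactors = FALSE)

  list(annotation = annotation, genes = genes, truth = truth,
       genome_length = genome_length)
}

#' Generate synthetic qPCR cycle-threshold measurements
#'
#' Emulates SYBR-style qPCR of selected genes in tumor/normal pairs under the
#' exact-doubling (efficiency 2) model implied by 2^-ddCt quantification:
#' `Ct = a_g - log2(expression) + noise`, with a reference gene of constant
#' expression. A probe planted with log2 fold change e therefore yields
#' ddCt = -e and a recovered fold of 2^e, exactly so at zero noise.
#'
#' @param truth ground-truth list from [generate_expression()].
#' @param config a [synth_config()]; `qpcr_ct_noise_sd` sets Ct noise.
#' @param gene_ids probes to assay; defaults to all planted differential
#'   probes.
#' @param n_patients number of tumor/normal pairs to simulate (the validation
#'   cohort may be larger than the array cohort).
#' @return data frame (patient_id, condition, gene_id, ct_target,
#'   ct_reference), one row per patient x condition x gene.
#' @export
generate_qpcr <- function(truth, config, gene_ids = NULL,
                          n_patients = config$n_patients) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 15485863L)
  probes <- truth$probes
  if (is.null(gene_ids)) gene_ids <- probes$probe_id[probes$de_status != "null"]
  missing <- setdiff(gene_ids, probes$probe_id)
  if (length(missing) > 0) {
    abort_lnchcc(paste("unknown gene ids:", paste(missing, collapse = ", ")),
                 "unknown_gene")
  }
  eff <- probes$effect_log2[match(gene_ids, probes$probe_id)]
  a <- stats::runif(length(gene_ids), 22, 30)  # per-gene Ct offset
  sdn <- config$qpcr_ct_noise_sd
  grid <- expand.grid(patient_id = sprintf("P%d", seq_len(n_patients)),
                      condition = c("tumor", "normal"),
                      gi = seq_along(gene_ids),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(grid)
  shift <- ifelse(grid$condition == "tumor", eff[grid$gi], 0)
  data.frame(patient_id = grid$patient_id,
             condition = grid$condition,
             gene_id = gene_ids[grid$gi],
             ct_target = a[grid$gi] - shift + stats::rnorm(n, 0, sdn),
             ct_reference = 15 + stats::rnorm(n, 0, sdn),
             stringsAsFactors = FALSE)
}

#' Write a full synthetic dataset to disk
#'
#' Emits, in the same formats the pipeline reads: expression TSV, design CSV,
#' probe annotation TSV, BED12 gene models, qPCR Ct CSV, the configuration as
#' YAML and the ground truth as TSVs (for test harnesses).
#'
#' @param config a [synth_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, the list of generated objects.
#' @export
simulate_study <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(unclass(config))
  ex <- generate_expression(config)
  an <- generate_annotation(config)
  ct <- generate_qpcr(ex$truth, config)
  write_expression(ex$expression, file.path(dir, "expression.tsv"), hash)
  write_design(ex$design, file.path(dir, "design.csv"), hash)
  write_probe_annotation(an$annotation, file.path(dir, "annotation.tsv"), hash)
  write_gene_models_bed(an$genes, file.path(dir, "genes.bed"))
  write_ct_table(ct, file.path(dir, "qpcr_ct.csv"), hash)
  yaml::write_yaml(unclass(config), file.path(dir, "config.yaml"))
  write_table_with_header(ex$truth$probes, file.path(dir, "truth_probes.tsv"), hash)
  write_table_with_header(ex$truth$couples, file.path(dir, "truth_couples.tsv"), hash)
  write_table_with_header(an$truth, file.path(dir, "truth_positions.tsv"), hash)
  invisible(list(expression = ex, annotation = an, qpcr = ct, hash = hash))
}
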