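#' Read a probe expression matrix and its paired design
#'
#' The expression file is tab-separated with a header row of sample ids and
#' probe ids in the first column; the design file is a CSV with columns
#' patient_id, tumor_sample_id, normal_sample_id. Lines starting with `#` are
#' ignored in both. Import is strict: duplicate probe or sample ids,
#' non-numeric cells, non-positive intensities and design samples absent
#' from the matrix each raise a distinct classed error and no partial result
#' is returned.
#'
#' @param path expression TSV.
#' @param design_path design CSV.
#' @param floor_intensities if `TRUE`, intensities <= 0 are floored to the
#'   smallest positive value in the matrix instead of being rejected
#'   (log2 transforms downstream require positivity).
#' @return list with `expression` (numeric matrix, probes x samples) and
#'   `design` (data frame).
#' @export
read_expression <- function(path, design_path, floor_intensities = FALSE) {
  raw <- read_table_skip_comments(path)
  probe_ids <- as.character(raw[[1]])
  if (anyDuplicated(probe_ids)) {
    abort_lnchcc("duplicate probe ids in expression matrix", "duplicate_ids")
  }
  mat <- as.matrix(raw[, -1, drop = FALSE])
  if (anyDuplicated(colnames(mat))) {
    abort_lnchcc("duplicate sample ids in expression matrix", "duplicate_ids")
  }
  if (!is.numeric(mat)) {
    abort_lnchcc("non-numeric intensity cell in expression matrix",
                 "non_numeric")
  }
  if (any(!is.finite(mat))) {
    abort_lnchcc("non-finite intensity in expression matrix", "non_numeric")
  }
  rownames(mat) <- probe_ids
  if (any(mat <= 0)) {
    if (floor_intensities) {
      mat[mat <= 0] <- min(mat[mat > 0])
    } else {
      abort_lnchcc("non-positive intensities present (set floor_intensities = TRUE to floor them)",
                   "nonpositive_intensity")
    }
  }
  design <- read_design(design_path)
  referenced <- c(design$tumor_sample_id, design$normal_sample_id)
  absent <- setdiff(referenced, colnames(mat))
  if (length(absent) > 0) {
    abort_lnchcc(paste("design references samples absent from the matrix:",
                       paste(absent, collapse = ", ")), "missing_sample")
  }
  if (anyDuplicated(referenced)) {
    abort_lnchcc("a sample is referenced more than once in the design",
                 "duplicate_ids")
  }
  message(sprintf("imported %d probes x %d samples, %d pairs",
                  nrow(mat), ncol(mat), nrow(design)))
  list(expression = mat, design = design)
}

#' @rdname read_expression
#' @export
read_design <- function(design_path) {
  design <- read_table_skip_comments(design_path, sep = ",")
  need <- c("patient_id", "tumor_sample_id", "normal_sample_id")
  if (!all(need %in% names(design))) {
    abort_lnchcc(paste("design must have columns:", paste(need, collapse = ", ")),
                 "bad_design")
  }
  design[need]
}

#' Writers for pipeline artifacts
#'
#' All tabular writers stamp a `#` comment header carrying the package
#' version and a configuration hash so outputs from different runs are
#' distinguishable.
#'
#' @param expression probe x sample matrix.
#' @param path output file.
#' @param hash configuration hash (see [config_hash()]).
#' @export
write_expression <- function(expression, path, hash = NULL) {
  df <- data.frame(probe_id = rownames(expression), expression,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_table_with_header(df, path, hash)
}

#' @rdname write_expression
#' @param design design data frame.
#' @export
write_design <- function(design, path, hash = NULL) {
  write_table_with_header(design, path, hash, sep = ",")
}

#' @rdname write_expression
#' @param annotation probe annotation data frame.
#' @export
write_probe_annotation <- function(annotation, path, hash = NULL) {
  write_table_with_header(annotation, path, hash)
}

#' Read a probe annotation table
#'
#' Expects columns probe_id, transcript_id, biotype (lncRNA|mRNA), chrom,
#' start, end, strand; coordinates are 0-based half-open (BED convention).
#' Probe-to-transcript mapping must be 1:1; multi-mapping probes are
#' rejected.
#'
#' @param path annotation TSV.
#' @return validated data frame.
#' @export
read_probe_annotation <- function(path) {
  ann <- read_table_skip_comments(path)
  need <- c("probe_id", "transcript_id", "biotype", "chrom", "start", "end",
            "strand")
  if (!all(need %in% names(ann))) {
    abort_lnchcc(paste("annotation must have columns:",
                       paste(need, collapse = ", ")), "bad_annotation")
  }
  if (anyDuplicated(ann$probe_id)) {
    abort_lnchcc("multi-mapping probes: duplicated probe_id in annotation",
                 "duplicate_ids")
  }
  if (!all(ann$biotype %in% c("lncRNA", "mRNA"))) {
    abort_lnchcc("biotype must be lncRNA or mRNA", "bad_annotation")
  }
  if (any(ann$start >= ann$end)) {
    abort_lnchcc("annotation intervals must satisfy start < end",
                 "bad_coordinates")
  }
  if (!all(ann$strand %in% c("+", "-"))) {
    abort_lnchcc("strand must be + or -", "bad_annotation")
  }
  ann
}

#' Read coding-gene models from BED12 or GFF3
#'
#' Returns gene models in the package's internal layout: a list with
#' `genes` (gene_id, chrom, strand, start, end, tss) and `exons`
#' (gene_id, start, end). Coordinates are 0-based half-open; GFF3 input
#' (1-based closed) is converted on read. The TSS is the interval start on
#' the + strand and the interval end on the - strand. Exons must be sorted,
#' non-overlapping and contained in the transcript span.
#'
#' @param path a `.bed` (BED12) or `.gff`/`.gff3` file.
#' @return gene model list.
#' @export
read_gene_models <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "bed") {
    .validate_bed12_lines(path)
    gr <- rtracklayer::import(path, format = "BED")
    blocks <- gr$blocks
    genes <- data.frame(
      gene_id = gr$name,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      stringsAsFactors = FALSE)
    exons <- do.call(rbind, lapply(seq_along(gr), function(i) {
      b <- blocks[[i]]  # block starts are transcript-relative 1-based
      data.frame(gene_id = gr$name[i],
                 start = genes$start[i] + IRanges::start(b) - 1L,
                 end = genes$start[i] + IRanges::end(b),
                 stringsAsFactors = FALSE)
    }))
  } else if (ext %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(path, format = "GFF3")
    type <- as.character(gr$type)
    tx <- gr[type %in% c("gene", "transcript", "mRNA")]
    ex <- gr[type == "exon"]
    tx_ids <- as.character(tx$ID)
    parent <- as.character(S4Vectors::unstrsplit(ex$Parent))
    genes <- data.frame(
      gene_id = tx_ids,
      chrom = as.character(GenomicRanges::seqnames(tx)),
      strand = as.character(GenomicRanges::strand(tx)),
      start = GenomicRanges::start(tx) - 1L,
      end = GenomicRanges::end(tx),
      stringsAsFactors = FALSE)
    exons <- data.frame(gene_id = parent,
                        start = GenomicRanges::start(ex) - 1L,
                        end = GenomicRanges::end(ex),
                        stringsAsFactors = FALSE)
  } else {
    abort_lnchcc("gene models must be .bed (BED12) or .gff3", "bad_format")
  }
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  exons <- exons[order(match(exons$gene_id, genes$gene_id), exons$start), ]
  rownames(genes) <- rownames(exons) <- NULL
  .validate_gene_models(genes, exons)
  list(genes = genes, exons = exons)
}

# Pre-validate BED lines so malformed coordinates are reported with their
# line number (the generic importer error would not say where).
.validate_bed12_lines <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t")[[1]]
    if (length(f) < 12) {
      abort_lnchcc(sprintf("line %d: expected 12 BED fields, found %d",
                           i, length(f)), "malformed_line")
    }
    if (is.na(suppressWarnings(as.numeric(f[2]))) ||
        is.na(suppressWarnings(as.numeric(f[3])))) {
      abort_lnchcc(sprintf("line %d: non-numeric chromStart/chromEnd", i),
                   "malformed_line")
    }
  }
  invisible(TRUE)
}

.validate_gene_models <- function(genes, exons) {
  if (any(genes$start >= genes$end)) {
    abort_lnchcc("gene interval with start >= end", "bad_coordinates")
  }
  for (gid in genes$gene_id) {
    e <- exons[exons$gene_id == gid, ]
    g <- genes[genes$gene_id == gid, ]
    if (nrow(e) == 0) abort_lnchcc(paste("gene without exons:", gid),
                                   "bad_coordinates")
    if (any(e$start < g$start | e$end > g$end)) {
      abort_lnchcc(paste("exon outside transcript span for", gid),
                   "bad_coordinates")
    }
    if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)])) {
      abort_lnchcc(paste("overlapping or unsorted exons for", gid),
                   "bad_coordinates")
    }
  }
  invisible(TRUE)
}

#' Write gene models as BED12
#'
#' @param models gene model list (`genes` + `exons`).
#' @param path output `.bed` path.
#' @export
write_gene_models_bed <- function(models, path) {
  g <- models$genes
  lines <- vapply(seq_len(nrow(g)), function(i) {
    e <- models$exons[models$exons$gene_id == g$gene_id[i], , drop = FALSE]
    sizes <- paste0(paste(e$end - e$start, collapse = ","), ",")
    starts <- paste0(paste(e$start - g$start[i], collapse = ","), ",")
    paste(g$chrom[i], format(g$start[i], scientific = FALSE),
          format(g$end[i], scientific = FALSE), g$gene_id[i], 0, g$strand[i],
          format(g$start[i], scientific = FALSE),
          format(g$end[i], scientific = FALSE), "0", nrow(e), sizes, starts,
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain-text gene set
#'
#' One identifier per line; blank lines and `#` comments are skipped.
#' Unknown ids are preserved verbatim (catalogs may reference transcripts
#' outside the probe content).
#'
#' @param path gene-set file.
#' @return character vector of ids.
#' @export
read_gene_set <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !grepl("^#", x)]
}

#' Read/write qPCR cycle-threshold tables
#'
#' CSV with columns patient_id, condition (tumor|normal), gene_id,
#' ct_target, ct_reference.
#'
#' @param path Ct CSV.
#' @return validated data frame.
#' @export
read_ct_table <- function(path) {
  ct <- read_table_skip_comments(path, sep = ",")
  need <- c("patient_id", "condition", "gene_id", "ct_target", "ct_reference")
  if (!all(need %in% names(ct))) {
    abort_lnchcc(paste("Ct table must have columns:", paste(need, collapse = ", ")),
                 "bad_ct_table")
  }
  if (!all(ct$condition %in% c("tumor", "normal"))) {
    abort_lnchcc("condition must be tumor or normal", "bad_ct_table")
  }
  ct
}

#' @rdname read_ct_table
#' @param ct Ct data frame.
#' @param hash configuration hash.
#' @export
write_ct_table <- function(ct, path, hash = NULL) {
  write_table_with_header(ct, path, hash, sep = ",")
}
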