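# Positional classification of lncRNAs relative to coding-gene models.
#
# Category vocabulary (single label per lncRNA, chosen by precedence):
#   exon_sense_overlapping > intron_sense_overlapping > natural_antisense >
#   intronic_antisense > bidirectional > intergenic.
# Overlap evidence outranks promoter geometry and sense outranks antisense.

.category_levels <- c("exon_sense_overlapping", "intron_sense_overlapping",
                      "natural_antisense", "intronic_antisense",
                      "bidirectional", "intergenic")

.gene_granges <- function(models) {
  g <- models$genes
  GenomicRanges::GRanges(g$chrom,
                         IRanges::IRanges(g$start + 1L, g$end),
                         strand = g$strand, gene_id = g$gene_id,
                         tss = g$tss)
}

.exon_granges <- function(models) {
  e <- models$exons
  strand <- models$genes$strand[match(e$gene_id, models$genes$gene_id)]
  chrom <- models$genes$chrom[match(e$gene_id, models$genes$gene_id)]
  GenomicRanges::GRanges(chrom, IRanges::IRanges(e$start + 1L, e$end),
                         strand = strand, gene_id = e$gene_id)
}

#' Classify lncRNA genomic position relative to coding genes
#'
#' Assigns each lncRNA exactly one of six categories describing its
#' relationship to the coding-gene models:
#' \itemize{
#'   \item exon_sense_overlapping: same-strand overlap touching at least one
#'     exon;
#'   \item intron_sense_overlapping: same-strand overlap with a gene but
#'     with no exon contact (the lncRNA lies within an intron);
#'   \item natural_antisense: opposite-strand overlap touching at least one
#'     exon;
#'   \item intronic_antisense: opposite-strand overlap wholly within an
#'     intron;
#'   \item bidirectional: no gene overlap, but an opposite-strand gene
#'     whose TSS lies within `bidir_tss` bp of the lncRNA TSS (a shared
#'     divergent promoter);
#'   \item intergenic: none of the above.
#' }
#' When several relations hold (multiple genes), precedence is
#' exon sense > intron sense > natural antisense > intronic antisense >
#' bidirectional > intergenic. Each call also carries the nearest coding
#' gene within `window` bp (see [nearest_coding_gene()]).
#'
#' @param lnc_annotation probe annotation rows for lncRNAs (0-based
#'   half-open start/end, strand).
#' @param models gene models from [read_gene_models()].
#' @param window nearest-gene search window in bp (strict `<`).
#' @param bidir_tss TSS-to-TSS distance defining a bidirectional pair.
#' @return data frame: lnc probe/transcript ids, category, nearby_gene_id
#'   (NA if none within the window), distance_bp.
#' @export
classify_lncrnas <- function(lnc_annotation, models, window = 3e5,
                             bidir_tss = 1000) {
  known <- unique(models$genes$chrom)
  if (!all(lnc_annotation$chrom %in% known)) {
    abort_lnchcc("lncRNA on a chromosome absent from the gene models",
                 "unknown_chromosome")
  }
  lnc <- GenomicRanges::GRanges(
    lnc_annotation$chrom,
    IRanges::IRanges(lnc_annotation$start + 1L, lnc_annotation$end),
    strand = lnc_annotation$strand)
  genes <- .gene_granges(models)
  exons <- .exon_granges(models)
  lnc_tss <- ifelse(lnc_annotation$strand == "+", lnc_annotation$start,
                    lnc_annotation$end)

  same_strand <- function(q, s, hits) {
    as.character(GenomicRanges::strand(q))[S4Vectors::queryHits(hits)] ==
      as.character(GenomicRanges::strand(s))[S4Vectors::subjectHits(hits)]
  }
  gh <- GenomicRanges::findOverlaps(lnc, genes, ignore.strand = TRUE)
  eh <- GenomicRanges::findOverlaps(lnc, exons, ignore.strand = TRUE)
  gh_sense <- same_strand(lnc, genes, gh)
  eh_sense <- same_strand(lnc, exons, eh)

  n <- length(lnc)
  has <- function(hits, keep) tabulate(S4Vectors::queryHits(hits)[keep], n) > 0
  exon_s <- has(eh, eh_sense)
  exon_a <- has(eh, !eh_sense)
  gene_s <- has(gh, gh_sense)
  gene_a <- has(gh, !gh_sense)

  # bidirectional: no overlap at all, opposite-strand TSS within bidir_tss
  overlap_any <- gene_s | gene_a
  bidir <- rep(FALSE, n)
  cand <- which(!overlap_any)
  if (length(cand) > 0) {
    for (i in cand) {
      opp <- models$genes$strand != lnc_annotation$strand[i] &
        models$genes$chrom == lnc_annotation$chrom[i]
      bidir[i] <- any(abs(models$genes$tss[opp] - lnc_tss[i]) <= bidir_tss)
    }
  }

  category <- rep("intergenic", n)
  category[bidir] <- "bidirectional"
  category[gene_a & !exon_a] <- "intronic_antisense"
  category[exon_a] <- "natural_antisense"
  category[gene_s & !exon_s] <- "intron_sense_overlapping"
  category[exon_s] <- "exon_sense_overlapping"

  near <- nearest_coding_gene(lnc_annotation, models, window = window)
  out <- data.frame(probe_id = lnc_annotation$probe_id,
                    transcript_id = lnc_annotation$transcript_id,
                    category = category,
                    nearby_gene_id = near$gene_id,
                    distance_bp = near$distance_bp,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Nearest coding gene within a window
#'
#' For each lncRNA, the gene minimizing the inter-interval gap (0 when
#' overlapping); `NA` when the minimum gap is not strictly below `window`.
#' Equidistant candidates are broken by lexicographically smaller gene id
#' for determinism.
#'
#' @param lnc_annotation lncRNA annotation rows (0-based half-open).
#' @param models gene models.
#' @param window distance window in bp, strict `<`.
#' @return data frame with `gene_id` and `distance_bp` per lncRNA.
#' @export
nearest_coding_gene <- function(lnc_annotation, models, window = 3e5) {
  g <- models$genes
  n <- nrow(lnc_annotation)
  gene_id <- rep(NA_character_, n)
  dist_bp <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    on_chr <- g$chrom == lnc_annotation$chrom[i]
    if (!any(on_chr)) next
    gc <- g[on_chr, ]
    gap <- pmax(0, pmax(gc$start - lnc_annotation$end[i],
                        lnc_annotation$start[i] - gc$end))
    best <- min(gap)
    if (best < window) {
      cand <- gc$gene_id[gap == best]
      gene_id[i] <- sort(cand)[1]
      dist_bp[i] <- best
    }
  }
  data.frame(gene_id = gene_id, distance_bp = dist_bp,
             stringsAsFactors = FALSE)
}

#' Catalog subgroup filter
#'
#' Given positional calls, differential results for both biotypes and a
#' user-supplied catalog of lncRNA ids (e.g. an enhancer-like or lincRNA
#' list), reports the catalog members that are differentially expressed and,
#' among those, the ones whose nearest coding gene (within the window used
#' for classification) is itself differentially expressed.
#'
#' @param calls positional calls from [classify_lncrnas()].
#' @param de_results differential table from [run_differential()]; the
#'   lncRNA rows are matched by probe_id, the mRNA rows by probe_id against
#'   the gene's transcript.
#' @param catalog character vector of lncRNA probe ids.
#' @param annotation probe annotation (to map mRNA probes to transcripts).
#' @return list: `n_catalog_de`, `n_with_de_neighbor`, and the filtered
#'   per-lncRNA table.
#' @export
subgroup_filter <- function(calls, de_results, catalog, annotation) {
  if (length(catalog) == 0) {
    warning("empty catalog: returning an empty result")
    return(list(n_catalog_de = 0L, n_with_de_neighbor = 0L,
                table = calls[0, ]))
  }
  de_ids <- de_results$probe_id[de_results$call != "ns"]
  members <- intersect(catalog, calls$probe_id)
  de_members <- intersect(members, de_ids)
  tab <- calls[calls$probe_id %in% de_members, , drop = FALSE]
  # a neighbor gene is DE if any DE mRNA probe maps to its transcript
  de_tx <- annotation$transcript_id[annotation$probe_id %in% de_ids &
                                      annotation$biotype == "mRNA"]
  tab$neighbor_de <- !is.na(tab$nearby_gene_id) &
    tab$nearby_gene_id %in% de_tx
  list(n_catalog_de = length(de_members),
       n_with_de_neighbor = sum(tab$neighbor_de),
       table = tab)
}
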