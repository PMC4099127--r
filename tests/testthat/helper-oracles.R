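# Independent oracles used across the test files. These deliberately avoid
# the package's own code paths (and, where possible, the same stats:: entry
# points) so that implementation and oracle can only agree by being correct.

# Two-sided p for a one-sample t statistic with df = 2, fully closed form:
# P(|T_2| > t) = 1 - t / sqrt(t^2 + 2).
oracle_t_p_df2 <- function(t) 1 - abs(t) / sqrt(t ^ 2 + 2)

# Two-sided p for a one-sample t-test via the incomplete-beta route,
# any df: P(|T| > t) = I_{df/(df+t^2)}(df/2, 1/2).
oracle_t_p <- function(t, df) stats::pbeta(df / (df + t ^ 2), df / 2, 1 / 2)

# Null tail of the Pearson coefficient at n = 6: the null density of r is
# (3/4)(1 - r^2) on [-1, 1], so P(|r| >= r0) = 1 - (3/2)(r0 - r0^3/3).
oracle_cor_p_n6 <- function(r0) 1 - 1.5 * (abs(r0) - abs(r0) ^ 3 / 3)

# Hand-rolled Benjamini-Hochberg step-up.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# Brute-force positional classifier over plain data frames (0-based
# half-open coordinates), scanning genes one by one and keeping the
# highest-precedence relation.
oracle_classify <- function(lnc, genes, exons, bidir_tss = 1000) {
  ranks <- c(exon_sense_overlapping = 1, intron_sense_overlapping = 2,
             natural_antisense = 3, intronic_antisense = 4,
             bidirectional = 5, intergenic = 6)
  best <- "intergenic"
  for (j in seq_len(nrow(genes))) {
    g <- genes[j, ]
    if (g$chrom != lnc$chrom) next
    if (lnc$start < g$end && g$start < lnc$end) {
      e <- exons[exons$gene_id == g$gene_id, ]
      exon_hit <- any(lnc$start < e$end & e$start < lnc$end)
      sense <- g$strand == lnc$strand
      cat_j <- if (sense && exon_hit) "exon_sense_overlapping"
      else if (sense) "intron_sense_overlapping"
      else if (exon_hit) "natural_antisense"
      else "intronic_antisense"
      if (ranks[cat_j] < ranks[best]) best <- cat_j
    }
  }
  if (best == "intergenic") {
    lnc_tss <- if (lnc$strand == "+") lnc$start else lnc$end
    opp <- genes$chrom == lnc$chrom & genes$strand != lnc$strand
    if (any(abs(genes$tss[opp] - lnc_tss) <= bidir_tss)) best <- "bidirectional"
  }
  best
}

# Brute-force nearest gene: minimum inter-interval gap, strict window,
# lexicographic tie-break.
oracle_nearest <- function(lnc, genes, window = 3e5) {
  on_chr <- genes[genes$chrom == lnc$chrom, ]
  if (nrow(on_chr) == 0) return(list(gene_id = NA_character_, gap = NA_real_))
  gap <- pmax(0, pmax(on_chr$start - lnc$end, lnc$start - on_chr$end))
  best <- min(gap)
  if (best >= window) return(list(gene_id = NA_character_, gap = NA_real_))
  list(gene_id = sort(on_chr$gene_id[gap == best])[1], gap = best)
}

# Random toy gene-model set on one chromosome, in the package's internal
# layout, for randomized classifier comparisons.
random_models <- function(n_genes = 3) {
  starts <- sort(sample.int(50000, n_genes)) + c(0, cumsum(rep(0, n_genes - 1)))
  genes <- data.frame(gene_id = sprintf("G%02d", seq_len(n_genes)),
                      chrom = "chrT",
                      strand = sample(c("+", "-"), n_genes, replace = TRUE),
                      start = starts,
                      end = starts + sample(2000:8000, n_genes, replace = TRUE),
                      stringsAsFactors = FALSE)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  exons <- do.call(rbind, lapply(seq_len(n_genes), function(j) {
    span <- genes$end[j] - genes$start[j]
    n_ex <- sample(1:3, 1)
    # carve non-overlapping sorted exons out of the span
    cuts <- sort(sample.int(span - 1, 2 * n_ex))
    data.frame(gene_id = genes$gene_id[j],
               start = genes$start[j] + cuts[seq(1, 2 * n_ex, by = 2)],
               end = genes$start[j] + cuts[seq(2, 2 * n_ex, by = 2)],
               stringsAsFactors = FALSE)
  }))
  list(genes = genes, exons = exons)
}

random_lnc <- function() {
  s <- sample.int(60000, 1)
  data.frame(probe_id = "LNC0001", transcript_id = "TLNC0001",
             chrom = "chrT", start = s, end = s + sample(200:5000, 1),
             strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
}
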