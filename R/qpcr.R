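# Relative quantification by the 2^-ddCt method and concordance scoring.

.ct_lookup <- function(ct, patient, gene, condition, column) {
  row <- ct$patient_id == patient & ct$gene_id == gene &
    ct$condition == condition
  if (!any(row)) {
    abort_lnchcc(sprintf("missing Ct cell: patient %s, gene %s, %s %s",
                         patient, gene, condition, column), "missing_ct")
  }
  # technical replicates averaged on the Ct scale
  mean(ct[[column]][row])
}

#' Relative expression by 2^-ddCt
#'
#' For one patient and gene: `dCt = Ct_target - Ct_reference` in each
#' condition, `ddCt = dCt(tumor) - dCt(normal)`, fold `= 2^-ddCt` (exact
#' doubling per cycle), `log2_ratio = -ddCt`. Reference-gene normalization
#' makes the result invariant to any constant shift of a patient's Ct
#' values.
#'
#' @param ct Ct table (patient_id, condition, gene_id, ct_target,
#'   ct_reference); technical replicates are averaged on the Ct scale.
#' @param patient,gene identifiers selecting the measurement.
#' @return list with `delta_delta_ct`, `fold` and `log2_ratio`.
#' @export
ddct_fold <- function(ct, patient, gene) {
  dct_t <- .ct_lookup(ct, patient, gene, "tumor", "ct_target") -
    .ct_lookup(ct, patient, gene, "tumor", "ct_reference")
  dct_n <- .ct_lookup(ct, patient, gene, "normal", "ct_target") -
    .ct_lookup(ct, patient, gene, "normal", "ct_reference")
  ddct <- dct_t - dct_n
  list(delta_delta_ct = ddct, fold = 2 ^ -ddct, log2_ratio = -ddct)
}

#' Per-patient qPCR log2 ratios for every gene
#'
#' @param ct Ct table.
#' @return matrix genes x patients of `-ddCt` (log2 tumor/normal).
#' @export
qpcr_log2_ratios <- function(ct) {
  genes <- unique(ct$gene_id)
  patients <- unique(ct$patient_id)
  out <- matrix(NA_real_, length(genes), length(patients),
                dimnames = list(genes, patients))
  for (g in genes) for (p in patients) {
    out[g, p] <- ddct_fold(ct, p, g)$log2_ratio
  }
  out
}

#' Paired t-test on delta-Ct values
#'
#' Two-sided paired t-test of per-patient tumor vs normal dCt for one gene
#' (equivalent to testing the mean ddCt against 0).
#'
#' @param ct Ct table.
#' @param gene gene id.
#' @return list with `t`, `p` and `degenerate` (see [paired_t_test()]);
#'   the sign convention follows dCt, so lower tumor dCt (higher
#'   expression) gives negative t.
#' @export
paired_delta_ct_test <- function(ct, gene) {
  patients <- unique(ct$patient_id[ct$gene_id == gene])
  if (length(patients) < 2) {
    abort_lnchcc("paired dCt test needs >= 2 patients", "too_few_pairs")
  }
  ddct <- vapply(patients, function(p) ddct_fold(ct, p, gene)$delta_delta_ct,
                 numeric(1))
  paired_t_test(ddct)
}

#' Microarray/qPCR concordance of per-patient log2 ratios
#'
#' A gene is concordant when its per-patient qPCR log2 ratios agree in sign
#' with the microarray log2 ratios: under the default majority rule, in
#' more than half of the patients with nonzero values on both platforms;
#' under the all-signs rule, in every such patient. Patients with a zero on
#' either platform are excluded from the vote.
#'
#' @param microarray,qpcr numeric vectors of per-patient log2 ratios.
#' @param rule "majority" (default) or "all-signs".
#' @return `TRUE` (concordant) or `FALSE`; `NA` when no patient is
#'   informative.
#' @export
concordance <- function(microarray, qpcr, rule = c("majority", "all-signs")) {
  rule <- match.arg(rule)
  if (length(microarray) != length(qpcr)) {
    abort_lnchcc("patient sets must match between platforms", "bad_input")
  }
  use <- microarray != 0 & qpcr != 0 & is.finite(microarray) & is.finite(qpcr)
  if (!any(use)) {
    warning("no informative patients (all-zero ratios)")
    return(NA)
  }
  agree <- sign(microarray[use]) == sign(qpcr[use])
  if (rule == "majority") mean(agree) > 0.5 else all(agree)
}

#' Sign agreement between lncRNAs and their nearby coding genes
#'
#' For each (lncRNA, neighbor gene) pair, the fraction of patients in which
#' the two log2 ratios share a sign, plus their Pearson correlation across
#' patients — the cis-regulation trend check applied to validated
#' lncRNA/neighbor couples.
#'
#' @param lnc_ratios,gene_ratios numeric matrices (pairs x patients), rows
#'   aligned pairwise.
#' @return data frame with `sign_agreement` and `r` per pair.
#' @export
nearby_gene_concordance <- function(lnc_ratios, gene_ratios) {
  stopifnot(all(dim(lnc_ratios) == dim(gene_ratios)))
  n <- nrow(lnc_ratios)
  agreement <- numeric(n)
  r <- numeric(n)
  for (i in seq_len(n)) {
    x <- lnc_ratios[i, ]; y <- gene_ratios[i, ]
    use <- x != 0 & y != 0
    agreement[i] <- if (any(use)) mean(sign(x[use]) == sign(y[use])) else NA
    r[i] <- if (stats::sd(x) > 0 && stats::sd(y) > 0) stats::cor(x, y) else NA
  }
  data.frame(pair = rownames(lnc_ratios) %||% seq_len(n),
             sign_agreement = agreement, r = r, stringsAsFactors = FALSE)
}
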