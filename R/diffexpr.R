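#' Quantile normalization
#'
#' Forces every array to share one intensity distribution: each column's
#' sorted values are replaced by the across-array means of the order
#' statistics (delegated to [limma::normalizeQuantiles()]). Works on the
#' linear intensity scale; row and column labels are preserved. The
#' operation is idempotent and a fixed point when all columns are already
#' identical.
#'
#' @param x probe x sample matrix of positive intensities.
#' @return normalized matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort_lnchcc("expression must be a numeric matrix", "bad_matrix")
  }
  if (ncol(x) < 2) {
    warning("single-sample matrix: quantile normalization is a no-op")
    return(x)
  }
  out <- limma::normalizeQuantiles(x)
  dimnames(out) <- dimnames(x)
  out
}

#' Per-pair log2 tumor/normal ratios
#'
#' For each probe and patient, `log2(tumor intensity) - log2(normal
#' intensity)` on the (normalized) expression matrix.
#'
#' @param expression probe x sample matrix (positive).
#' @param design paired design data frame.
#' @return probe x patient matrix of log2 ratios.
#' @export
per_pair_log2_ratio <- function(expression, design) {
  t_idx <- match(design$tumor_sample_id, colnames(expression))
  n_idx <- match(design$normal_sample_id, colnames(expression))
  if (any(is.na(t_idx)) || any(is.na(n_idx))) {
    abort_lnchcc("design references samples absent from the matrix",
                 "missing_sample")
  }
  if (any(expression[, c(t_idx, n_idx)] <= 0)) {
    abort_lnchcc("non-positive intensity: log2 ratio undefined",
                 "nonpositive_intensity")
  }
  ratios <- log2(expression[, t_idx, drop = FALSE]) -
    log2(expression[, n_idx, drop = FALSE])
  colnames(ratios) <- design$patient_id
  ratios
}

#' Paired t-test on per-pair log2 ratios
#'
#' Two-sided one-sample t-test of the per-patient log2 ratios against 0
#' (equivalent to the paired t-test on log2 tumor vs normal), with
#' `n_pairs - 1` degrees of freedom. Degenerate inputs: all ratios equal to
#' zero gives t = 0, p = 1; zero variance with a nonzero mean is the
#' infinite-t limit, returned as p = 0 with `degenerate = TRUE`.
#'
#' @param ratios numeric vector of per-pair log2 ratios (>= 2 values).
#' @return list with `t`, `p` and `degenerate`.
#' @export
paired_t_test <- function(ratios) {
  ratios <- ratios[is.finite(ratios)]
  if (length(ratios) < 2) {
    abort_lnchcc("paired t-test needs at least 2 pairs", "too_few_pairs")
  }
  if (stats::sd(ratios) == 0) {
    if (mean(ratios) == 0) return(list(t = 0, p = 1, degenerate = TRUE))
    return(list(t = sign(mean(ratios)) * Inf, p = 0, degenerate = TRUE))
  }
  fit <- stats::t.test(ratios)
  list(t = unname(fit$statistic), p = fit$p.value, degenerate = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (delegated to [stats::p.adjust()]); adjusted
#' values are monotone in p and lie in [0, 1].
#'
#' @param p p-values in [0, 1].
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort_lnchcc("p-values must lie in [0, 1]", "bad_pvalues")
  }
  stats::p.adjust(p, method = "BH")
}

#' Differential call from the triple criterion
#'
#' A probe is called up if its mean fold change is at least `fc_min`, down if
#' it is at most `1/fc_min`, in both cases requiring p < `p_max` and
#' q < `q_max`; otherwise ns. Boundaries are inclusive on the fold-change
#' side (>= 2.0, <= 0.5 at the defaults) and exclusive on p and q.
#'
#' @param mean_fc linear mean fold changes (geometric mean of per-pair
#'   ratios).
#' @param p,q p-values and FDR-adjusted values.
#' @param fc_min fold-change threshold (default 2).
#' @param p_max,q_max significance cutoffs (default 0.05 both).
#' @return character vector "up"/"down"/"ns".
#' @export
call_de <- function(mean_fc, p, q, fc_min = 2, p_max = 0.05, q_max = 0.05) {
  sig <- p < p_max & q < q_max
  ifelse(sig & mean_fc >= fc_min, "up",
         ifelse(sig & mean_fc <= 1 / fc_min, "down", "ns"))
}

#' Fold-change bin counts for one patient
#'
#' Counts a probe as up if its linear fold (2^ratio) is >= `fc_min` and down
#' if <= 1/`fc_min`; up folds (down reciprocals) are then binned half-open
#' into [2,4), [4,6) and [6, Inf) at the default bin edges, mirroring the
#' per-patient tallies of aberrantly expressed probes reported in array
#' studies.
#'
#' @param ratios per-pair log2 ratios of one patient (vector over probes).
#' @param patient_id label for the output.
#' @param bins increasing linear fold bin edges, first edge also the
#'   up/down threshold.
#' @return data frame with one row per direction: counts per bin, `total`,
#'   and the direction-summed `aberrant` count on the "up" row.
#' @export
bin_fold_changes <- function(ratios, patient_id = "patient", bins = c(2, 4, 6)) {
  fold <- 2 ^ ratios
  up <- fold[fold >= bins[1]]
  down <- 1 / fold[fold <= 1 / bins[1]]
  edges <- c(bins, Inf)
  count_bins <- function(v) {
    vapply(seq_len(length(edges) - 1),
           function(i) sum(v >= edges[i] & v < edges[i + 1]), integer(1))
  }
  up_counts <- count_bins(up)
  down_counts <- count_bins(down)
  out <- data.frame(patient_id = patient_id,
                    direction = c("up", "down"),
                    rbind(up_counts, down_counts),
                    total = c(sum(up_counts), sum(down_counts)),
                    aberrant = c(sum(up_counts) + sum(down_counts), NA),
                    stringsAsFactors = FALSE)
  names(out)[3:(2 + length(bins))] <-
    c(paste0("fc_", bins[-length(bins)], "_", bins[-1]),
      paste0("fc_gt_", bins[length(bins)]))
  rownames(out) <- NULL
  out
}

#' Per-patient fold-change bin summary table
#'
#' Applies [bin_fold_changes()] to every patient of a per-pair ratio matrix.
#'
#' @param ratios probe x patient log2 ratio matrix.
#' @param bins linear fold bin edges.
#' @return stacked data frame, two rows (up/down) per patient.
#' @export
fc_bin_summary <- function(ratios, bins = c(2, 4, 6)) {
  do.call(rbind, lapply(colnames(ratios), function(p) {
    bin_fold_changes(ratios[, p], patient_id = p, bins = bins)
  }))
}

#' Aggregate printed fold-change bin counts
#'
#' Reconstructs the per-direction totals and the per-patient aberrant count
#' from bin counts alone (the arithmetic that links the bin columns of a
#' published per-patient tally to its "Total" and "Aberrant" columns).
#'
#' @param up_counts,down_counts integer vectors of per-bin counts.
#' @return list with `up_total`, `down_total` and `aberrant`.
#' @export
bin_totals <- function(up_counts, down_counts) {
  list(up_total = sum(up_counts), down_total = sum(down_counts),
       aberrant = sum(up_counts) + sum(down_counts))
}

#' Differential expression over a paired design
#'
#' Computes per-pair log2 ratios, the mean fold change as the geometric mean
#' of per-pair ratios, a paired t-test per probe, Benjamini-Hochberg FDR
#' (within biotype by default, mirroring separate lncRNA/mRNA tallies;
#' `fdr_within_biotype = FALSE` pools), and the triple-criterion call.
#' `consistent_direction` records whether all per-pair ratios share one
#' sign. With `require_all_pairs = TRUE` an up/down call additionally
#' requires every per-pair fold to pass the fold-change threshold.
#'
#' @param expression normalized probe x sample matrix.
#' @param design paired design.
#' @param biotype per-probe biotype vector aligned with rows (or `NULL` for
#'   a single stratum).
#' @param fc_min,p_max,q_max call thresholds.
#' @param fdr_within_biotype adjust p-values within each biotype stratum.
#' @param require_all_pairs stricter per-pair fold filter.
#' @return data frame: probe_id, biotype, one ratio column per patient,
#'   mean_log2_fc, fold_change, p_value, q_value, call,
#'   consistent_direction.
#' @export
run_differential <- function(expression, design, biotype = NULL,
                             fc_min = 2, p_max = 0.05, q_max = 0.05,
                             fdr_within_biotype = TRUE,
                             require_all_pairs = FALSE) {
  if (nrow(design) < 2) {
    abort_lnchcc("testing needs at least 2 patients", "too_few_pairs")
  }
  ratios <- per_pair_log2_ratio(expression, design)
  tests <- apply(ratios, 1, paired_t_test)
  p <- vapply(tests, `[[`, numeric(1), "p")
  mean_log2 <- rowMeans(ratios)
  mean_fc <- 2 ^ mean_log2
  if (is.null(biotype)) biotype <- rep("all", nrow(ratios))
  q <- numeric(length(p))
  if (fdr_within_biotype) {
    for (bt in unique(biotype)) {
      idx <- biotype == bt
      q[idx] <- bh_fdr(p[idx])
    }
  } else {
    q <- bh_fdr(p)
  }
  call <- call_de(mean_fc, p, q, fc_min, p_max, q_max)
  if (require_all_pairs) {
    all_up <- rowSums(2 ^ ratios >= fc_min) == ncol(ratios)
    all_dn <- rowSums(2 ^ ratios <= 1 / fc_min) == ncol(ratios)
    call[call == "up" & !all_up] <- "ns"
    call[call == "down" & !all_dn] <- "ns"
  }
  out <- data.frame(probe_id = rownames(ratios), biotype = biotype,
                    ratios, mean_log2_fc = mean_log2, fold_change = mean_fc,
                    p_value = p, q_value = q, call = call,
                    consistent_direction =
                      abs(rowSums(sign(ratios))) == ncol(ratios),
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out
}
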