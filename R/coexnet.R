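# Thresholded Pearson lncRNA-mRNA co-expression network.

#' Pearson correlation of two expression profiles
#'
#' Standard product-moment coefficient over matched samples; requires at
#' least 3 samples and non-constant vectors.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation coefficient in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort_lnchcc("correlation needs two equal-length vectors of >= 3 samples",
                 "too_few_samples")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_lnchcc("constant expression profile: correlation undefined",
                 "constant_profile")
  }
  stats::cor(x, y)
}

#' P-value for a Pearson correlation via the t transform
#'
#' Two-sided p from `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2`
#' degrees of freedom; `|r| = 1` returns the limit p = 0. Vectorized over
#' `r`.
#'
#' @param r correlation coefficient(s), |r| <= 1.
#' @param n number of samples (>= 3).
#' @return p-value(s) in [0, 1].
#' @export
correlation_p <- function(r, n) {
  if (n < 3) abort_lnchcc("correlation p-value needs n >= 3", "too_few_samples")
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) {
    abort_lnchcc("|r| must not exceed 1", "bad_correlation")
  }
  r <- pmin(1, pmax(-1, r))
  p <- ifelse(abs(r) == 1, 0, {
    tt <- r * sqrt(n - 2) / sqrt(pmax(.Machine$double.eps, 1 - r ^ 2))
    2 * stats::pt(-abs(tt), df = n - 2)
  })
  p
}

#' Build the bipartite lncRNA-mRNA co-expression network
#'
#' All-pairs Pearson correlation between the given lncRNA and mRNA probes
#' across every array of the experiment (tumor and normal pooled), retaining
#' edges with `|r| >= r_min` and `p < p_max`. Constant probes are excluded
#' and reported. The network is bipartite by construction: only
#' lncRNA-mRNA pairs are tested.
#'
#' @param expression normalized probe x sample matrix over all arrays.
#' @param lnc_ids,mrna_ids probe ids of the differentially expressed lncRNAs
#'   and mRNAs to connect.
#' @param r_min minimum |r| (default 0.99).
#' @param p_max maximum p (default 0.001).
#' @return list with:
#'   \describe{
#'     \item{edges}{data frame (lnc_probe_id, mrna_probe_id, r, p_value,
#'       sign), sorted by decreasing |r|.}
#'     \item{summary}{[network_composition()] of the edge set.}
#'     \item{extremes}{rows with the maximum positive and most negative r.}
#'     \item{excluded}{ids of constant probes dropped before correlation.}
#'   }
#' @export
build_network <- function(expression, lnc_ids, mrna_ids,
                          r_min = 0.99, p_max = 0.001) {
  lnc_ids <- intersect(lnc_ids, rownames(expression))
  mrna_ids <- intersect(mrna_ids, rownames(expression))
  if (length(lnc_ids) == 0 || length(mrna_ids) == 0) {
    warning("no candidate probes on one side: empty network")
    empty <- data.frame(lnc_probe_id = character(0),
                        mrna_probe_id = character(0), r = numeric(0),
                        p_value = numeric(0), sign = character(0))
    return(list(edges = empty,
                summary = network_composition(empty, length(lnc_ids),
                                              length(mrna_ids)),
                extremes = empty, excluded = character(0)))
  }
  n <- ncol(expression)
  lx <- t(expression[lnc_ids, , drop = FALSE])
  mx <- t(expression[mrna_ids, , drop = FALSE])
  const_l <- lnc_ids[apply(lx, 2, stats::sd) == 0]
  const_m <- mrna_ids[apply(mx, 2, stats::sd) == 0]
  excluded <- c(const_l, const_m)
  if (length(excluded) > 0) {
    message(sprintf("excluding %d constant probe(s) from the network",
                    length(excluded)))
    lx <- lx[, !(colnames(lx) %in% const_l), drop = FALSE]
    mx <- mx[, !(colnames(mx) %in% const_m), drop = FALSE]
  }
  cmat <- stats::cor(lx, mx)
  hit <- which(abs(cmat) >= r_min, arr.ind = TRUE)
  r <- cmat[hit]
  p <- correlation_p(r, n)
  keep <- p < p_max
  edges <- data.frame(lnc_probe_id = colnames(lx)[hit[, 1]][keep],
                      mrna_probe_id = colnames(mx)[hit[, 2]][keep],
                      r = r[keep], p_value = p[keep],
                      sign = ifelse(r[keep] > 0, "positive", "negative"),
                      stringsAsFactors = FALSE)
  edges <- edges[order(-abs(edges$r), edges$lnc_probe_id,
                       edges$mrna_probe_id), ]
  rownames(edges) <- NULL
  extremes <- edges[0, ]
  if (nrow(edges) > 0) {
    pos <- edges[edges$sign == "positive", ]
    neg <- edges[edges$sign == "negative", ]
    extremes <- rbind(if (nrow(pos)) pos[which.max(pos$r), ],
                      if (nrow(neg)) neg[which.min(neg$r), ])
  }
  list(edges = edges,
       summary = network_composition(edges, length(lnc_ids), length(mrna_ids)),
       extremes = extremes, excluded = excluded)
}

#' Network composition summary
#'
#' Edge, node and signed-edge counts plus the percentage of the
#' differentially expressed probes of each biotype participating in the
#' network, rounded to the nearest integer (the convention used when such
#' networks report e.g. "131 mRNAs (39% of all differentially expressed
#' mRNAs)").
#'
#' @param edges network edge table.
#' @param n_de_lnc,n_de_mrna sizes of the differential sets the nodes came
#'   from.
#' @return list of counts, percentages and per-node degree tables.
#' @export
network_composition <- function(edges, n_de_lnc, n_de_mrna) {
  lnc_deg <- table(edges$lnc_probe_id)
  mrna_deg <- table(edges$mrna_probe_id)
  list(n_edges = nrow(edges),
       n_lnc_nodes = length(lnc_deg),
       n_mrna_nodes = length(mrna_deg),
       n_positive_edges = sum(edges$sign == "positive"),
       pct_lnc_of_de = round(100 * length(lnc_deg) / max(1, n_de_lnc)),
       pct_mrna_of_de = round(100 * length(mrna_deg) / max(1, n_de_mrna)),
       lnc_degree = lnc_deg, mrna_degree = mrna_deg)
}

#' Export the network as GraphML and an edge list
#'
#' @param edges edge table from [build_network()].
#' @param graphml_path,edgelist_path output paths (either may be `NULL`).
#' @return invisibly, the igraph object.
#' @export
export_network <- function(edges, graphml_path = NULL, edgelist_path = NULL) {
  g <- igraph::graph_from_data_frame(
    edges[, c("lnc_probe_id", "mrna_probe_id")], directed = FALSE)
  igraph::V(g)$type <- igraph::V(g)$name %in% edges$mrna_probe_id
  if (nrow(edges) > 0) {
    igraph::E(g)$r <- edges$r
    igraph::E(g)$p_value <- edges$p_value
    igraph::E(g)$sign <- edges$sign
  }
  if (!is.null(graphml_path)) {
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  if (!is.null(edgelist_path)) {
    utils::write.table(edges, edgelist_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(g)
}
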