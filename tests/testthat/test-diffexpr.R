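test_that("quantile normalization matches the hand rank-mean oracle", {
  x <- cbind(a = c(1, 3), b = c(2, 4))
  rownames(x) <- c("p1", "p2")
  qn <- quantile_normalize(x)
  # rank means: (1+2)/2 = 1.5 at rank 1, (3+4)/2 = 3.5 at rank 2
  expect_equal(unname(qn), cbind(c(1.5, 3.5), c(1.5, 3.5)))
  expect_identical(dimnames(qn), dimnames(x))
  # order statistics are preserved within each column
  y <- cbind(c(3, 1), c(2, 4))
  qy <- quantile_normalize(y)
  expect_equal(qy[, 1], c(3.5, 1.5))
})

test_that("quantile normalization is idempotent and kills column spread", {
  set.seed(21)
  x <- matrix(2 ^ rnorm(300, 10, 2), 50, 6)
  qn <- quantile_normalize(x)
  sorted <- apply(qn, 2, sort)
  spread <- max(apply(sorted, 1, function(r) diff(range(r))))
  expect_lt(spread, 1e-9)
  expect_equal(quantile_normalize(qn), qn, tolerance = 1e-12)
  expect_error(quantile_normalize(data.frame(x)), class = "lnchcc_bad_matrix")
  expect_warning(quantile_normalize(x[, 1, drop = FALSE]), "no-op")
})

test_that("per-pair ratios equal the brute-force log2 quotient", {
  set.seed(22)
  ex <- generate_expression(synth_config(n_lnc_probes = 10, n_mrna_probes = 10,
                                         seed = 22))
  r <- per_pair_log2_ratio(ex$expression, ex$design)
  expect_identical(colnames(r), ex$design$patient_id)
  for (i in seq_len(nrow(ex$design))) {
    manual <- log2(ex$expression[, ex$design$tumor_sample_id[i]] /
                     ex$expression[, ex$design$normal_sample_id[i]])
    expect_equal(unname(r[, i]), unname(manual))
  }
  bad_design <- ex$design; bad_design$tumor_sample_id[1] <- "T9"
  expect_error(per_pair_log2_ratio(ex$expression, bad_design),
               class = "lnchcc_missing_sample")
})

test_that("ratios are invariant to a global intensity rescale", {
  ex <- generate_expression(synth_config(n_lnc_probes = 10, n_mrna_probes = 10,
                                         seed = 23))
  r1 <- per_pair_log2_ratio(ex$expression, ex$design)
  r2 <- per_pair_log2_ratio(ex$expression * 7.3, ex$design)
  expect_equal(r1, r2)
})

test_that("the paired t-test matches closed-form oracles to 1e-10", {
  fit <- paired_t_test(c(1.0, 1.2, 0.8))
  expect_equal(fit$t, 1 / (0.2 / sqrt(3)), tolerance = 1e-12)
  expect_equal(fit$p, oracle_t_p_df2(fit$t), tolerance = 1e-10)
  expect_equal(fit$p, oracle_t_p(fit$t, 2), tolerance = 1e-10)
  expect_false(fit$degenerate)

  set.seed(24)
  for (n in c(3, 5, 19)) {
    v <- rnorm(n, 0.4, 1)
    fit <- paired_t_test(v)
    expect_equal(fit$p, oracle_t_p(fit$t, n - 1), tolerance = 1e-10)
  }
})

test_that("degenerate ratio vectors take their limit values", {
  expect_identical(paired_t_test(c(0, 0, 0)),
                   list(t = 0, p = 1, degenerate = TRUE))
  up <- paired_t_test(c(1, 1, 1))
  expect_identical(up$t, Inf)
  expect_identical(up$p, 0)
  expect_true(up$degenerate)
  expect_identical(paired_t_test(c(-2, -2))$t, -Inf)
  expect_error(paired_t_test(1.5), class = "lnchcc_too_few_pairs")
})

test_that("BH adjustment matches the hand step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(25)
  p <- runif(200) ^ 2
  q <- bh_fdr(p)
  expect_equal(q, oracle_bh(p), tolerance = 1e-12)
  expect_true(all(q >= p - 1e-12) && all(q <= 1))
  # adjusted values are monotone in p
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  expect_error(bh_fdr(c(0.5, 1.2)), class = "lnchcc_bad_pvalues")
  expect_error(bh_fdr(c(0.5, NA)), class = "lnchcc_bad_pvalues")
})

test_that("the triple criterion is inclusive on fold and exclusive on p/q", {
  expect_identical(call_de(2.0, 0.01, 0.01), "up")
  expect_identical(call_de(0.5, 0.01, 0.01), "down")
  expect_identical(call_de(1.99, 0.01, 0.01), "ns")
  expect_identical(call_de(4, 0.05, 0.01), "ns")  # p boundary excluded
  expect_identical(call_de(4, 0.01, 0.05), "ns")  # q boundary excluded
  expect_identical(call_de(4, 0.0499, 0.0499), "up")
})

test_that("fold-change bins are half-open with reciprocal down binning", {
  # dyadic folds at the bin edges so 2^log2(fold) is exact
  ratios <- log2(c(2.0, 3.99, 4.0, 8.0, 16.0, 1 / 2.5, 1 / 8.0, 1.2))
  out <- bin_fold_changes(ratios, patient_id = "H1")
  up <- out[out$direction == "up", ]
  down <- out[out$direction == "down", ]
  expect_equal(unlist(up[c("fc_2_4", "fc_4_6", "fc_gt_6")],
                      use.names = FALSE), c(2, 1, 2))
  expect_equal(up$total, 5)
  expect_equal(unlist(down[c("fc_2_4", "fc_4_6", "fc_gt_6")],
                      use.names = FALSE), c(1, 0, 1))
  expect_equal(down$total, 2)
  expect_equal(up$aberrant, 7)
  expect_identical(up$patient_id, "H1")
})

test_that("published per-patient tallies obey the bin arithmetic", {
  h1_lnc <- bin_totals(c(1917, 461, 335), c(1120, 235, 301))
  expect_identical(h1_lnc$up_total, 2713)
  expect_identical(h1_lnc$down_total, 1656)
  expect_identical(h1_lnc$aberrant, 4369)
  h1_mrna <- bin_totals(c(2295, 487, 428), c(1852, 419, 596))
  expect_identical(h1_mrna$up_total, 3210)
  expect_identical(h1_mrna$aberrant, 6077)
})

test_that("fc_bin_summary stacks one up/down pair per patient", {
  ex <- generate_expression(synth_config(n_lnc_probes = 40, n_mrna_probes = 40,
                                         frac_up = 0.2, frac_down = 0.2,
                                         effect_log2_range = c(3, 3),
                                         seed = 26))
  ratios <- per_pair_log2_ratio(ex$expression, ex$design)
  s <- fc_bin_summary(ratios)
  expect_identical(nrow(s), 6L)
  expect_identical(unique(s$patient_id), ex$design$patient_id)
  # totals agree with direct counting at the fold-2 threshold
  for (p in ex$design$patient_id) {
    fold <- 2 ^ ratios[, p]
    expect_equal(s$total[s$patient_id == p & s$direction == "up"],
                 sum(fold >= 2))
    expect_equal(s$total[s$patient_id == p & s$direction == "down"],
                 sum(fold <= 0.5))
  }
})

test_that("run_differential assembles ratios, tests and calls coherently", {
  cfg <- synth_config(n_lnc_probes = 60, n_mrna_probes = 60, frac_up = 0.15,
                      frac_down = 0.15, effect_log2_range = c(3, 3),
                      seed = 27)
  ex <- generate_expression(cfg)
  norm <- quantile_normalize(ex$expression)
  de <- run_differential(norm, ex$design, biotype = ex$truth$probes$biotype)
  expect_identical(de$probe_id, rownames(norm))
  expect_equal(de$fold_change, 2 ^ de$mean_log2_fc)
  # p-values reproduce a direct per-probe test
  ratios <- per_pair_log2_ratio(norm, ex$design)
  i <- which.max(abs(de$mean_log2_fc))
  expect_equal(de$p_value[i], paired_t_test(ratios[i, ])$p)
  # q-values are BH within each biotype stratum
  for (bt in c("lncRNA", "mRNA")) {
    idx <- de$biotype == bt
    expect_equal(de$q_value[idx], oracle_bh(de$p_value[idx]),
                 tolerance = 1e-12)
  }
  pooled <- run_differential(norm, ex$design,
                             biotype = ex$truth$probes$biotype,
                             fdr_within_biotype = FALSE)
  expect_equal(pooled$q_value, oracle_bh(pooled$p_value), tolerance = 1e-12)
  # the stricter per-pair filter can only remove calls
  strict <- run_differential(norm, ex$design,
                             biotype = ex$truth$probes$biotype,
                             require_all_pairs = TRUE)
  expect_true(all(strict$call == de$call | strict$call == "ns"))
  expect_error(run_differential(norm, ex$design[1, ]),
               class = "lnchcc_too_few_pairs")
})
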