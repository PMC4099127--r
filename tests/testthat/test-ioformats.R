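make_dataset <- function(dir, mat = NULL) {
  if (is.null(mat)) {
    set.seed(42)
    mat <- matrix(2 ^ rnorm(60, 10, 2), 10, 6,
                  dimnames = list(sprintf("P%02d", 1:10),
                                  c("T1", "T2", "T3", "N1", "N2", "N3")))
  }
  design <- data.frame(patient_id = c("P1", "P2", "P3"),
                       tumor_sample_id = c("T1", "T2", "T3"),
                       normal_sample_id = c("N1", "N2", "N3"),
                       stringsAsFactors = FALSE)
  write_expression(mat, file.path(dir, "expr.tsv"), "abc")
  write_design(design, file.path(dir, "design.csv"), "abc")
  list(mat = mat, design = design)
}

test_that("expression and design round-trip through their files", {
  d <- tempfile("io"); dir.create(d)
  on.exit(unlink(d, recursive = TRUE))
  ref <- make_dataset(d)
  dat <- suppressMessages(read_expression(file.path(d, "expr.tsv"),
                                          file.path(d, "design.csv")))
  expect_equal(dat$expression, ref$mat)
  expect_identical(dat$design, ref$design)
  expect_message(read_expression(file.path(d, "expr.tsv"),
                                 file.path(d, "design.csv")),
                 "10 probes x 6 samples, 3 pairs")
})

test_that("strict import rejects each malformed input with its own class", {
  d <- tempfile("io"); dir.create(d)
  on.exit(unlink(d, recursive = TRUE))
  ref <- make_dataset(d)

  dup <- ref$mat; rownames(dup)[2] <- "P01"
  write_expression(dup, file.path(d, "dup.tsv"))
  expect_error(read_expression(file.path(d, "dup.tsv"),
                               file.path(d, "design.csv")),
               class = "lnchcc_duplicate_ids")

  lines <- readLines(file.path(d, "expr.tsv"))
  lines[4] <- sub("\t[0-9.]+$", "\tnot_a_number", lines[4])
  writeLines(lines, file.path(d, "bad.tsv"))
  expect_error(read_expression(file.path(d, "bad.tsv"),
                               file.path(d, "design.csv")),
               class = "lnchcc_non_numeric")

  neg <- ref$mat; neg[1, 1] <- -5
  write_expression(neg, file.path(d, "neg.tsv"))
  expect_error(read_expression(file.path(d, "neg.tsv"),
                               file.path(d, "design.csv")),
               class = "lnchcc_nonpositive_intensity")
  floored <- suppressMessages(
    read_expression(file.path(d, "neg.tsv"), file.path(d, "design.csv"),
                    floor_intensities = TRUE))
  expect_equal(floored$expression[1, 1], min(ref$mat[ref$mat > 0]))

  bad_design <- data.frame(patient_id = "P4", tumor_sample_id = "T4",
                           normal_sample_id = "N1")
  write_design(bad_design, file.path(d, "bad_design.csv"))
  err <- tryCatch(read_expression(file.path(d, "expr.tsv"),
                                  file.path(d, "bad_design.csv")),
                  error = identity)
  expect_s3_class(err, "lnchcc_missing_sample")
  expect_match(conditionMessage(err), "T4")

  write_design(ref$design[, 1:2], file.path(d, "short_design.csv"))
  expect_error(read_design(file.path(d, "short_design.csv")),
               class = "lnchcc_bad_design")
})

test_that("probe annotation round-trips and is validated", {
  d <- tempfile("io"); dir.create(d)
  on.exit(unlink(d, recursive = TRUE))
  ann <- data.frame(probe_id = c("LNC0001", "MRNA0001"),
                    transcript_id = c("TL1", "G1"),
                    biotype = c("lncRNA", "mRNA"), chrom = "chr1",
                    start = c(100L, 5000L), end = c(900L, 9000L),
                    strand = c("+", "-"), stringsAsFactors = FALSE)
  write_probe_annotation(ann, file.path(d, "ann.tsv"), "h")
  expect_identical(read_probe_annotation(file.path(d, "ann.tsv")), ann)

  bad <- ann; bad$probe_id[2] <- "LNC0001"
  write_probe_annotation(bad, file.path(d, "a2.tsv"))
  expect_error(read_probe_annotation(file.path(d, "a2.tsv")),
               class = "lnchcc_duplicate_ids")
  bad <- ann; bad$biotype[1] <- "rRNA"
  write_probe_annotation(bad, file.path(d, "a3.tsv"))
  expect_error(read_probe_annotation(file.path(d, "a3.tsv")),
               class = "lnchcc_bad_annotation")
  bad <- ann; bad$start[1] <- 900
  write_probe_annotation(bad, file.path(d, "a4.tsv"))
  expect_error(read_probe_annotation(file.path(d, "a4.tsv")),
               class = "lnchcc_bad_coordinates")
})

test_that("gene models round-trip through BED12", {
  cfg <- synth_config(n_lnc_probes = 21, n_mrna_probes = 21, seed = 9)
  models <- generate_annotation(cfg)$genes
  path <- tempfile(fileext = ".bed")
  on.exit(unlink(path))
  write_gene_models_bed(models, path)
  back <- read_gene_models(path)
  expect_equal(back$genes$start, models$genes$start)
  expect_equal(back$genes$end, models$genes$end)
  expect_identical(back$genes$gene_id, models$genes$gene_id)
  expect_identical(back$genes$strand, models$genes$strand)
  expect_equal(back$genes$tss, models$genes$tss)
  expect_equal(back$exons$start, models$exons$start)
  expect_equal(back$exons$end, models$exons$end)
  # blockCount is honoured: three exons per gene
  expect_identical(nrow(back$exons), 3L * nrow(back$genes))
})

test_that("the TSS of a minus-strand gene is its interval end", {
  path <- tempfile(fileext = ".bed")
  on.exit(unlink(path))
  writeLines("chr1\t1000\t4000\tGN\t0\t-\t1000\t4000\t0\t2\t500,500,\t0,2500,",
             path)
  m <- read_gene_models(path)
  expect_identical(m$genes$tss, 4000L)
  expect_equal(m$exons$start, c(1000, 3500))
  expect_equal(m$exons$end, c(1500, 4000))
})

test_that("BED12 and GFF3 of the same gene give identical models", {
  bed <- tempfile(fileext = ".bed")
  gff <- tempfile(fileext = ".gff3")
  on.exit(unlink(c(bed, gff)))
  writeLines("chrS\t100\t700\tG1\t0\t+\t100\t700\t0\t2\t100,400,\t0,200,",
             bed)
  writeLines(c("##gff-version 3",
               "chrS\tsrc\tgene\t101\t700\t.\t+\t.\tID=G1",
               "chrS\tsrc\texon\t101\t200\t.\t+\t.\tParent=G1",
               "chrS\tsrc\texon\t301\t700\t.\t+\t.\tParent=G1"), gff)
  a <- read_gene_models(bed)
  b <- read_gene_models(gff)
  expect_equal(a$genes[c("gene_id", "chrom", "strand", "start", "end", "tss")],
               b$genes[c("gene_id", "chrom", "strand", "start", "end", "tss")])
  expect_equal(a$exons, b$exons)
})

test_that("malformed BED lines are reported with their line number", {
  path <- tempfile(fileext = ".bed")
  on.exit(unlink(path))
  writeLines(c("chr1\t0\t100\tG1\t0\t+\t0\t100\t0\t1\t100,\t0,",
               "chr1\t0\t100"), path)
  err <- tryCatch(read_gene_models(path), error = identity)
  expect_s3_class(err, "lnchcc_malformed_line")
  expect_match(conditionMessage(err), "line 2")

  writeLines("chr1\tzero\t100\tG1\t0\t+\t0\t100\t0\t1\t100,\t0,", path)
  err <- tryCatch(read_gene_models(path), error = identity)
  expect_s3_class(err, "lnchcc_malformed_line")
  expect_match(conditionMessage(err), "line 1")

  expect_error(read_gene_models(tempfile(fileext = ".vcf")),
               class = "lnchcc_bad_format")
})

test_that("inconsistent exon structure is rejected", {
  path <- tempfile(fileext = ".bed")
  on.exit(unlink(path))
  # second block extends past chromEnd
  writeLines("chr1\t0\t100\tG1\t0\t+\t0\t100\t0\t2\t50,80,\t0,40,", path)
  expect_error(read_gene_models(path), class = "lnchcc_bad_coordinates")
})

test_that("gene sets skip comments and blank lines", {
  path <- tempfile()
  on.exit(unlink(path))
  writeLines(c("# catalog", "", "GENE0001", "  GENE0002  ", "#x", "GENE0003"),
             path)
  expect_identical(read_gene_set(path), c("GENE0001", "GENE0002", "GENE0003"))
})

test_that("Ct tables round-trip and are validated", {
  d <- tempfile("io"); dir.create(d)
  on.exit(unlink(d, recursive = TRUE))
  ct <- data.frame(patient_id = rep(c("P1", "P1"), each = 1),
                   condition = c("tumor", "normal"), gene_id = "G1",
                   ct_target = c(20.1, 23.4), ct_reference = c(15.2, 15.2),
                   stringsAsFactors = FALSE)
  write_ct_table(ct, file.path(d, "ct.csv"), "h")
  expect_identical(read_ct_table(file.path(d, "ct.csv")), ct)
  bad <- ct; bad$condition[1] <- "Tumour"
  write_ct_table(bad, file.path(d, "ct2.csv"))
  expect_error(read_ct_table(file.path(d, "ct2.csv")),
               class = "lnchcc_bad_ct_table")
})

test_that("outputs carry the version and configuration hash header", {
  path <- tempfile()
  on.exit(unlink(path))
  h <- config_hash(list(a = 1))
  expect_identical(nchar(h), 32L)
  expect_identical(h, config_hash(list(a = 1)))
  expect_false(identical(h, config_hash(list(a = 2))))
  write_ct_table(data.frame(patient_id = "P1", condition = "tumor",
                            gene_id = "G", ct_target = 1, ct_reference = 1),
                 path, h)
  head2 <- readLines(path, n = 2)
  expect_match(head2[1], "^# lnchcc ")
  expect_identical(head2[2], paste("# config_hash:", h))
})
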