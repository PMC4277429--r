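test_that("DEXSeq-dialect files are read, meta-rows dropped", {
  d <- withr::local_tempdir()
  f1 <- write_dexseq_file(c("G1:E001" = 5, "G1:E002" = 7),
                          file.path(d, "a.txt"))
  f2 <- write_dexseq_file(c("G1:E001" = 2, "G1:E002" = 9),
                          file.path(d, "b.txt"))
  ss <- data.frame(sample_id = c("a", "b"), group = c("A", "B"),
                   file_path = c(f1, f2))
  expect_message(tab <- read_dexseq_counts(ss), "meta-feature")
  expect_equal(dim(tab), c(2L, 2L))
  expect_equal(unname(tab$counts["G1:E002", ]), c(7, 9))
  expect_equal(tab$gene_id, c("G1", "G1"))
  expect_false("_ambiguous" %in% rownames(tab$counts))
})

test_that("DEXSeq reading rejects universe mismatches and bad counts", {
  d <- withr::local_tempdir()
  f1 <- write_dexseq_file(c("G1:E001" = 5, "G1:E002" = 7),
                          file.path(d, "a.txt"))
  f2 <- write_dexseq_file(c("G1:E002" = 9), file.path(d, "b.txt"))
  ss <- data.frame(sample_id = c("a", "b"), group = c("A", "B"),
                   file_path = c(f1, f2))
  expect_error(suppressMessages(read_dexseq_counts(ss)),
               "universe mismatch.*b\\.txt")

  f3 <- write_dexseq_file(c("G1:E001" = -1, "G1:E002" = 7),
                          file.path(d, "neg.txt"))
  ss3 <- data.frame(sample_id = "c", group = "A", file_path = f3)
  expect_error(suppressMessages(read_dexseq_counts(ss3)),
               "line 1.*non-negative integer")

  f4 <- write_dexseq_file(c("G1:E001" = 1.5, "G1:E002" = 7),
                          file.path(d, "frac.txt"))
  ss4 <- data.frame(sample_id = "c", group = "A", file_path = f4)
  expect_error(suppressMessages(read_dexseq_counts(ss4)), "integer")
})

test_that("multi-file read equals column-wise concatenation of single reads", {
  d <- withr::local_tempdir()
  set.seed(42)
  exons <- c("G1:E001", "G1:E002", "G2:E001")
  paths <- vapply(1:3, function(i) {
    write_dexseq_file(stats::setNames(rpois(3, 20), exons),
                      file.path(d, paste0("s", i, ".txt")))
  }, character(1))
  ss <- data.frame(sample_id = paste0("s", 1:3),
                   group = c("A", "A", "B"), file_path = paths)
  joint <- suppressMessages(read_dexseq_counts(ss))
  singles <- lapply(1:3, function(i)
    suppressMessages(read_dexseq_counts(ss[i, , drop = FALSE])))
  expect_equal(joint$counts,
               do.call(cbind, lapply(singles, function(s) s$counts)))
})

test_that("count matrix TSV round-trips exactly", {
  tab <- make_tiny_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix(tab, path)
  back <- read_count_matrix(path, sample_sheet = tab$samples)
  expect_identical(back$counts, tab$counts)
  expect_identical(back$gene_id, tab$gene_id)
  expect_identical(back$samples$group, tab$samples$group)
})

test_that("count matrix reader rejects duplicates and empty data", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\texon_id\ts1\ts2",
               "G1\tG1:E001\t5\t6",
               "G1\tG1:E001\t7\t8"), path)
  expect_error(read_count_matrix(path), "duplicate exon_id")
  writeLines("gene_id\texon_id\ts1\ts2", path)
  expect_error(read_count_matrix(path), "no exons")
})

test_that("external exon results are validated; p = 0 accepted with note", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("exon_id\tlog2fc\tpvalue",
               "G1:E001\t1.2\t0.03"), path)
  r <- read_external_exon_results(path)
  expect_equal(nrow(r), 1L)
  expect_equal(r$gene_id, "G1")  # resolved from the colon convention
  expect_equal(r$x, 1.2)

  writeLines(c("exon_id\tlog2fc\tpvalue", "G1:E001\t1.2\t1.5"), path)
  expect_error(read_external_exon_results(path), "\\[0, 1\\]")

  writeLines(c("exon_id\tlog2fc\tpvalue", "G1:E001\t1.2\t0"), path)
  expect_message(r0 <- read_external_exon_results(path), "clamped")
  expect_equal(r0$p, 0)
})

test_that("gene results are written sorted by final score, ties by gene id", {
  sc <- data.frame(gene_id = c("GB", "GA", "GC"), n_exons = c(3L, 2L, 4L),
                   median_log2fc = c(1, -1, 0.5), score_m = c(2, -1, 3),
                   median_p = exp(-c(2, 1, 3)), null_p = c(0.2, 0.01, 0.2),
                   fdr = c(0.2, 0.03, 0.2))
  sc$final_score <- c(0.2, 0.03, 0.2)
  sc$called <- FALSE
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gene_results(sc, path)
  out <- read.delim(path)
  expect_equal(out$gene_id, c("GA", "GB", "GC"))

  write_gene_results(sc[0, ], path)
  lines <- readLines(path)
  expect_length(lines, 1L)
  expect_match(lines, "^gene_id\t")
})

test_that("flattened-GFF coordinates attach to exon ids without altering data", {
  gff <- withr::local_tempfile(fileext = ".gff")
  writeLines(c(
    "chr1\tflatten\taggregate_gene\t100\t900\t.\t+\t.\tgene_id \"G1\"",
    "chr1\tflatten\texonic_part\t100\t200\t.\t+\t.\ttranscripts \"T1\"; exonic_part_number \"E001\"; gene_id \"G1\"",
    "chr1\tflatten\texonic_part\t300\t400\t.\t+\t.\ttranscripts \"T1\"; exonic_part_number \"E002\"; gene_id \"G1\""),
    gff)
  res <- data.frame(exon_id = c("G1:E002", "G1:E001", "G9:E001"), x = 1:3)
  out <- attach_exon_coordinates(res, gff)
  expect_equal(out$start, c(300L, 100L, NA))
  expect_equal(out$end, c(400L, 200L, NA))
  expect_equal(out$chrom, c("chr1", "chr1", NA))
  expect_equal(out$x, res$x)
})
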