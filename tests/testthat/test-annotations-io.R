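test_that("BED repeat parsing maps fields and keeps 0-based half-open coordinates", {
  path <- withr::local_tempfile(lines = c(
    "chr1\t100\t200\tcopyA\t0\t+",
    "chr2\t50\t80\tcopyB\t0\t-\tAluY"))
  copies <- read_repeat_annotation(path, "bed")
  expect_equal(copies$copy_id, c("copyA", "copyB"))
  expect_equal(copies$chrom, c("chr1", "chr2"))
  expect_equal(copies$start, c(100, 50))
  expect_equal(copies$end, c(200, 80))
  expect_equal(copies$strand, c("+", "-"))
  expect_equal(copies$subfamily[2], "AluY")
})

test_that("RepeatMasker .out coordinates are converted from 1-based inclusive", {
  path <- withr::local_tempfile(lines = c(
    "   SW   perc perc perc  query     position in query",
    "score   div. del. ins.  sequence  begin  end",
    "",
    "  463   1.3  0.6  1.7  chr1      101    200 (1000) +  AluYa5  SINE/Alu  1 100 (0)  1",
    "  239   29.4 1.9  1.0  chr1      501    600 (600)  C  L1PA3   LINE/L1   5 204 (0)  2"))
  copies <- read_repeat_annotation(path, "rmsk_out")
  expect_equal(copies$start, c(100, 500))
  expect_equal(copies$end, c(200, 600))
  expect_equal(copies$end - copies$start, c(100, 100))
  expect_equal(copies$strand, c("+", "-"))
  expect_equal(copies$subfamily, c("AluYa5", "L1PA3"))
})

test_that("invalid intervals and duplicate ids are rejected with line context", {
  bad <- withr::local_tempfile(lines = "chr1\t200\t100\tcopyA\t0\t+")
  expect_error(read_repeat_annotation(bad, "bed"), "invalid repeat interval")
  dup <- withr::local_tempfile(lines = c(
    "chr1\t1\t5\tcopyA\t0\t+", "chr1\t10\t20\tcopyA\t0\t+"))
  expect_error(read_repeat_annotation(dup, "bed"), "duplicate copy_id")
  short <- withr::local_tempfile(lines = "chr1\t1\t5")
  expect_error(read_repeat_annotation(short, "bed"), "line 1")
})

test_that("GTF gene records convert coordinates and demand strand + unique ids", {
  gtf <- withr::local_tempfile(lines = c(
    "#comment",
    paste("chr1", "src", "gene", "1001", "2000", ".", "+", ".",
          'gene_id "G1"; gene_name "foo";', sep = "\t"),
    paste("chr1", "src", "transcript", "1001", "1500", ".", "+", ".",
          'gene_id "G1";', sep = "\t"),
    paste("chr2", "src", "gene", "501", "900", ".", "-", ".",
          'gene_id "G2";', sep = "\t")))
  genes <- read_gene_annotation(gtf, "gtf_lite")
  expect_equal(nrow(genes), 2L)   # transcript rows ignored
  expect_equal(genes$start, c(1000, 500))
  expect_equal(genes$end, c(2000, 900))

  dup <- withr::local_tempfile(lines = rep(paste(
    "chr1", "src", "gene", "1", "10", ".", "+", ".", 'gene_id "G1";',
    sep = "\t"), 2))
  expect_error(read_gene_annotation(dup, "gtf_lite"), "duplicate gene_id")

  unstranded <- withr::local_tempfile(lines = "chr1\t0\t10\tG1\t0\t.")
  expect_error(read_gene_annotation(unstranded, "bed"), "TSS undefined")
})

test_that("TSS is start on + strand and end on - strand", {
  genes <- toy_genes("chr1", c(100, 100), c(400, 400), c("+", "-"))
  expect_equal(unname(gene_tss(genes)), c(100, 400))
})

test_that("count matrix round-trips byte-identically and rejects bad cells", {
  m <- matrix(c(1L, 0L, 7L, 42L), 2, dimnames = list(c("fA", "fB"),
                                                     c("s1", "s2")))
  cm <- count_matrix(m, "gene")
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_count_matrix(cm, p1)
  back <- read_count_matrix(p1, "gene")
  expect_equal(unclass(back), unclass(cm), ignore_attr = FALSE)
  write_count_matrix(back, p2)
  expect_identical(readLines(p1), readLines(p2))

  neg <- withr::local_tempfile(lines = c("feature_id\ts1", "fA\t-3"))
  expect_error(read_count_matrix(neg, "gene"), "egative")
  bad <- withr::local_tempfile(lines = c("feature_id\ts1", "fA\tx"))
  expect_error(read_count_matrix(bad, "gene"), "non-numeric")

  empty <- withr::local_tempfile(lines = "feature_id\ts1\ts2")
  e <- read_count_matrix(empty, "gene")
  expect_equal(dim(e), c(0L, 2L))
})

test_that("random format conversions preserve interval lengths", {
  set.seed(11)
  for (i in 1:25) {
    b1 <- sample.int(5000, 1); span <- sample.int(800, 1)
    rmsk <- withr::local_tempfile(lines = sprintf(
      "1 1.0 0.0 0.0 chrZ %d %d (0) + Rep%d SINE/x 1 10 (0) %d",
      b1, b1 + span - 1, i, i))
    copies <- read_repeat_annotation(rmsk, "rmsk_out")
    expect_equal(copies$end - copies$start, span)
    gtf <- withr::local_tempfile(lines = paste(
      "chrZ", "s", "gene", b1, b1 + span - 1, ".", "-", ".",
      sprintf('gene_id "G%d";', i), sep = "\t"))
    genes <- read_gene_annotation(gtf, "gtf_lite")
    expect_equal(genes$end - genes$start, span)
  }
})

test_that("sample sheet validation enforces karyotype/sex consistency", {
  sheet <- data.frame(sample_id = c("a", "b"), karyotype = c("XX", "XYY"),
                      sex = c("female", "male"))
  expect_silent(validate_sample_sheet(sheet))
  sheet$sex <- c("male", "male")
  expect_error(validate_sample_sheet(sheet), "mismatch")
  bad <- data.frame(sample_id = "a", karyotype = "XXX")
  expect_error(validate_sample_sheet(bad), "unknown karyotype")
})

test_that("mismatched chromosome naming is an explicit error, not an empty overlap", {
  regions <- toy_genes("chr1", 0, 100)
  names(regions)[1] <- "gene_id"
  copies <- toy_copies("1", 10, 20)
  expect_error(count_overlaps(regions, copies), "naming")
})
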