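test_that("CpG read tables parse with 0-based positions and keep zero-coverage rows", {
  f <- withr::local_tempfile(lines = c(
    "# a comment",
    "chr1\t100\t+\t7\t3",
    "chr1\t101\t-\t0\t0"))
  tab <- read_cpg_table(f, "tsv")
  expect_equal(tab$pos, c(100L, 101L))
  expect_equal(tab$strand, c("+", "-"))
  expect_equal(tab$meth_reads, c(7L, 0L))
  expect_equal(tab$unmeth_reads, c(3L, 0L))

  f1 <- withr::local_tempfile(lines = "chr1\t101\t+\t7\t3")
  expect_equal(read_cpg_table(f1, "tsv-1based")$pos, 100L)

  fb <- withr::local_tempfile(lines = "chr1\t100\t102\t+\t7\t3")
  expect_equal(read_cpg_table(fb, "bedgraph-pair")$pos, 100L)
})

test_that("malformed CpG rows fail with the offending line named", {
  f <- withr::local_tempfile(lines = c("# hdr", "chr1\t100\t+\t-1\t3"))
  expect_error(read_cpg_table(f), "line 2.*negative read count")
  f2 <- withr::local_tempfile(lines = c("chr1\t100\t+\t7\t3", "chr1\tx\t+\t1\t1"))
  expect_error(read_cpg_table(f2), "line 2.*non-numeric")
  f3 <- withr::local_tempfile(lines = "chr1\t100\t.\t7\t3")
  expect_error(read_cpg_table(f3), "strand")
})

test_that("gene models resolve the TSS by strand and drop ambiguous genes", {
  f <- withr::local_tempfile(lines = c(
    "chr1\t5000\t7000\tgeneA\t0\t+",
    "chr1\t5000\t7000\tgeneB\t0\t-",
    "chr1\t9000\t9500\tgeneC\t0\t+",
    "chr2\t100\t600\tgeneC\t0\t+"), fileext = ".bed")
  gm <- read_gene_models(f, "bed")
  expect_equal(gm$genes$tss[gm$genes$gene_id == "geneA"], 5000L)
  expect_equal(gm$genes$tss[gm$genes$gene_id == "geneB"], 6999L)
  expect_false("geneC" %in% gm$genes$gene_id)
  expect_equal(sort(unique(gm$rejected$gene_id)), "geneC")
})

test_that("GTF coordinates are converted from 1-based", {
  f <- withr::local_tempfile(lines = c(
    'chr1\tsrc\tgene\t5001\t7000\t.\t+\t.\tgene_id "gA";',
    'chr1\tsrc\tgene\t5001\t7000\t.\t-\t.\tgene_id "gB";'), fileext = ".gtf")
  gm <- read_gene_models(f, "gtf")
  expect_equal(gm$genes$tss[gm$genes$gene_id == "gA"], 5000L)
  expect_equal(gm$genes$tss[gm$genes$gene_id == "gB"], 6999L)
})

test_that("interval tracks merge on read and reject inverted intervals", {
  f <- withr::local_tempfile(lines = c("chr1\t100\t200", "chr1\t150\t300"),
                             fileext = ".bed")
  iv <- read_intervals(f)
  expect_equal(iv, data.frame(chrom = "chr1", start = 100L, end = 300L))
  f2 <- withr::local_tempfile(lines = "chr1\t200\t100", fileext = ".bed")
  expect_error(read_intervals(f2))
})

test_that("interval merging is idempotent and order-independent", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    iv <- data.frame(chrom = sample(c("chr1", "chr2"), n, TRUE),
                     start = sample(0:500, n))
    iv$end <- iv$start + sample(1:100, n, TRUE)
    m1 <- merge_intervals(iv)
    expect_identical(merge_intervals(m1), m1)
    expect_identical(merge_intervals(iv[sample(n), ]), m1)
  }
})

test_that("expression tables reject duplicates and non-numeric values", {
  f <- withr::local_tempfile(lines = c("gene_id\tfpkm", "geneA\t12.5", "geneB\t0"))
  e <- read_expression(f)
  expect_equal(e$expression, c(12.5, 0))
  fdup <- withr::local_tempfile(lines = c("gene_id\tfpkm", "geneA\t1", "geneA\t2"))
  expect_error(read_expression(fdup), "duplicate")
  fna <- withr::local_tempfile(lines = c("gene_id\tfpkm", "geneA\tNA"))
  expect_error(read_expression(fna), "non-numeric")
})

test_that("CpG scanning finds dinucleotides case-insensitively at the C position", {
  f <- withr::local_tempfile(lines = c(">s1", "ACGT", ">s2", "CGCG", ">s3", "AcgT"),
                             fileext = ".fa")
  sites <- scan_cpg_positions(f)
  expect_equal(sites$pos[sites$chrom == "s1"], 1L)
  expect_equal(sites$pos[sites$chrom == "s2"], c(0L, 2L))
  expect_equal(sites$pos[sites$chrom == "s3"], 1L)
  expect_equal(attr(sites, "seqlengths"), c(s1 = 4L, s2 = 4L, s3 = 4L))
})

test_that("CpG scan counts match a substring-count oracle on random sequences", {
  set.seed(7)
  for (i in 1:3) {
    seq <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = "")
    f <- withr::local_tempfile(lines = c(">r", seq), fileext = ".fa")
    sites <- scan_cpg_positions(f)
    hits <- gregexpr("CG", seq, fixed = TRUE)[[1]]
    expect_equal(sites$pos, as.integer(hits) - 1L)
  }
})

test_that("result tables round-trip through the TSV writers", {
  df <- data.frame(gene_id = c("a", "b"), n = c(3L, 5L),
                   value = c(1.25, 2/3), label = c("x", "y"),
                   flag = c(TRUE, FALSE), stringsAsFactors = FALSE)
  f <- withr::local_tempfile()
  write_result_table(df, f, comments = c("meta: 1", "meta: 2"))
  back <- read_result_table(f)
  expect_equal(back, df, tolerance = 1e-9)
})
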