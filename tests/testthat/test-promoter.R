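test_that("promoters are the 1 kb immediately upstream, mirrored on the minus strand", {
  g <- data.frame(gene_id = c("a", "b", "c"), chrom = "chr1",
                  tss = c(10000L, 5000L, 300L), strand = c("+", "-", "+"))
  p <- derive_promoters(g)
  expect_equal(p$start, c(9000L, 5001L, 0L))
  expect_equal(p$end, c(10000L, 6001L, 300L))
  expect_equal(p$clipped, c(FALSE, FALSE, TRUE))
})

test_that("promoters fully off-chromosome are dropped and reported", {
  g <- data.frame(gene_id = c("a", "edge"), chrom = "chr1",
                  tss = c(5000L, 0L), strand = "+")
  expect_warning(p <- derive_promoters(g), "off-chromosome")
  expect_equal(p$gene_id, "a")
  expect_equal(attr(p, "excluded")$gene_id, "edge")
})

test_that("site methylation level is meth/(meth+unmeth), NA when unsequenced", {
  expect_equal(site_methylation_level(7, 3), 0.7)
  expect_true(is.na(site_methylation_level(0, 0)))
  expect_equal(site_methylation_level(0, 12), 0)
  expect_error(site_methylation_level(-1, 3), "non-negative")
})

test_that("strand collapsing averages the two strands and keys minus records to p-1", {
  rec <- data.frame(chrom = "chr1", pos = c(100L, 101L),
                    strand = c("+", "-"),
                    meth_reads = c(6L, 8L), unmeth_reads = c(4L, 2L))
  s <- collapse_strands(rec)
  expect_equal(nrow(s), 1L)
  expect_equal(s$pos, 100L)
  expect_equal(s$level, 0.7)   # mean(0.6, 0.8)
  expect_equal(s$strands_observed, "both")

  rec$unmeth_reads[2] <- 0L; rec$meth_reads[2] <- 0L
  s1 <- collapse_strands(rec)
  expect_equal(s1$level, 0.6)
  expect_equal(s1$strands_observed, "plus")

  rec$meth_reads[1] <- 0L; rec$unmeth_reads[1] <- 0L
  s0 <- collapse_strands(rec)
  expect_true(is.na(s0$level))
  expect_equal(s0$strands_observed, "none")
})

test_that("duplicate strand records at one site are rejected", {
  rec <- data.frame(chrom = "chr1", pos = c(100L, 100L), strand = "+",
                    meth_reads = 1L, unmeth_reads = 1L)
  expect_error(collapse_strands(rec), "more than one record")
})

test_that("promoter profiles sum levels and extrapolate unsequenced census sites", {
  # all sequenced: direct arithmetic
  p1 <- profile_one(c(1, 1, 0, 0), n_sites = 4)
  expect_equal(p1$meth_count, 2)
  expect_equal(p1$unmeth_count, 2)
  expect_equal(p1$pct_methylation, 50)

  # 6 of 8 sequenced, mean 0.25 imputed into the 2 unsequenced sites
  p2 <- profile_one(c(0.5, 0.5, 0.5, 0, 0, 0), n_sites = 8)
  expect_equal(p2$n_sequenced, 6L)
  expect_equal(p2$meth_count, 1.5 + 2 * 0.25)
  expect_equal(p2$unmeth_count, 6)
  expect_equal(p2$pct_methylation, 25)

  # nothing sequenced: counts undefined, filter fails
  p0 <- profile_one(rep(NA_real_, 0), n_sites = 5)
  expect_true(is.na(p0$meth_count))
  expect_false(p0$passes_filter)
})

test_that("sequenced promoter sites missing from the census are an error", {
  prom <- data.frame(gene_id = "g1", chrom = "chr1", start = 0L, end = 1000L,
                     strand = "+", clipped = FALSE)
  census <- data.frame(chrom = "chr1", pos = c(10L, 20L))
  obs <- data.frame(chrom = "chr1", pos = 30L, level = 0.5,
                    strands_observed = "plus")
  expect_error(profile_promoters(prom, obs, census), "not in the CpG census")
})

test_that("coverage filter is strict on the fraction and non-strict on the count", {
  prof <- data.frame(n_sites = c(10L, 10L, 3L, 0L),
                     n_sequenced = c(5L, 6L, 3L, 0L))
  expect_equal(passes_coverage_filter(prof), c(FALSE, TRUE, FALSE, FALSE))
})

test_that("meth + unmeth counts conserve the census size; profiles behave monotonically", {
  set.seed(11)
  for (i in 1:25) {
    n_sites <- sample(4:30, 1)
    n_seq <- sample(1:n_sites, 1)
    p <- profile_one(runif(n_seq), n_sites)
    # conservation
    expect_lt(abs(p$meth_count + p$unmeth_count - n_sites), 1e-9)
    expect_gte(p$pct_methylation, 0)
    expect_lte(p$pct_methylation, 100)
  }
})

test_that("raising a site level never decreases meth_count or increases unmeth_count", {
  set.seed(12)
  for (i in 1:10) {
    n_sites <- sample(5:15, 1)
    n_seq <- sample(2:n_sites, 1)
    lv <- runif(n_seq)
    p <- profile_one(lv, n_sites)
    j <- sample(n_seq, 1)
    lv2 <- lv
    lv2[j] <- min(1, lv[j] + runif(1, 0, 1 - lv[j]))
    p2 <- profile_one(lv2, n_sites)
    expect_gte(p2$meth_count, p$meth_count - 1e-12)
    expect_lte(p2$unmeth_count, p$unmeth_count + 1e-12)
  }
})

test_that("extrapolation is a no-op when every census site is sequenced", {
  set.seed(13)
  for (i in 1:10) {
    n <- sample(4:20, 1)
    lv <- runif(n)
    p <- profile_one(lv, n)
    expect_equal(p$meth_count, sum(lv), tolerance = 1e-12)   # direct-sum oracle
    expect_equal(p$unmeth_count, sum(1 - lv), tolerance = 1e-12)
  }
})
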