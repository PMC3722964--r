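small_params <- function(seed = 1, ...) {
  methylome_params(n_genes = 400L, seed = seed, ...)
}

test_that("the generator is deterministic: same seed, byte-identical files", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulate_methylome(small_params(seed = 5), d1)
  s2 <- simulate_methylome(small_params(seed = 5), d2)
  for (k in names(s1$paths))
    expect_identical(unname(tools::md5sum(s1$paths[[k]])),
                     unname(tools::md5sum(s2$paths[[k]])), label = k)
  s3 <- simulate_methylome(small_params(seed = 6), withr::local_tempdir())
  expect_false(identical(unname(tools::md5sum(s1$paths[["cpg_reads"]])),
                         unname(tools::md5sum(s3$paths[["cpg_reads"]]))))
})

test_that("truth-only mode reproduces the written truth exactly", {
  d <- withr::local_tempdir()
  full <- simulate_methylome(small_params(seed = 8), d)
  fast <- simulate_methylome(small_params(seed = 8), write = FALSE)
  expect_equal(fast$truth, full$truth)
  expect_null(fast$paths)
})

test_that("latent U + M equals the CpG count exactly", {
  tr <- simulate_methylome(small_params(seed = 3), write = FALSE)$truth
  expect_equal(tr$U + tr$M, as.numeric(tr$cpg_count), tolerance = 0)
})

test_that("the expression law matches the latent counts", {
  p <- small_params(seed = 4)
  tr <- simulate_methylome(p, write = FALSE)$truth
  expected <- p$a * pmin(tr$U, p$u_sat) - p$b * tr$M * (tr$U < p$u_sat)
  expect_equal(tr$log_expr, expected)
  # activator-only: no repression term
  pa <- small_params(seed = 4, model = "activator_only")
  tra <- simulate_methylome(pa, write = FALSE)$truth
  expect_equal(tra$log_expr, pa$a * pmin(tra$U, pa$u_sat))
  # null model: expression independent of U and M in truth
  p0 <- small_params(seed = 4, a = 0, b = 0)
  tr0 <- simulate_methylome(p0, write = FALSE)$truth
  expect_equal(tr0$log_expr, rep(0, nrow(tr0)))
})

test_that("invalid generator parameters fail validation before any file is written", {
  expect_error(methylome_params(cgi_fraction = 1.5))
  expect_error(methylome_params(a = -1))
  expect_error(methylome_params(u_sat = 0))
  expect_error(methylome_params(p_unsequenced = 2))
})

test_that("predicted trend signs follow the model presets", {
  expect_equal(unname(expected_qualitative_pattern(methylome_params())),
               c("positive", "weak_negative", "flat", "flat"))
  null <- methylome_params(a = 0, b = 0)
  expect_true(all(expected_qualitative_pattern(null) == "flat"))
  rep_only <- methylome_params(model = "repressor_only")
  expect_equal(unname(expected_qualitative_pattern(rep_only)[["nonCGI_meth"]]),
               "negative")
})

test_that("simulated trends carry the predicted signs (truth-level, one seed)", {
  tr <- simulate_methylome(methylome_params(n_genes = 4000L, seed = 11),
                           write = FALSE)$truth
  an <- run_analysis(truth_gene_records(tr))
  get <- function(cl, ft) an$trends[an$trends$class == cl & an$trends$feature == ft, ]
  expect_gt(get("nonCGI", "unmeth_count")$rho, 0.9)
  expect_lt(get("nonCGI", "unmeth_count")$p_two_sided, 0.01)
  expect_lt(get("nonCGI", "meth_count")$rho, 0)
  # repressor-only: negative methylation trend
  trr <- simulate_methylome(methylome_params(n_genes = 4000L, seed = 12,
                                             model = "repressor_only"),
                            write = FALSE)$truth
  anr <- run_analysis(truth_gene_records(trr))
  expect_lt(anr$trends$rho[anr$trends$class == "nonCGI" &
                             anr$trends$feature == "meth_count"], -0.5)
})

test_that("read-level estimates track the latent counts", {
  d <- withr::local_tempdir()
  sim <- simulate_methylome(methylome_params(n_genes = 1500L, seed = 13), d)
  gm <- read_gene_models(sim$paths[["genes"]], "bed")
  prom <- derive_promoters(gm$genes)
  gr <- rtracklayer::import(sim$paths[["cpg_sites"]], format = "bed")
  census <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                       pos = GenomicRanges::start(gr) - 1L)
  sites <- collapse_strands(read_cpg_table(sim$paths[["cpg_reads"]]))
  prof <- profile_promoters(prom, sites, census)
  m <- match(prof$gene_id, sim$truth$gene_id)
  ok <- prof$passes_filter
  expect_gt(cor(prof$meth_count[ok], sim$truth$M[m][ok]), 0.95)
  expect_gt(cor(prof$unmeth_count[ok], sim$truth$U[m][ok]), 0.95)
  # census size agrees with the latent CpG count
  expect_equal(prof$n_sites, sim$truth$cpg_count[m])
})
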