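test_that("one-sided Mann-Whitney exact p matches hand-enumerated cases", {
  r1 <- mann_whitney_one_sided(c(3, 4), c(1, 2))
  expect_equal(r1$p, 1 / 6)
  expect_equal(r1$method, "exact-enumeration")
  r2 <- mann_whitney_one_sided(c(10, 11, 12), c(1, 2, 3))
  expect_equal(r2$p, 1 / 20)
  r3 <- mann_whitney_one_sided(c(1, 2), c(1, 2))
  expect_gte(r3$p, 0.5)
  expect_error(mann_whitney_one_sided(numeric(), 1:3), "non-empty")
})

test_that("exact Mann-Whitney p agrees with wilcox.test on tie-free samples", {
  set.seed(31)
  for (i in 1:30) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    x <- sample(seq(0.01, 1, 0.01), n1 + n2)  # distinct values, no ties
    r <- mann_whitney_one_sided(x[1:n1], x[-(1:n1)])
    wt <- wilcox.test(x[1:n1], x[-(1:n1)], alternative = "greater", exact = TRUE)
    expect_equal(r$p, wt$p.value, tolerance = 1e-12)
    expect_equal(r$U, unname(wt$statistic))
  }
})

test_that("exact Mann-Whitney p matches full labeling enumeration, ties included", {
  set.seed(32)
  for (i in 1:40) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    pool <- sample(1:5, n1 + n2, replace = TRUE)  # heavy ties
    hi <- pool[1:n1]; lo <- pool[-(1:n1)]
    expect_equal(mann_whitney_one_sided(hi, lo)$p, oracle_mw_p(hi, lo),
                 tolerance = 1e-12)
  }
})

test_that("normal approximation tracks the exact Mann-Whitney p for mid-size groups", {
  set.seed(33)
  for (i in 1:10) {
    n <- sample(8:10, 1)
    x <- rnorm(2 * n)
    hi <- x[1:n]; lo <- x[-(1:n)]
    p_exact <- mann_whitney_one_sided(hi, lo, exact_max = 10)$p
    p_approx <- mann_whitney_one_sided(hi, lo, exact_max = 0)$p
    expect_lt(abs(p_exact - p_approx), 0.01)
  }
})

test_that("Spearman trend rho matches the definitional formula", {
  tr_up <- spearman_median_trend(1:10, (1:10)^2)
  expect_equal(tr_up$rho, 1)
  tr_dn <- spearman_median_trend(1:10, -(1:10))
  expect_equal(tr_dn$rho, -1)
  # two adjacent ranks swapped: rho = 1 - 6*2/(10*99)
  y <- 1:10; y[5:6] <- y[6:5]
  tr_swap <- spearman_median_trend(1:10, y)
  expect_equal(tr_swap$rho, 1 - 12 / 990)
  # n = 3 perfectly increasing: one-sided exact p = 1/6
  tr3 <- spearman_median_trend(1:3, c(2, 5, 9), alternative = "greater")
  expect_equal(tr3$p_value, 1 / 6)
  expect_equal(tr3$method, "exact-permutation")
})

test_that("exact permutation p matches full enumeration and cor.test", {
  set.seed(34)
  for (n in c(5, 6, 7)) {
    for (i in 1:3) {
      x <- rnorm(n); y <- rnorm(n)
      tr <- spearman_median_trend(x, y)
      expect_equal(tr$p_two_sided, oracle_spearman_p(x, y, "two.sided"),
                   tolerance = 1e-12)
      expect_equal(tr$p_one_sided, oracle_spearman_p(x, y, "greater"),
                   tolerance = 1e-12)
      # independent route: cor.test's exact Spearman p (tie-free case)
      ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = TRUE))
      expect_equal(tr$p_two_sided, ct$p.value, tolerance = 1e-9)
    }
  }
})

test_that("exact permutation handles tied medians via average ranks", {
  x <- c(1, 2, 2, 3, 4, 5)
  y <- c(2, 1, 3, 3, 5, 6)
  tr <- spearman_median_trend(x, y)
  expect_equal(tr$rho, cor(x, y, method = "spearman"))
  expect_equal(tr$p_two_sided, oracle_spearman_p(x, y, "two.sided"),
               tolerance = 1e-12)
})

test_that("constant medians yield an undefined trend, not a spurious p", {
  tr <- spearman_median_trend(rep(1, 5), 1:5)
  expect_true(is.na(tr$rho))
  expect_equal(tr$method, "undefined")
})

test_that("rank statistics are invariant under monotone transforms", {
  set.seed(35)
  x <- runif(9); y <- rexp(9)  # odd n: medians are order statistics
  tr <- spearman_median_trend(x, y)
  tr_t <- spearman_median_trend(x, log1p(y))
  expect_equal(tr$rho, tr_t$rho)
  expect_equal(tr$p_two_sided, tr_t$p_two_sided)
  hi <- rexp(6); lo <- rexp(5)
  expect_equal(mann_whitney_one_sided(hi, lo)$p,
               mann_whitney_one_sided(log1p(hi), log1p(lo))$p)
  # medians commute with monotone transforms
  expect_equal(median(log1p(y)), log1p(median(y)))
})

test_that("the t approximation is used above the exact limit and is recorded", {
  set.seed(36)
  x <- rnorm(12); y <- rnorm(12)
  tr <- spearman_median_trend(x, y)
  expect_equal(tr$method, "t-approximation")
  expect_equal(tr$n_bins, 12L)
})
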