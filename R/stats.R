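## Nonparametric machinery for the bin analysis: one-sided Mann-Whitney with
## exact p by labeling enumeration (midranks for ties), and Spearman trend on
## bin medians with exact permutation p-values.

# all permutations of 1..n as an (n! x n) integer matrix; cached.
# Built by the insertion construction: a permutation of 1..k is the position
# of k plus a permutation of 1..k-1 on the remaining columns.
.perm_matrix <- function(n) {
  stopifnot(n >= 1, n <= 9)  # 9! = 362880 rows; n = 10 is handled chunked
  key <- paste0("perm", n)
  cached <- .methbin_cache[[key]]
  if (!is.null(cached)) return(cached)
  P <- matrix(1L, 1L, 1L)
  if (n > 1L) for (k in 2:n) {
    m <- nrow(P)
    Pk <- matrix(0L, m * k, k)
    for (j in seq_len(k)) {
      rows <- ((j - 1L) * m + 1L):(j * m)
      Pk[rows, j] <- k
      Pk[rows, -j] <- P
    }
    P <- Pk
  }
  .methbin_cache[[key]] <- P
  P
}

#' One-sided Mann-Whitney (rank-sum) test, exact for small groups
#'
#' Tests the alternative that `high` is stochastically greater than `low`.
#' Ties receive midranks. When both group sizes are at most `exact_max` the
#' p-value is exact: all `choose(n, n_high)` assignments of the pooled values
#' to the two groups are enumerated and the p-value is the fraction with a
#' rank-sum statistic at least the observed one. For larger groups the normal
#' approximation with tie and continuity correction is used (via
#' [stats::wilcox.test()]).
#'
#' @param high,low Numeric vectors of expression values; both non-empty.
#' @param exact_max Largest group size for which the exact enumeration is
#'   used (default 8).
#' @return List with `U` (Mann-Whitney statistic for `high`), `p` (one-sided
#'   p-value), `method` (`"exact-enumeration"` or `"normal-approximation"`).
#' @export
mann_whitney_one_sided <- function(high, low, exact_max = 8L) {
  if (length(high) == 0L || length(low) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  n1 <- length(high)
  n2 <- length(low)
  r <- rank(c(high, low))  # midranks
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    sel <- combn(n1 + n2, n1)
    rs <- colSums(matrix(r[sel], nrow = n1))
    U_perm <- rs - n1 * (n1 + 1) / 2
    p <- mean(U_perm >= U - 1e-9)
    method <- "exact-enumeration"
  } else {
    wt <- suppressWarnings(
      wilcox.test(high, low, alternative = "greater", exact = FALSE, correct = TRUE))
    p <- wt$p.value
    method <- "normal-approximation"
  }
  list(U = U, p = p, method = method)
}

# exact permutation p-value for Spearman's rho given tied-adjusted ranks.
# rho is a monotone linear function of S = sum(rx * ry[perm]), so comparisons
# are done on S; n = 10 is enumerated in chunks over the first position using
# the cached 9! matrix.
.spearman_perm_p <- function(rx, ry, rho_obs, alternative) {
  n <- length(rx)
  mx <- mean(rx); my <- mean(ry)
  sx <- sd(rx); sy <- sd(ry)
  rho_of <- function(S) (S - n * mx * my) / ((n - 1) * sx * sy)
  eps <- 1e-12
  count_fun <- switch(alternative,
    two.sided = function(r) sum(abs(r) >= abs(rho_obs) - eps),
    greater = function(r) sum(r >= rho_obs - eps),
    less = function(r) sum(r <= rho_obs + eps))
  if (n <= 9L) {
    P <- .perm_matrix(n)
    S <- as.vector(matrix(ry[P], nrow = nrow(P)) %*% rx)
    count_fun(rho_of(S)) / factorial(n)
  } else {
    P9 <- .perm_matrix(9L)
    cnt <- 0
    for (v in seq_len(n)) {
      rest <- setdiff(seq_len(n), v)
      M <- matrix(ry[rest][P9], nrow = nrow(P9))
      S <- ry[v] * rx[1L] + as.vector(M %*% rx[2:n])
      cnt <- cnt + count_fun(rho_of(S))
    }
    cnt / factorial(n)
  }
}

#' Spearman trend across bins, on per-bin medians
#'
#' Correlates per-bin feature medians with per-bin expression medians using
#' Spearman's rho (average ranks for ties). The p-value is an exact
#' permutation p (full enumeration of the `n!` orderings) when the number of
#' bins is at most `exact_max`, and the t approximation otherwise. Both the
#' method and the sidedness are recorded; `p_one_sided` always tests the
#' `greater` (positive-trend) direction.
#'
#' @param feature_medians,expr_medians Numeric vectors, one value per bin.
#' @param feature Optional label stored in the result.
#' @param alternative Sidedness of the reported `p_value`: `"two.sided"`
#'   (default), `"greater"`, or `"less"`.
#' @param exact_max Largest `n` enumerated exactly (default 10; `10!` =
#'   3,628,800 orderings).
#' @return Object of class `"trend_result"`: list with `feature`, `n_bins`,
#'   `rho`, `p_value`, `p_two_sided`, `p_one_sided`, `alternative`, `method`
#'   (`"exact-permutation"` or `"t-approximation"`). With constant medians on
#'   either axis, `rho` and the p-values are `NA` and `method` is
#'   `"undefined"`.
#' @export
spearman_median_trend <- function(feature_medians, expr_medians, feature = "feature",
                                  alternative = c("two.sided", "greater", "less"),
                                  exact_max = 10L) {
  alternative <- match.arg(alternative)
  x <- feature_medians
  y <- expr_medians
  if (length(x) != length(y)) stop("median vectors differ in length", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need at least 3 bins for a trend test", call. = FALSE)
  res <- list(feature = feature, n_bins = n, rho = NA_real_,
              p_value = NA_real_, p_two_sided = NA_real_, p_one_sided = NA_real_,
              alternative = alternative, method = "undefined")
  class(res) <- "trend_result"
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) return(res)
  rx <- rank(x)
  ry <- rank(y)
  rho <- cor(rx, ry)
  res$rho <- rho
  if (n <= exact_max && n <= 10L) {
    res$method <- "exact-permutation"
    res$p_two_sided <- .spearman_perm_p(rx, ry, rho, "two.sided")
    res$p_one_sided <- .spearman_perm_p(rx, ry, rho, "greater")
    res$p_value <- if (alternative == "two.sided") res$p_two_sided
      else if (alternative == "greater") res$p_one_sided
      else .spearman_perm_p(rx, ry, rho, "less")
  } else {
    res$method <- "t-approximation"
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    res$p_two_sided <- 2 * pt(-abs(tt), df = n - 2)
    res$p_one_sided <- pt(tt, df = n - 2, lower.tail = FALSE)
    res$p_value <- switch(alternative,
      two.sided = res$p_two_sided,
      greater = res$p_one_sided,
      less = pt(tt, df = n - 2))
  }
  res
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("Spearman trend on bin medians: %s (%d bins)\n", x$feature, x$n_bins))
  if (is.na(x$rho)) {
    cat("  rho undefined (constant medians)\n")
  } else {
    cat(sprintf("  rho = %.4f, p (%s, %s) = %.3g\n", x$rho, x$alternative,
                x$method, x$p_value))
    cat(sprintf("  p two-sided = %.3g, p one-sided (greater) = %.3g\n",
                x$p_two_sided, x$p_one_sided))
  }
  invisible(x)
}

#' Empirical cumulative distribution table
#'
#' Right-continuous step ECDF evaluated at the sorted unique values; the last
#' fraction is exactly 1.
#'
#' @param values Non-empty numeric vector.
#' @return data.frame with `value` (sorted unique values) and `fraction`
#'   (cumulative fraction of observations `<= value`).
#' @export
ecdf_table <- function(values) {
  if (length(values) == 0L) stop("ecdf of an empty sample is undefined", call. = FALSE)
  v <- sort(unique(values))
  data.frame(value = v, fraction = ecdf(values)(v))
}
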