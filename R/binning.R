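## Equal-count and fixed-span binning, median sub-splits, and the
## bin-trend / sub-bin analysis object.

#' Equal-count bins over a ranking feature
#'
#' Genes are stably sorted by the feature (ties broken by `gene_id`) and cut
#' into `k` bins of equal size. When `N` is not divisible by `k` the common
#' size is `floor(N / k)` and the `N mod k` leftover genes are appended one
#' each to the last (highest-feature) bins.
#'
#' @param genes data.frame with `gene_id` and the feature column.
#' @param feature Name of the ranking feature column.
#' @param k Number of bins (default 10).
#' @return `genes` with an integer `bin` column (1 = lowest feature values);
#'   the attribute `"bin_sizes"` gives the per-bin sizes.
#' @export
equal_count_bins <- function(genes, feature, k = 10L) {
  stopifnot(feature %in% names(genes), "gene_id" %in% names(genes))
  N <- nrow(genes)
  if (N < k) stop(sprintf("need at least k = %d genes, got %d", k, N), call. = FALSE)
  sizes <- bin_sizes(N, k)
  ord <- order(genes[[feature]], genes$gene_id)
  bin <- integer(N)
  bin[ord] <- rep(seq_len(k), times = sizes)
  genes$bin <- bin
  attr(genes, "bin_sizes") <- sizes
  genes
}

#' Per-bin sizes for equal-count binning
#'
#' @param N Number of genes.
#' @param k Number of bins.
#' @return Integer vector of length `k`: `floor(N / k)` for the first
#'   `k - N %% k` bins, one more for the rest.
#' @export
bin_sizes <- function(N, k = 10L) {
  stopifnot(N >= k, k >= 1)
  base <- N %/% k
  r <- N %% k
  c(rep.int(base, k - r), rep.int(base + 1L, r))
}

#' Fixed-span bins over a ranking feature
#'
#' Consecutive half-open windows `[lo, lo + span)` starting at the minimum
#' feature value. Empty windows are dropped; windows holding fewer than
#' `min_occupancy` genes are kept in the output but flagged
#' (`included = FALSE`) and excluded from downstream statistics.
#'
#' @param genes data.frame with `gene_id` and the feature column.
#' @param feature Name of the ranking feature column.
#' @param span Window width on the feature scale (> 0).
#' @param min_occupancy Minimum genes per window for inclusion in statistics
#'   (default 50).
#' @return `genes` with an integer `bin` column (1 = lowest window); the
#'   attribute `"bins"` is a data.frame `bin`, `lo`, `hi`, `n`, `included`.
#' @export
fixed_span_bins <- function(genes, feature, span, min_occupancy = 50L) {
  stopifnot(feature %in% names(genes), span > 0)
  x <- genes[[feature]]
  lo0 <- min(x)
  win <- floor((x - lo0) / span)  # half-open [lo, lo + span) windows
  occ <- sort(unique(win))
  bin <- match(win, occ)
  meta <- data.frame(bin = seq_along(occ), lo = lo0 + occ * span,
                     hi = lo0 + (occ + 1) * span,
                     n = as.integer(table(factor(bin, levels = seq_along(occ)))))
  meta$included <- meta$n >= min_occupancy
  genes$bin <- bin
  attr(genes, "bins") <- meta
  genes
}

#' Median split of a bin by a secondary feature
#'
#' Stable sort by the secondary feature (original order breaks ties); the
#' lower `ceiling(n / 2)` ranks form the low subgroup, the rest the high
#' subgroup. Halves are exactly equal for even `n`; ties at the median are
#' allocated by rank order so the subgroup sizes never depend on tie values.
#'
#' @param secondary Numeric vector (one value per bin member), length >= 2.
#' @return Character vector (`"low"` / `"high"`) aligned with the input.
#' @export
median_split <- function(secondary) {
  n <- length(secondary)
  if (n < 2L) stop("median split needs at least 2 members", call. = FALSE)
  ord <- order(secondary, seq_len(n))
  grp <- character(n)
  grp[ord] <- rep(c("low", "high"), c(ceiling(n / 2), floor(n / 2)))
  grp
}

# per-bin summaries for a binned gene table (only included bins for
# fixed-span binning)
.bin_summary <- function(binned, feature) {
  bins <- sort(unique(binned$bin))
  do.call(rbind, lapply(bins, function(b) {
    g <- binned[binned$bin == b, ]
    data.frame(bin = b, n = nrow(g),
               feature_median = median(g[[feature]]),
               expr_median = median(g$expression))
  }))
}

# median-split each bin by `secondary` and run the one-sided Mann-Whitney
# test (high subgroup stochastically greater than low)
.subbin_tests <- function(binned, secondary, mw_alpha = 0.001, mw_exact_max = 8L) {
  bins <- sort(unique(binned$bin))
  rows <- lapply(bins, function(b) {
    g <- binned[binned$bin == b, ]
    if (nrow(g) < 2L)
      return(data.frame(bin = b, n = nrow(g), n_low = NA_integer_,
                        n_high = NA_integer_, median_low = NA_real_,
                        median_high = NA_real_, U = NA_real_, p = NA_real_,
                        significant = NA, skipped = TRUE))
    side <- median_split(g[[secondary]])
    lo <- g$expression[side == "low"]
    hi <- g$expression[side == "high"]
    mw <- mann_whitney_one_sided(hi, lo, exact_max = mw_exact_max)
    data.frame(bin = b, n = nrow(g), n_low = length(lo), n_high = length(hi),
               median_low = median(lo), median_high = median(hi),
               U = mw$U, p = mw$p, significant = mw$p < mw_alpha, skipped = FALSE)
  })
  do.call(rbind, rows)
}

#' Bin-based methylome-expression association analysis
#'
#' The analysis core: within each promoter class (CGI and non-CGI), genes are
#' ranked by the CMepG count and by the CUn-MepG count and cut into `k`
#' equal-count bins; each trend is tested by Spearman correlation of the
#' per-bin feature medians against the per-bin expression medians (exact
#' permutation p-values for `k <= 10`). For the non-CGI class each bin is
#' additionally median-split by a secondary feature and the two subgroups are
#' compared with a one-sided Mann-Whitney test (high subgroup greater), with
#' a significance bar of `mw_alpha`; three sub-bin grids are computed:
#' CUn-MepG bins split by CMepG, CMepG bins split by CUn-MepG, and percent
#' methylation bins split by total CpG count.
#'
#' @param genes data.frame of integrated gene records with columns `gene_id`,
#'   `meth_count`, `unmeth_count`, `pct_methylation`, `cgi_label` (`"CGI"` /
#'   `"nonCGI"`), `expression`; `cpg_count` is derived as `meth_count +
#'   unmeth_count` when absent.
#' @param k Number of equal-count bins (default 10).
#' @param mw_alpha Mann-Whitney significance bar (default 0.001).
#' @param spearman_alternative Sidedness of the trend `p_value`
#'   (`"two.sided"` default; one-sided p is always reported alongside).
#' @param spearman_exact_max Largest bin count with exact permutation p
#'   (default 10).
#' @param mw_exact_max Largest subgroup size with exact Mann-Whitney p
#'   (default 8).
#' @param fixed_span Optional named numeric vector of spans, e.g.
#'   `c(meth_count = 1.8, unmeth_count = 2)`, triggering a fixed-span rerun
#'   of the trend analysis.
#' @param span_min_occupancy Minimum genes per fixed-span window (default 50).
#' @param stratified If `TRUE`, also compute the non-CGI CUn-MepG bin medians
#'   separately for genes above/below the median percent methylation.
#' @param keep_ecdfs If `TRUE` (default), store the per-bin expression ECDF
#'   tables.
#' @return Object of class `"cpg_bin_analysis"`; see Details. Main
#'   components: `trends` (data.frame, one row per class x feature),
#'   `assignments` (per class x feature gene-to-bin tables with subgroup
#'   labels where defined), `bin_summaries`, `subbins` (non-CGI sub-bin
#'   Mann-Whitney grid), `ecdfs`, and optional `fixed_span` and `stratified`
#'   components.
#' @export
run_analysis <- function(genes, k = 10L, mw_alpha = 0.001,
                         spearman_alternative = "two.sided",
                         spearman_exact_max = 10L, mw_exact_max = 8L,
                         fixed_span = NULL, span_min_occupancy = 50L,
                         stratified = FALSE, keep_ecdfs = TRUE) {
  need <- c("gene_id", "meth_count", "unmeth_count", "pct_methylation",
            "cgi_label", "expression")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stop("gene records missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(genes$cpg_count))
    genes$cpg_count <- genes$meth_count + genes$unmeth_count
  classes <- c("CGI", "nonCGI")
  features <- c("unmeth_count", "meth_count")
  for (cl in classes)
    if (!any(genes$cgi_label == cl))
      stop("no genes after classification (", cl, ")", call. = FALSE)

  trends <- list()
  assignments <- list()
  bin_summaries <- list()
  ecdfs <- list()
  for (cl in classes) {
    sub <- genes[genes$cgi_label == cl, , drop = FALSE]
    for (ft in features) {
      binned <- tryCatch(equal_count_bins(sub, ft, k), error = function(e)
        stop("binning stage (", cl, ", ", ft, "): ", conditionMessage(e), call. = FALSE))
      summ <- .bin_summary(binned, ft)
      tr <- spearman_median_trend(summ$feature_median, summ$expr_median,
                                  feature = paste(cl, ft, sep = "."),
                                  alternative = spearman_alternative,
                                  exact_max = spearman_exact_max)
      trends[[paste(cl, ft, sep = ".")]] <- data.frame(
        class = cl, feature = ft, n_bins = tr$n_bins, rho = tr$rho,
        p_value = tr$p_value, p_two_sided = tr$p_two_sided,
        p_one_sided = tr$p_one_sided, alternative = tr$alternative,
        method = tr$method, stringsAsFactors = FALSE)
      assignments[[cl]][[ft]] <- binned[, c("gene_id", ft, "bin")]
      bin_summaries[[paste(cl, ft, sep = ".")]] <-
        cbind(class = cl, feature = ft, summ, stringsAsFactors = FALSE)
      if (keep_ecdfs)
        ecdfs[[cl]][[ft]] <- lapply(split(binned$expression, binned$bin), ecdf_table)
    }
  }

  # non-CGI sub-bin grids (primary bins median-split by secondary feature)
  grids <- list(c(primary = "unmeth_count", secondary = "meth_count"),
                c(primary = "meth_count", secondary = "unmeth_count"),
                c(primary = "pct_methylation", secondary = "cpg_count"))
  noncgi <- genes[genes$cgi_label == "nonCGI", , drop = FALSE]
  subbins <- do.call(rbind, lapply(grids, function(gd) {
    binned <- equal_count_bins(noncgi, gd[["primary"]], k)
    tests <- .subbin_tests(binned, gd[["secondary"]], mw_alpha, mw_exact_max)
    cbind(class = "nonCGI", primary = gd[["primary"]],
          secondary = gd[["secondary"]], tests, stringsAsFactors = FALSE)
  }))
  # attach subgroup labels to the primary-feature assignments
  for (gd in grids[1:2]) {
    binned <- equal_count_bins(noncgi, gd[["primary"]], k)
    grp <- unlist(lapply(split(seq_len(nrow(binned)), binned$bin), function(ix) {
      if (length(ix) < 2L) return(setNames(rep(NA_character_, length(ix)), ix))
      setNames(median_split(binned[[gd[["secondary"]]]][ix]), ix)
    }))
    binned$subgroup <- grp[as.character(seq_len(nrow(binned)))]
    assignments[["nonCGI"]][[gd[["primary"]]]] <-
      binned[, c("gene_id", gd[["primary"]], "bin", "subgroup")]
  }

  out <- list(trends = do.call(rbind, c(trends, list(make.row.names = FALSE))),
              assignments = assignments,
              bin_summaries = do.call(rbind, c(bin_summaries, list(make.row.names = FALSE))),
              subbins = subbins,
              ecdfs = if (keep_ecdfs) ecdfs else NULL,
              config = list(k = k, mw_alpha = mw_alpha,
                            spearman_alternative = spearman_alternative,
                            spearman_exact_max = spearman_exact_max,
                            mw_exact_max = mw_exact_max,
                            fixed_span = fixed_span,
                            span_min_occupancy = span_min_occupancy),
              n_genes = c(CGI = sum(genes$cgi_label == "CGI"),
                          nonCGI = nrow(noncgi)))

  if (!is.null(fixed_span)) {
    fs_trends <- list()
    fs_meta <- list()
    for (cl in classes) {
      sub <- genes[genes$cgi_label == cl, , drop = FALSE]
      for (ft in intersect(names(fixed_span), features)) {
        binned <- fixed_span_bins(sub, ft, fixed_span[[ft]], span_min_occupancy)
        meta <- attr(binned, "bins")
        keep <- binned$bin %in% meta$bin[meta$included]
        summ <- .bin_summary(binned[keep, , drop = FALSE], ft)
        tr <- if (nrow(summ) >= 3L)
          spearman_median_trend(summ$feature_median, summ$expr_median,
                                feature = paste(cl, ft, "span", sep = "."),
                                alternative = spearman_alternative,
                                exact_max = spearman_exact_max)
        else list(n_bins = nrow(summ), rho = NA_real_, p_value = NA_real_,
                  p_two_sided = NA_real_, p_one_sided = NA_real_,
                  alternative = spearman_alternative, method = "undefined")
        fs_trends[[paste(cl, ft, sep = ".")]] <- data.frame(
          class = cl, feature = ft, span = fixed_span[[ft]], n_bins = tr$n_bins,
          rho = tr$rho, p_value = tr$p_value, p_two_sided = tr$p_two_sided,
          p_one_sided = tr$p_one_sided, method = tr$method, stringsAsFactors = FALSE)
        fs_meta[[paste(cl, ft, sep = ".")]] <-
          cbind(class = cl, feature = ft, meta, stringsAsFactors = FALSE)
      }
    }
    out$fixed_span <- list(trends = do.call(rbind, c(fs_trends, list(make.row.names = FALSE))),
                           bins = do.call(rbind, c(fs_meta, list(make.row.names = FALSE))))
  }

  if (isTRUE(stratified)) {
    cutv <- median(noncgi$pct_methylation)
    strata <- list(low_methylation = noncgi[noncgi$pct_methylation <= cutv, , drop = FALSE],
                   high_methylation = noncgi[noncgi$pct_methylation > cutv, , drop = FALSE])
    out$stratified <- do.call(rbind, lapply(names(strata), function(nm) {
      st <- strata[[nm]]
      if (nrow(st) < k) return(NULL)
      binned <- equal_count_bins(st, "unmeth_count", k)
      cbind(stratum = nm, .bin_summary(binned, "unmeth_count"),
            stringsAsFactors = FALSE)
    }))
  }

  class(out) <- "cpg_bin_analysis"
  out
}

#' @export
print.cpg_bin_analysis <- function(x, ...) {
  cat("Bin-based methylome-expression association\n")
  cat(sprintf("  genes: %d CGI, %d nonCGI; k = %d equal-count bins\n",
              x$n_genes[["CGI"]], x$n_genes[["nonCGI"]], x$config$k))
  cat("\nSpearman trends on bin medians:\n")
  tr <- x$trends
  tr$rho <- round(tr$rho, 4)
  print(tr[, c("class", "feature", "n_bins", "rho", "p_two_sided",
               "p_one_sided", "method")], row.names = FALSE)
  nsig <- sum(x$subbins$significant, na.rm = TRUE)
  cat(sprintf("\nnon-CGI sub-bin Mann-Whitney tests: %d of %d significant at p < %g\n",
              nsig, sum(!x$subbins$skipped), x$config$mw_alpha))
  invisible(x)
}

#' @export
summary.cpg_bin_analysis <- function(object, ...) {
  print(object)
  cat("\nSub-bin tests by grid (high subgroup > low subgroup):\n")
  sb <- object$subbins
  for (pr in unique(sb$primary)) {
    g <- sb[sb$primary == pr, ]
    cat(sprintf("  %s bins split by %s: %d/%d bins significant\n",
                pr, g$secondary[1L], sum(g$significant, na.rm = TRUE),
                sum(!g$skipped)))
  }
  invisible(object)
}

#' Plot bin medians per class and feature
#'
#' One panel per class x feature: per-bin median expression (log scale)
#' against per-bin median feature value, annotated with the Spearman trend.
#'
#' @param x A `"cpg_bin_analysis"` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cpg_bin_analysis <- function(x, ...) {
  bs <- x$bin_summaries
  combos <- unique(bs[, c("class", "feature")])
  op <- graphics::par(mfrow = c(2, ceiling(nrow(combos) / 2)),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (i in seq_len(nrow(combos))) {
    g <- bs[bs$class == combos$class[i] & bs$feature == combos$feature[i], ]
    tr <- x$trends[x$trends$class == combos$class[i] &
                     x$trends$feature == combos$feature[i], ]
    graphics::plot(g$feature_median, g$expr_median, log = "y",
                   xlab = paste("median", combos$feature[i]),
                   ylab = "median expression",
                   main = sprintf("%s (rho = %.2f, p = %.3g)", combos$class[i],
                                  tr$rho, tr$p_two_sided), pch = 19, ...)
    graphics::lines(g$feature_median, g$expr_median, lty = 2)
  }
  invisible(x)
}
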