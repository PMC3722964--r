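## Promoter derivation, strand collapsing, and the per-promoter
## CMepG / CUn-MepG census with extrapolation over unsequenced CpGs.

#' Derive promoter intervals (1 kb upstream of the TSS)
#'
#' The promoter of a gene is the `upstream_len` bases immediately upstream of
#' its transcription start site, excluding the TSS base itself: on `+` it is
#' `[tss - upstream_len, tss)`, on `-` the mirror `[tss + 1, tss + 1 +
#' upstream_len)`. Promoters running off the chromosome start (or end, when
#' sequence lengths are known) are clipped and flagged; genes whose promoter
#' is entirely off-chromosome are dropped and reported.
#'
#' @param genes data.frame with `gene_id`, `chrom`, `tss` (0-based), `strand`,
#'   as returned by [read_gene_models()].
#' @param upstream_len Promoter length in bp (default 1000).
#' @param seqlengths Optional named vector of chromosome lengths used to clip
#'   at the chromosome end.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `clipped`. Dropped genes are in the attribute
#'   `"excluded"`.
#' @export
derive_promoters <- function(genes, upstream_len = 1000L, seqlengths = NULL) {
  stopifnot(upstream_len > 0)
  need <- c("gene_id", "chrom", "tss", "strand")
  stopifnot(all(need %in% names(genes)))
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - upstream_len, genes$tss + 1L)
  end <- ifelse(plus, genes$tss, genes$tss + 1L + upstream_len)
  raw_start <- start
  raw_end <- end
  start <- pmax(start, 0L)
  if (!is.null(seqlengths)) {
    sl <- seqlengths[genes$chrom]
    end <- ifelse(is.na(sl), end, pmin(end, sl))
  }
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    start = as.integer(start), end = as.integer(end),
                    strand = genes$strand,
                    clipped = start != raw_start | end != raw_end,
                    stringsAsFactors = FALSE)
  off <- out$end <= out$start
  excluded <- out[off, c("gene_id", "chrom", "start", "end", "strand")]
  if (any(off))
    warning(sum(off), " gene(s) with promoter entirely off-chromosome dropped",
            call. = FALSE)
  out <- out[!off, , drop = FALSE]
  rownames(out) <- rownames(excluded) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Per-strand methylation level of a site
#'
#' The methylation level is methylated reads divided by total reads; a site
#' with zero total reads is unsequenced, encoded as `NA`.
#'
#' @param meth_reads,unmeth_reads Non-negative integer vectors.
#' @return Numeric vector of levels in `[0, 1]`, `NA` where unsequenced.
#' @export
site_methylation_level <- function(meth_reads, unmeth_reads) {
  if (any(meth_reads < 0 | unmeth_reads < 0))
    stop("read counts must be non-negative", call. = FALSE)
  tot <- meth_reads + unmeth_reads
  ifelse(tot > 0, meth_reads / tot, NA_real_)
}

#' Collapse strand-level bisulfite observations into per-site levels
#'
#' A CpG site is keyed by the 0-based plus-strand position of its C; a
#' minus-strand record at position `p + 1` observes the site at `p`. When both
#' strands are sequenced the site level is the arithmetic mean of the two
#' per-strand levels ("two-strand average"); with one sequenced strand that
#' strand's level is used as-is; with neither the site is unsequenced (`NA`).
#'
#' @param records data.frame as from [read_cpg_table()] (`chrom`, `pos`,
#'   `strand`, `meth_reads`, `unmeth_reads`).
#' @return data.frame with `chrom`, `pos` (plus-strand C position), `level`
#'   (`NA` if unsequenced), `strands_observed` (`"none"`, `"plus"`, `"minus"`,
#'   `"both"`; sequenced strands only).
#' @export
collapse_strands <- function(records) {
  need <- c("chrom", "pos", "strand", "meth_reads", "unmeth_reads")
  stopifnot(all(need %in% names(records)))
  minus <- records$strand == "-"
  site_pos <- records$pos - minus
  if (any(site_pos < 0))
    stop("minus-strand record at position 0 cannot belong to a CpG site", call. = FALSE)
  # numeric site keys (chrom index * 1e10 + position) stay exact in doubles
  # and avoid string churn on genome-scale tables
  chrom_i <- as.integer(factor(records$chrom))
  key <- chrom_i * 1e10 + site_pos
  if (anyDuplicated(key * 2 + minus)) {
    d <- which(duplicated(key * 2 + minus))[1L]
    stop(sprintf("more than one record for site (%s, %d) strand %s",
                 records$chrom[d], site_pos[d], records$strand[d]), call. = FALSE)
  }
  lv <- site_methylation_level(records$meth_reads, records$unmeth_reads)
  seqd <- !is.na(lv)
  ukey <- sort(unique(key))
  idx <- match(key, ukey)
  n_seq <- as.vector(rowsum(as.numeric(seqd), idx, reorder = TRUE))
  sum_lv <- as.vector(rowsum(ifelse(seqd, lv, 0), idx, reorder = TRUE))
  plus_seq <- as.vector(rowsum(as.numeric(seqd & !minus), idx, reorder = TRUE)) > 0
  minus_seq <- as.vector(rowsum(as.numeric(seqd & minus), idx, reorder = TRUE)) > 0
  first <- match(seq_along(ukey), idx)
  level <- ifelse(n_seq > 0, sum_lv / n_seq, NA_real_)
  obs <- ifelse(plus_seq & minus_seq, "both",
                ifelse(plus_seq, "plus", ifelse(minus_seq, "minus", "none")))
  # ukey is sorted, so rows come out ordered by (chrom, pos)
  out <- data.frame(chrom = records$chrom[first],
                    pos = as.integer(site_pos[first]),
                    level = level, strands_observed = obs,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-promoter CMepG / CUn-MepG census with extrapolation
#'
#' For each promoter, the CpG census (`all_cpg_sites`) fixes the denominator:
#' every census CpG whose C lies in the promoter counts, sequenced or not.
#' Each unsequenced census site is assigned the mean level of the promoter's
#' sequenced sites (extrapolation), so that `meth_count` (the CMepG count,
#' sum of levels) and `unmeth_count` (the CUn-MepG count, sum of `1 - level`)
#' always satisfy `meth_count + unmeth_count = n_sites`. Promoters with no
#' sequenced site have undefined counts (`NA`) and fail the filter.
#'
#' The coverage filter keeps promoters with strictly more than `min_fraction`
#' of their census CpGs sequenced and at least `min_sequenced` sequenced CpGs.
#'
#' @param promoters data.frame from [derive_promoters()].
#' @param site_levels data.frame from [collapse_strands()]. Sequenced sites
#'   inside a promoter must be census sites; anything else is an error.
#' @param all_cpg_sites data.frame with `chrom`, `pos`: the CpG census, from
#'   [scan_cpg_positions()] or a CpG BED. The census is never inferred from
#'   the read table.
#' @param min_fraction,min_sequenced Coverage-filter thresholds (defaults
#'   0.5 strict and 4).
#' @return data.frame with `gene_id`, `n_sites`, `n_sequenced`, `meth_count`,
#'   `unmeth_count`, `pct_methylation` (in `[0, 100]`), `passes_filter`.
#' @export
profile_promoters <- function(promoters, site_levels, all_cpg_sites,
                              min_fraction = 0.5, min_sequenced = 4L) {
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(promoters)))
  stopifnot(all(c("chrom", "pos") %in% names(all_cpg_sites)))
  prom_gr <- .gr_from_df(promoters$chrom, promoters$start, promoters$end)
  census_gr <- .gr_from_df(all_cpg_sites$chrom, all_cpg_sites$pos, all_cpg_sites$pos + 1L)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(census_gr, prom_gr))
  cen_q <- S4Vectors::queryHits(hits)
  cen_s <- S4Vectors::subjectHits(hits)

  # attach observed levels to census sites by (chrom, pos) via numeric keys
  chroms <- unique(c(all_cpg_sites$chrom, site_levels$chrom))
  census_key <- match(all_cpg_sites$chrom, chroms) * 1e10 + all_cpg_sites$pos
  obs_key <- match(site_levels$chrom, chroms) * 1e10 + site_levels$pos
  lvl_at <- site_levels$level[match(census_key, obs_key)]

  # observed, sequenced sites inside a promoter must be census sites
  stray <- which(!is.na(site_levels$level) & !(obs_key %in% census_key))
  if (length(stray)) {
    so <- site_levels[stray, , drop = FALSE]
    obs_gr <- .gr_from_df(so$chrom, so$pos, so$pos + 1L)
    oh <- suppressWarnings(GenomicRanges::findOverlaps(obs_gr, prom_gr))
    if (length(oh)) {
      b <- so[S4Vectors::queryHits(oh)[1L], ]
      stop(sprintf("sequenced site (%s, %d) inside a promoter is not in the CpG census",
                   b$chrom, b$pos), call. = FALSE)
    }
  }

  n <- nrow(promoters)
  lev <- lvl_at[cen_q]
  seqd <- !is.na(lev)
  n_sites <- tabulate(cen_s, nbins = n)
  n_sequenced <- as.integer(tabulate(cen_s[seqd], nbins = n))
  sum_lvl <- numeric(n)
  if (any(seqd)) {
    tmp <- rowsum(lev[seqd], cen_s[seqd])
    sum_lvl[as.integer(rownames(tmp))] <- tmp[, 1L]
  }
  mean_lvl <- ifelse(n_sequenced > 0, sum_lvl / n_sequenced, NA_real_)
  meth <- sum_lvl + (n_sites - n_sequenced) * mean_lvl
  meth[n_sequenced == 0L] <- NA_real_
  unmeth <- n_sites - meth
  pct <- ifelse(n_sites > 0, 100 * meth / n_sites, NA_real_)
  out <- data.frame(gene_id = promoters$gene_id,
                    n_sites = n_sites, n_sequenced = n_sequenced,
                    meth_count = meth, unmeth_count = unmeth,
                    pct_methylation = pct,
                    stringsAsFactors = FALSE)
  out$passes_filter <- passes_coverage_filter(out, min_fraction, min_sequenced)
  rownames(out) <- NULL
  out
}

#' Coverage filter on promoter profiles
#'
#' A promoter passes when strictly more than `min_fraction` of its census
#' CpGs are sequenced (">50%") and it has at least `min_sequenced` sequenced
#' CpGs. Promoters with an empty census fail.
#'
#' @param profile data.frame with `n_sites` and `n_sequenced` (e.g. from
#'   [profile_promoters()]).
#' @param min_fraction Strict lower bound on `n_sequenced / n_sites`.
#' @param min_sequenced Non-strict lower bound on `n_sequenced`.
#' @return Logical vector.
#' @export
passes_coverage_filter <- function(profile, min_fraction = 0.5, min_sequenced = 4L) {
  stopifnot(all(c("n_sites", "n_sequenced") %in% names(profile)))
  with(profile, n_sites > 0 & n_sequenced / pmax(n_sites, 1L) > min_fraction &
         n_sequenced >= min_sequenced)
}
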