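## CGI / non-CGI promoter classification by overlap fraction, with the
## optional UMR-based robustness exclusion of the non-CGI group.

#' Fraction of a promoter covered by CpG islands
#'
#' Overlapped bases divided by the actual (possibly clipped) promoter length.
#' CGI intervals are merged first so fragmented annotations never double
#' count.
#'
#' @param promoters data.frame from [derive_promoters()].
#' @param cgi data.frame of intervals (`chrom`, `start`, `end`, 0-based
#'   half-open), e.g. from [read_intervals()].
#' @return Numeric vector of fractions in `[0, 1]`, one per promoter.
#' @export
promoter_cgi_fraction <- function(promoters, cgi) {
  stopifnot(all(c("chrom", "start", "end") %in% names(promoters)))
  cgi <- merge_intervals(cgi)
  n <- nrow(promoters)
  if (n == 0L) return(numeric())
  if (nrow(cgi) == 0L) return(numeric(n))
  prom_gr <- .gr_from_df(promoters$chrom, promoters$start, promoters$end)
  cgi_gr <- .gr_from_df(cgi$chrom, cgi$start, cgi$end)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(prom_gr, cgi_gr))
  ov <- GenomicRanges::width(suppressWarnings(IRanges::pintersect(
    prom_gr[S4Vectors::queryHits(hits)], cgi_gr[S4Vectors::subjectHits(hits)])))
  total <- numeric(n)
  if (length(ov)) {
    tmp <- rowsum(ov, S4Vectors::queryHits(hits))
    total[as.integer(rownames(tmp))] <- tmp[, 1L]
  }
  total / (promoters$end - promoters$start)
}

#' Classify promoters as CGI, non-CGI, or excluded
#'
#' A gene is a CGI gene when strictly more than `threshold` (default 10%) of
#' its promoter overlaps a CpG island, and a non-CGI gene when there is no
#' overlap at all. Genes in between (0 < fraction <= threshold) belong to
#' neither analysis group and are labelled `excluded`.
#'
#' @param fraction Numeric vector of overlap fractions
#'   ([promoter_cgi_fraction()]).
#' @param threshold Strict CGI threshold (default 0.10).
#' @return Character vector with values `"CGI"`, `"nonCGI"`, `"excluded"`.
#' @export
classify_cgi <- function(fraction, threshold = 0.10) {
  stopifnot(all(fraction >= 0 & fraction <= 1))
  ifelse(fraction > threshold, "CGI", ifelse(fraction == 0, "nonCGI", "excluded"))
}

#' Remove non-CGI genes whose promoter overlaps a constitutively
#' unmethylated region (UMR)
#'
#' Robustness variant of the classification: any overlap (>= 1 bp) between a
#' non-CGI promoter and a UMR flags the gene for removal from the non-CGI
#' group. CGI and excluded genes are untouched.
#'
#' @param classes data.frame with `gene_id` and `label` (from
#'   [classify_cgi()]).
#' @param promoters data.frame from [derive_promoters()] (same genes).
#' @param umr data.frame of UMR intervals.
#' @return `classes` with a logical `umr_excluded` column; the removed-gene
#'   report is the attribute `"removed"`.
#' @export
apply_umr_exclusion <- function(classes, promoters, umr) {
  stopifnot(all(c("gene_id", "label") %in% names(classes)))
  m <- match(classes$gene_id, promoters$gene_id)
  if (anyNA(m)) stop("classes and promoters must cover the same genes", call. = FALSE)
  umr <- merge_intervals(umr)
  flag <- logical(nrow(classes))
  if (nrow(umr) > 0L) {
    prom_gr <- .gr_from_df(promoters$chrom[m], promoters$start[m], promoters$end[m])
    umr_gr <- .gr_from_df(umr$chrom, umr$start, umr$end)
    ov <- suppressWarnings(GenomicRanges::countOverlaps(prom_gr, umr_gr)) > 0
    flag <- classes$label == "nonCGI" & ov
  }
  classes$umr_excluded <- flag
  attr(classes, "removed") <- classes$gene_id[flag]
  classes
}
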