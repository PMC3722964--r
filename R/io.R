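## Readers and writers for the external formats the pipeline touches.
## Internal convention: all coordinates 0-based, half-open. 1-based dialects
## (GTF, GRanges) are converted at this boundary and nowhere else.

# 0-based half-open data.frame -> GRanges (1-based closed)
.gr_from_df <- function(chrom, start, end, strand = "*") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end), strand = strand)
}

.df_from_gr <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

# number of leading comment ('#') lines, for error messages that name the
# offending file line
.n_leading_comments <- function(path) {
  n <- 0L
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L || !startsWith(ln, "#")) break
    n <- n + 1L
  }
  n
}

.has_header <- function(path, numeric_field) {
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) return(FALSE)
    if (!startsWith(ln, "#") && nzchar(trimws(ln))) break
  }
  fields <- strsplit(trimws(ln), "[\t ]+")[[1]]
  if (length(fields) < numeric_field) return(FALSE)
  suppressWarnings(is.na(as.numeric(fields[numeric_field])))
}

.stop_row <- function(path, row, offset, msg) {
  stop(sprintf("%s: line %d: %s", path, row + offset, msg), call. = FALSE)
}

#' Read a per-CpG bisulfite read-count table
#'
#' Each row is one strand-specific observation at a genomic CpG: chromosome,
#' position of the observed cytosine, strand, number of methylated reads and
#' number of unmethylated reads. Rows with zero total reads are legal and mean
#' "site not sequenced".
#'
#' @param path Path to the table. Lines starting with `#` are ignored; a
#'   header row is detected automatically.
#' @param dialect Column layout and coordinate base:
#'   * `"tsv"`: `chrom pos strand meth unmeth`, `pos` 0-based;
#'   * `"tsv-1based"`: same layout, `pos` 1-based (converted on read);
#'   * `"bedgraph-pair"`: `chrom start end strand meth unmeth`, 0-based
#'     half-open, the position taken as `start`.
#' @return A data.frame with columns `chrom`, `pos` (0-based position of the
#'   observed C), `strand` (`"+"`/`"-"`), `meth_reads`, `unmeth_reads`.
#' @seealso [collapse_strands()] to pair the two strand observations of a site.
#' @export
read_cpg_table <- function(path, dialect = c("tsv", "tsv-1based", "bedgraph-pair")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pos_field <- 2L
  header <- .has_header(path, pos_field)
  offset <- .n_leading_comments(path) + as.integer(header)
  df <- read.table(path, header = header, sep = "", comment.char = "#",
                   colClasses = "character", stringsAsFactors = FALSE)
  ncol_need <- if (dialect == "bedgraph-pair") 6L else 5L
  if (ncol(df) < ncol_need)
    stop(sprintf("%s: expected >= %d columns for dialect '%s', found %d",
                 path, ncol_need, dialect, ncol(df)), call. = FALSE)
  if (dialect == "bedgraph-pair") {
    out <- data.frame(chrom = df[[1L]], pos = df[[2L]], strand = df[[4L]],
                      meth_reads = df[[5L]], unmeth_reads = df[[6L]],
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(chrom = df[[1L]], pos = df[[2L]], strand = df[[3L]],
                      meth_reads = df[[4L]], unmeth_reads = df[[5L]],
                      stringsAsFactors = FALSE)
  }
  for (col in c("pos", "meth_reads", "unmeth_reads")) {
    v <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      .stop_row(path, bad[1L], offset, sprintf("non-numeric %s '%s'", col, out[[col]][bad[1L]]))
    if (any(v != trunc(v)))
      .stop_row(path, which(v != trunc(v))[1L], offset, sprintf("non-integer %s", col))
    out[[col]] <- as.integer(v)
  }
  if (dialect == "tsv-1based") out$pos <- out$pos - 1L
  bad <- which(out$pos < 0L)
  if (length(bad)) .stop_row(path, bad[1L], offset, "negative position")
  bad <- which(out$meth_reads < 0L | out$unmeth_reads < 0L)
  if (length(bad)) .stop_row(path, bad[1L], offset, "negative read count")
  bad <- which(!out$strand %in% c("+", "-"))
  if (length(bad))
    .stop_row(path, bad[1L], offset, sprintf("strand must be '+' or '-', got '%s'", out$strand[bad[1L]]))
  out
}

#' Read gene models and resolve each gene to a single TSS
#'
#' Supports BED (0-based half-open; TSS is `start` on `+`, `end - 1` on `-`)
#' and GTF (1-based inclusive, converted). A gene id that maps to more than
#' one distinct (chrom, tss, strand) is treated as having ambiguous location
#' and excluded; exact duplicate records are collapsed silently.
#'
#' @param path Path to a BED or GTF file.
#' @param dialect `"bed"` or `"gtf"`. For GTF, `gene` features are used when
#'   present, otherwise `transcript` features, otherwise all rows.
#' @return A list with `genes` (data.frame `gene_id`, `chrom`, `tss`
#'   (0-based), `strand`) and `rejected` (data.frame of ambiguous genes with
#'   their conflicting locations).
#' @export
read_gene_models <- function(path, dialect = c("bed", "gtf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = dialect)
  if (dialect == "gtf") {
    type <- as.character(gr$type)
    if (any(type == "gene")) gr <- gr[type == "gene"]
    else if (any(type == "transcript")) gr <- gr[as.character(gr$type) == "transcript"]
    ids <- gr$gene_id
    if (is.null(ids)) ids <- gr$transcript_id
  } else {
    ids <- gr$name
  }
  if (is.null(ids) || anyNA(ids))
    stop(path, ": every gene record needs an identifier (BED name / GTF gene_id)",
         call. = FALSE)
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*"))
    stop(path, ": gene records must be stranded", call. = FALSE)
  tss <- ifelse(strand == "+", GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr) - 1L)
  tab <- data.frame(gene_id = as.character(ids),
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    tss = as.integer(tss), strand = strand,
                    stringsAsFactors = FALSE)
  tab <- unique(tab)
  dup_ids <- unique(tab$gene_id[duplicated(tab$gene_id)])
  rejected <- tab[tab$gene_id %in% dup_ids, , drop = FALSE]
  genes <- tab[!tab$gene_id %in% dup_ids, , drop = FALSE]
  rownames(genes) <- rownames(rejected) <- NULL
  list(genes = genes, rejected = rejected)
}

#' Read an annotation interval track (BED)
#'
#' Intervals are kept 0-based half-open and overlapping or bookended
#' intervals on one chromosome are merged, so downstream overlap-fraction
#' computations never double count.
#'
#' @param path Path to a BED3+ file.
#' @return A data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), merged and sorted.
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) stop(path, ": invalid BED intervals: ",
                                          conditionMessage(e), call. = FALSE))
  if (any(GenomicRanges::width(gr) < 1L))
    stop(path, ": interval with start >= end", call. = FALSE)
  merge_intervals(.df_from_gr(gr))
}

#' Merge intervals to a minimal sorted disjoint set
#'
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @return The merged data.frame (union semantics; adjacent intervals joined).
#' @export
merge_intervals <- function(intervals) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (nrow(intervals) == 0L)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  if (any(intervals$start >= intervals$end))
    stop("interval with start >= end", call. = FALSE)
  gr <- GenomicRanges::reduce(.gr_from_df(intervals$chrom, intervals$start, intervals$end))
  out <- .df_from_gr(gr)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a two-column gene expression table
#'
#' @param path TSV with a header and columns gene id, expression value
#'   (e.g. FPKM). Lines starting with `#` are skipped.
#' @return data.frame with columns `gene_id`, `expression`.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop(path, ": expected two tab-separated columns", call. = FALSE)
  val <- suppressWarnings(as.numeric(df[[2L]]))
  if (anyNA(val)) {
    bad <- which(is.na(val))[1L]
    stop(sprintf("%s: row %d: non-numeric expression value '%s'", path, bad, df[[2L]][bad]),
         call. = FALSE)
  }
  if (any(val < 0))
    stop(path, ": negative expression value", call. = FALSE)
  if (anyDuplicated(df[[1L]]))
    stop(sprintf("%s: duplicate gene id '%s'", path, df[[1L]][duplicated(df[[1L]])][1L]),
         call. = FALSE)
  data.frame(gene_id = df[[1L]], expression = val, stringsAsFactors = FALSE)
}

#' Locate every CpG dinucleotide in a genome FASTA
#'
#' Sites are reported at the 0-based plus-strand position of the C; matching
#' is case-insensitive. Characters outside the IUPAC nucleotide alphabet are
#' replaced by `N` with a warning (they cannot form part of a CpG).
#'
#' @param path Path to a FASTA file.
#' @return data.frame with columns `chrom`, `pos` (0-based C position); the
#'   attribute `"seqlengths"` carries a named vector of sequence lengths.
#' @export
scan_cpg_positions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  seqs <- tryCatch(Biostrings::readDNAStringSet(path), error = function(e) {
    raw <- Biostrings::readBStringSet(path)
    warning("non-nucleotide characters in ", path, "; replaced by N", call. = FALSE)
    cleaned <- vapply(as.character(raw), function(s)
      gsub("[^ACGTRYSWKMBDHVNacgtryswkmbdhvn]", "N", s), character(1))
    Biostrings::DNAStringSet(cleaned)
  })
  hits <- Biostrings::vmatchPattern("CG", seqs, fixed = TRUE)
  chrom <- rep(names(seqs), S4Vectors::elementNROWS(hits))
  pos <- unlist(lapply(hits, BiocGenerics::start), use.names = FALSE)
  out <- data.frame(chrom = chrom,
                    pos = if (length(pos)) as.integer(pos - 1L) else integer(),
                    stringsAsFactors = FALSE)
  attr(out, "seqlengths") <- setNames(Biostrings::width(seqs), names(seqs))
  out
}

#' Write a result table as TSV with '#' comment header lines
#'
#' @param df data.frame to write.
#' @param path Output path.
#' @param comments Character vector of metadata lines (written as `# ...`).
#' @return `path`, invisibly.
#' @export
write_result_table <- function(df, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  # fixed full-precision formatting: doubles survive the round-trip exactly
  # and reruns stay byte-identical
  fmt <- df
  for (j in seq_along(fmt)) {
    if (is.numeric(fmt[[j]]) && !is.integer(fmt[[j]]))
      fmt[[j]] <- sprintf("%.17g", fmt[[j]])
  }
  write.table(fmt, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a table written by [write_result_table()]
#'
#' @param path Path to the TSV.
#' @return data.frame with types restored by [utils::type.convert()].
#' @export
read_result_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  utils::type.convert(df, as.is = TRUE)
}
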