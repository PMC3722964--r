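## End-to-end orchestration: configuration, stage wiring, result tables and
## a machine-readable run manifest.

#' Pipeline configuration
#'
#' Collects input paths and the analysis parameters. Defaults equal the
#' study's stated choices (1000 bp promoters, >50% / >=4 coverage filter,
#' 10% CGI threshold, 10 equal-count bins, fixed spans 1.8 / 2.0 for the
#' CMepG / CUn-MepG features, Mann-Whitney bar 0.001), so a bare run
#' reproduces the canonical analysis.
#'
#' @param cpg_reads,genes,cgi,umr,expression,fasta,cpg_sites Input paths
#'   (`umr`, `fasta`, `cpg_sites` optional; the CpG census comes from
#'   `cpg_sites` (BED) when given, otherwise from scanning `fasta`).
#' @param cpg_dialect Dialect for [read_cpg_table()].
#' @param gene_dialect `"bed"` or `"gtf"`.
#' @param upstream_len Promoter length (default 1000).
#' @param min_fraction,min_sequenced Coverage-filter thresholds (0.5 strict, 4).
#' @param cgi_threshold Strict CGI overlap threshold (0.10).
#' @param k Number of equal-count bins (10).
#' @param spans Named fixed-span widths (`meth_count` 1.8, `unmeth_count` 2).
#' @param mw_alpha Mann-Whitney significance bar (0.001).
#' @param umr_exclusion Drop non-CGI genes whose promoter overlaps a UMR.
#' @param fixed_span Also run the fixed-span binning variant.
#' @param stratified Also compute methylation-stratified CUn-MepG bin medians.
#' @param seed Seed for the `simulate` stage.
#' @param sim_params Optional [methylome_params()] object for the `simulate`
#'   stage (default: generator defaults at `seed`).
#' @param outdir Output directory.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(cpg_reads = NULL, genes = NULL, cgi = NULL,
                            umr = NULL, expression = NULL, fasta = NULL,
                            cpg_sites = NULL,
                            cpg_dialect = "tsv", gene_dialect = "bed",
                            upstream_len = 1000L, min_fraction = 0.5,
                            min_sequenced = 4L, cgi_threshold = 0.10,
                            k = 10L, spans = c(meth_count = 1.8, unmeth_count = 2),
                            mw_alpha = 0.001, umr_exclusion = FALSE,
                            fixed_span = FALSE, stratified = FALSE,
                            seed = 1L, sim_params = NULL,
                            outdir = tempfile("methbin_run")) {
  stopifnot(upstream_len > 0, min_fraction > 0, min_sequenced > 0,
            cgi_threshold > 0, k >= 2, all(spans > 0), mw_alpha > 0)
  cfg <- list(cpg_reads = cpg_reads, genes = genes, cgi = cgi, umr = umr,
              expression = expression, fasta = fasta, cpg_sites = cpg_sites,
              cpg_dialect = cpg_dialect, gene_dialect = gene_dialect,
              upstream_len = as.integer(upstream_len),
              min_fraction = min_fraction,
              min_sequenced = as.integer(min_sequenced),
              cgi_threshold = cgi_threshold, k = as.integer(k), spans = spans,
              mw_alpha = mw_alpha, umr_exclusion = umr_exclusion,
              fixed_span = fixed_span, stratified = stratified,
              seed = as.integer(seed), sim_params = sim_params,
              outdir = outdir)
  class(cfg) <- "pipeline_config"
  cfg
}

.require_inputs <- function(cfg, keys) {
  for (k in keys) {
    p <- cfg[[k]]
    if (is.null(p)) stop("input missing: no '", k, "' path configured", call. = FALSE)
    if (!file.exists(p)) stop("input missing: ", p, call. = FALSE)
  }
}

#' Integrate promoter profiles, CGI classes, and expression into gene records
#'
#' Keeps genes that pass the coverage filter, belong to the CGI or non-CGI
#' analysis group, (optionally) survive the UMR exclusion, and have an
#' expression value. Exclusion counts at each step are in the attribute
#' `"counts"`.
#'
#' @param profiles data.frame from [profile_promoters()].
#' @param classes data.frame with `gene_id`, `label` (and `umr_excluded` if
#'   UMR exclusion was applied).
#' @param expression data.frame from [read_expression()].
#' @param umr_exclusion Apply the `umr_excluded` flag (default `FALSE`).
#' @return data.frame of gene records for [run_analysis()].
#' @export
integrate_gene_records <- function(profiles, classes, expression,
                                   umr_exclusion = FALSE) {
  counts <- list(profiled = nrow(profiles))
  keep <- profiles[profiles$passes_filter, , drop = FALSE]
  counts$pass_coverage_filter <- nrow(keep)
  m <- match(keep$gene_id, classes$gene_id)
  keep$cgi_label <- classes$label[m]
  counts$cgi <- sum(keep$cgi_label == "CGI", na.rm = TRUE)
  counts$noncgi <- sum(keep$cgi_label == "nonCGI", na.rm = TRUE)
  counts$excluded_overlap <- sum(keep$cgi_label == "excluded", na.rm = TRUE)
  keep <- keep[!is.na(keep$cgi_label) & keep$cgi_label %in% c("CGI", "nonCGI"), ,
               drop = FALSE]
  if (umr_exclusion) {
    if (is.null(classes$umr_excluded))
      stop("umr_exclusion requested but classes carry no umr_excluded flag",
           call. = FALSE)
    flag <- classes$umr_excluded[match(keep$gene_id, classes$gene_id)]
    counts$umr_removed <- sum(flag)
    keep <- keep[!flag, , drop = FALSE]
  } else counts$umr_removed <- 0L
  e <- match(keep$gene_id, expression$gene_id)
  counts$no_expression <- sum(is.na(e))
  keep$expression <- expression$expression[e]
  keep <- keep[!is.na(keep$expression), , drop = FALSE]
  counts$final <- nrow(keep)
  out <- data.frame(gene_id = keep$gene_id, meth_count = keep$meth_count,
                    unmeth_count = keep$unmeth_count,
                    cpg_count = keep$meth_count + keep$unmeth_count,
                    pct_methylation = keep$pct_methylation,
                    cgi_label = keep$cgi_label, expression = keep$expression,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "counts") <- counts
  out
}

#' Write the analysis result bundle as TSV tables
#'
#' Emits `trend_results.tsv`, one `bins_<class>_<feature>.tsv` per
#' assignment, `subbin_tests.tsv`, per-bin `ecdf_<class>_<feature>_<bin>.tsv`
#' tables, and the optional fixed-span / stratified tables. All tables
#' round-trip through [read_result_table()].
#'
#' @param res A `"cpg_bin_analysis"` object.
#' @param outdir Output directory (created if missing).
#' @return Character vector of written paths, invisibly.
#' @export
write_analysis_tables <- function(res, outdir) {
  stopifnot(inherits(res, "cpg_bin_analysis"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  w <- function(df, name) {
    p <- file.path(outdir, name)
    write_result_table(df, p, sprintf("k: %d", res$config$k))
    written <<- c(written, p)
  }
  w(res$trends, "trend_results.tsv")
  w(res$bin_summaries, "bin_summaries.tsv")
  w(res$subbins, "subbin_tests.tsv")
  for (cl in names(res$assignments))
    for (ft in names(res$assignments[[cl]]))
      w(res$assignments[[cl]][[ft]], sprintf("bins_%s_%s.tsv", cl, ft))
  if (!is.null(res$ecdfs))
    for (cl in names(res$ecdfs))
      for (ft in names(res$ecdfs[[cl]]))
        for (b in names(res$ecdfs[[cl]][[ft]]))
          w(res$ecdfs[[cl]][[ft]][[b]], sprintf("ecdf_%s_%s_%s.tsv", cl, ft, b))
  if (!is.null(res$fixed_span)) {
    w(res$fixed_span$trends, "fixed_span_trends.tsv")
    w(res$fixed_span$bins, "fixed_span_bins.tsv")
  }
  if (!is.null(res$stratified))
    w(res$stratified, "stratified_medians.tsv")
  invisible(written)
}

#' Run the pipeline
#'
#' Stages run in study order: simulate (optional) -> promoter profiling ->
#' CGI classification -> integration and bin analysis. Intermediate tables
#' (`promoters.tsv`, `promoter_profiles.tsv`, `cgi_classes.tsv`,
#' `gene_records.tsv`) and the result bundle are written under
#' `config$outdir`, together with `manifest.json` recording the
#' configuration, input checksums, and gene counts at every filter step.
#' Reruns with identical inputs and configuration produce byte-identical
#' tables.
#'
#' @param subcommand One of `"all"`, `"simulate"`, `"profile"`, `"classify"`,
#'   `"analyze"`. `"simulate"` generates data only; `"all"` chains every
#'   stage (generating synthetic inputs first only when no `cpg_reads` input
#'   is configured); the single-stage subcommands read their inputs from the
#'   configured paths / earlier outputs in `outdir`.
#' @param config A [pipeline_config()] object.
#' @return Invisibly, a list with `analysis` (the `"cpg_bin_analysis"`
#'   object, when the analyze stage ran), `manifest`, and `outdir`.
#' @export
run_pipeline <- function(subcommand = c("all", "simulate", "profile",
                                        "classify", "analyze"),
                         config = pipeline_config()) {
  subcommand <- match.arg(subcommand)
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(subcommand = subcommand, counts = list(), outputs = character())
  analysis <- NULL

  do_sim <- subcommand == "simulate" ||
    (subcommand == "all" && is.null(config$cpg_reads))
  if (do_sim) {
    sim <- simulate_methylome(if (!is.null(config$sim_params)) config$sim_params
                              else methylome_params(seed = config$seed),
                              file.path(outdir, "sim"))
    for (k in intersect(names(sim$paths),
                        c("cpg_reads", "genes", "cgi", "umr", "expression", "cpg_sites")))
      config[[k]] <- sim$paths[[k]]
    manifest$counts$simulated_genes <- nrow(sim$truth)
  }
  if (subcommand == "simulate") {
    manifest$config <- .manifest_config(config)
    manifest <- .write_manifest(manifest, config, outdir)
    return(invisible(list(analysis = NULL, manifest = manifest, outdir = outdir)))
  }

  stages <- switch(subcommand, all = c("profile", "classify", "analyze"),
                   subcommand)

  promoters <- profiles <- classes <- NULL
  if ("profile" %in% stages) {
    .require_inputs(config, c("cpg_reads", "genes"))
    if (is.null(config$cpg_sites) && is.null(config$fasta))
      stop("input missing: need a CpG census ('cpg_sites' BED or 'fasta')",
           call. = FALSE)
    gm <- read_gene_models(config$genes, config$gene_dialect)
    manifest$counts$gene_models <- nrow(gm$genes) + length(unique(gm$rejected$gene_id))
    manifest$counts$ambiguous_location <- length(unique(gm$rejected$gene_id))
    census <- if (!is.null(config$cpg_sites)) {
      .require_inputs(config, "cpg_sites")
      # one row per site; deliberately unmerged so back-to-back CpGs stay distinct
      gr <- rtracklayer::import(config$cpg_sites, format = "bed")
      data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                 pos = GenomicRanges::start(gr) - 1L, stringsAsFactors = FALSE)
    } else scan_cpg_positions(config$fasta)
    seqlen <- attr(census, "seqlengths")
    promoters <- derive_promoters(gm$genes, config$upstream_len, seqlen)
    manifest$counts$promoters <- nrow(promoters)
    reads <- read_cpg_table(config$cpg_reads, config$cpg_dialect)
    sites <- collapse_strands(reads)
    profiles <- profile_promoters(promoters, sites, census,
                                  config$min_fraction, config$min_sequenced)
    manifest$counts$pass_coverage_filter <- sum(profiles$passes_filter)
    write_result_table(promoters, file.path(outdir, "promoters.tsv"))
    write_result_table(profiles, file.path(outdir, "promoter_profiles.tsv"))
  }

  if ("classify" %in% stages) {
    .require_inputs(config, "cgi")
    if (is.null(promoters)) {
      p <- file.path(outdir, "promoters.tsv")
      if (!file.exists(p)) stop("input missing: ", p, " (run 'profile' first)",
                                call. = FALSE)
      promoters <- read_result_table(p)
    }
    frac <- promoter_cgi_fraction(promoters, read_intervals(config$cgi))
    classes <- data.frame(gene_id = promoters$gene_id, overlap_fraction = frac,
                          label = classify_cgi(frac, config$cgi_threshold),
                          stringsAsFactors = FALSE)
    if (!is.null(config$umr)) {
      .require_inputs(config, "umr")
      classes <- apply_umr_exclusion(classes, promoters, read_intervals(config$umr))
    } else classes$umr_excluded <- FALSE
    manifest$counts$cgi <- sum(classes$label == "CGI")
    manifest$counts$noncgi <- sum(classes$label == "nonCGI")
    manifest$counts$excluded_overlap <- sum(classes$label == "excluded")
    manifest$counts$umr_flagged <- sum(classes$umr_excluded)
    write_result_table(classes, file.path(outdir, "cgi_classes.tsv"))
  }

  if ("analyze" %in% stages) {
    .require_inputs(config, "expression")
    if (is.null(profiles)) {
      p <- file.path(outdir, "promoter_profiles.tsv")
      if (!file.exists(p)) stop("input missing: ", p, " (run 'profile' first)",
                                call. = FALSE)
      profiles <- read_result_table(p)
    }
    if (is.null(classes)) {
      p <- file.path(outdir, "cgi_classes.tsv")
      if (!file.exists(p)) stop("input missing: ", p, " (run 'classify' first)",
                                call. = FALSE)
      classes <- read_result_table(p)
    }
    expr <- read_expression(config$expression)
    records <- integrate_gene_records(profiles, classes, expr,
                                      config$umr_exclusion)
    manifest$counts <- c(manifest$counts, attr(records, "counts"))
    write_result_table(records, file.path(outdir, "gene_records.tsv"))
    analysis <- run_analysis(records, k = config$k, mw_alpha = config$mw_alpha,
                             fixed_span = if (isTRUE(config$fixed_span)) config$spans else NULL,
                             stratified = config$stratified)
    manifest$outputs <- basename(write_analysis_tables(analysis, outdir))
  }

  manifest$config <- .manifest_config(config)
  manifest <- .write_manifest(manifest, config, outdir)
  invisible(list(analysis = analysis, manifest = manifest, outdir = outdir))
}

.manifest_config <- function(config) {
  cfg <- unclass(config)
  if (!is.null(cfg$sim_params)) cfg$sim_params <- unclass(cfg$sim_params)
  cfg[!vapply(cfg, is.null, logical(1))]
}

.write_manifest <- function(manifest, config, outdir) {
  ins <- c("cpg_reads", "genes", "cgi", "umr", "expression", "fasta", "cpg_sites")
  paths <- unlist(.manifest_config(config)[ins])
  if (length(paths))
    manifest$input_md5 <- as.list(tools::md5sum(paths[file.exists(paths)]))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
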