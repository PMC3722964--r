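## Seeded synthetic methylome + expression generator with known ground truth.
## Expression follows a combined activator/repressor law on the latent
## unmethylated (U) and methylated (M) promoter CpG counts:
##   log E = a * min(U, u_sat) - b * M * 1(U < u_sat) + N(0, noise_sd),
## i.e. CUn-MepG-binding activators saturate at u_sat and methyl-binding
## repressors matter only below saturation. Presets zero one slope.

#' Parameters of the synthetic methylome generator
#'
#' Defaults describe a genome-scale study: 12000 genes of which 64% carry a
#' promoter CpG island (CGI), overdispersed promoter CpG counts (negative
#' binomial; mean 15 for non-CGI, 60 for CGI promoters), promoter methylation
#' concentrated near 0 for CGI promoters and broad on `[0, 1]` for non-CGI
#' promoters, per-site beta jitter around the promoter level, Poisson read
#' coverage of mean 10 per strand with a 15% per-strand chance of a site
#' being unsequenced.
#'
#' @param n_genes Number of genes (default 12000).
#' @param cgi_fraction Fraction of genes whose promoter carries a CGI
#'   (default 0.64).
#' @param cpg_mu,cpg_size Named vectors (`nonCGI`, `CGI`): negative-binomial
#'   mean and size of the promoter CpG count.
#' @param meth_beta List (`nonCGI`, `CGI`) of beta shape pairs for the
#'   promoter methylation level.
#' @param site_concentration Beta concentration of per-site levels around the
#'   promoter level (larger = less jitter; default 12).
#' @param coverage Mean reads per strand per site (default 10).
#' @param p_unsequenced Per-strand probability that a site has no reads
#'   (default 0.15).
#' @param model `"combined"` (default), `"activator_only"` (forces `b = 0`)
#'   or `"repressor_only"` (forces `a = 0`).
#' @param a Activation slope per unmethylated CpG (log-expression units;
#'   default 0.15).
#' @param u_sat Saturation point of the activator term, in CpGs (default 20).
#' @param b Repression slope per methylated CpG below saturation
#'   (default 0.05).
#' @param noise_sd Gaussian noise sd on log-expression (default 1).
#' @param umr_fraction Fraction of non-CGI promoters annotated as containing
#'   a constitutively unmethylated region (default 0.02).
#' @param seed Integer seed; every random draw is governed by it.
#' @return Validated list of class `"methylome_params"`.
#' @export
methylome_params <- function(n_genes = 12000L, cgi_fraction = 0.64,
                             cpg_mu = c(nonCGI = 15, CGI = 60),
                             cpg_size = c(nonCGI = 5, CGI = 15),
                             meth_beta = list(nonCGI = c(0.9, 0.9), CGI = c(0.6, 12)),
                             site_concentration = 12,
                             coverage = 10, p_unsequenced = 0.15,
                             model = c("combined", "activator_only", "repressor_only"),
                             a = 0.15, u_sat = 20, b = 0.05, noise_sd = 1,
                             umr_fraction = 0.02, seed = 1L) {
  model <- match.arg(model)
  if (model == "activator_only") b <- 0
  if (model == "repressor_only") a <- 0
  p <- list(n_genes = as.integer(n_genes), cgi_fraction = cgi_fraction,
            cpg_mu = cpg_mu, cpg_size = cpg_size, meth_beta = meth_beta,
            site_concentration = site_concentration, coverage = coverage,
            p_unsequenced = p_unsequenced, model = model, a = a,
            u_sat = u_sat, b = b, noise_sd = noise_sd,
            umr_fraction = umr_fraction, seed = as.integer(seed))
  with(p, {
    stopifnot(n_genes >= 1, cgi_fraction >= 0, cgi_fraction <= 1,
              all(cpg_mu > 0), all(cpg_size > 0),
              all(vapply(meth_beta, function(x) all(x > 0), logical(1))),
              site_concentration > 0, coverage > 0,
              p_unsequenced >= 0, p_unsequenced <= 1,
              a >= 0, b >= 0, u_sat > 0, noise_sd >= 0,
              umr_fraction >= 0, umr_fraction <= 1)
  })
  class(p) <- "methylome_params"
  p
}

# gene layout constants: one gene per 5 kb slot, promoter fully inside it
.SLOT <- 5000L
.N_CHROM <- 4L

#' Generate a synthetic methylome + expression dataset
#'
#' Writes, under `dir`: `cpg_reads.tsv` (strand-level bisulfite counts),
#' `genes.bed`, `cgi.bed`, `cpg_sites.bed` (the CpG census), `umr.bed` (when
#' `umr_fraction > 0`), `expression.tsv` and the ground-truth sidecar
#' `truth.tsv`. Output is fully determined by `params$seed`: the same seed
#' yields byte-identical files.
#'
#' Per gene, CpG sites are placed on an even-position grid inside its 1000 bp
#' promoter; per-site methylation levels are beta-distributed around the
#' gene's promoter level; per-strand read depths are Poisson with dropout;
#' and expression follows the activator/repressor law described in
#' [methylome_params()], exponentiated to an FPKM-like value. The CGI track
#' covers 60% of each CGI-class promoter so the >10% overlap rule recovers
#' the class.
#'
#' @param params A [methylome_params()] object.
#' @param dir Output directory (created if missing).
#' @param write If `FALSE`, draw only the latent truth (classes, counts,
#'   expression) and write nothing: read counts are never drawn, so the truth
#'   is identical to a full run with the same seed. Useful when calibrating
#'   the downstream statistics over many seeds.
#' @return Invisibly, a list with `paths` (named file paths; `NULL` when
#'   `write = FALSE`), `truth` (data.frame: `gene_id`, `class`, `cpg_count`,
#'   `M`, `U`, `log_expr`, `expression`), and `params`.
#' @export
simulate_methylome <- function(params = methylome_params(),
                               dir = tempfile("methbin_sim"), write = TRUE) {
  stopifnot(inherits(params, "methylome_params"))
  if (write) dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(params$seed)
  n <- params$n_genes

  cls <- ifelse(runif(n) < params$cgi_fraction, "CGI", "nonCGI")
  strand <- ifelse(runif(n) < 0.5, "+", "-")
  chrom <- paste0("chr", rep_len(seq_len(.N_CHROM), n))
  slot_idx <- ave(seq_len(n), chrom, FUN = seq_along) - 1L
  slot_start <- slot_idx * .SLOT
  tss <- slot_start + 1500L
  prom_start <- ifelse(strand == "+", tss - 1000L, tss + 1L)
  prom_end <- prom_start + 1000L

  cpg_count <- pmax(1L, pmin(450L, rnbinom(n, mu = params$cpg_mu[cls],
                                           size = params$cpg_size[cls])))
  m_shapes <- do.call(rbind, params$meth_beta[cls])
  m_gene <- pmin(0.998, pmax(0.002, rbeta(n, m_shapes[, 1L], m_shapes[, 2L])))

  gene_id <- sprintf("G%05d", seq_len(n))

  # per-site positions (even offsets keep CpG sites disjoint) and true levels
  site_gene <- rep.int(seq_len(n), cpg_count)
  offsets <- unlist(lapply(seq_len(n), function(i)
    sort(sample.int(500L, cpg_count[i]) - 1L) * 2L), use.names = FALSE)
  site_pos <- prom_start[site_gene] + offsets
  kap <- params$site_concentration
  mg <- m_gene[site_gene]
  site_level <- rbeta(length(site_gene), kap * mg, kap * (1 - mg))

  M <- as.vector(rowsum(site_level, site_gene))
  U <- cpg_count - M
  log_expr <- params$a * pmin(U, params$u_sat) -
    params$b * M * (U < params$u_sat)
  expr <- exp(log_expr + rnorm(n, 0, params$noise_sd))

  truth <- data.frame(gene_id = gene_id, class = cls, cpg_count = cpg_count,
                      M = M, U = U, log_expr = log_expr, expression = expr,
                      stringsAsFactors = FALSE)
  if (!write)
    return(invisible(list(paths = NULL, truth = truth, params = params)))

  # strand-level read counts with dropout
  ns <- length(site_gene)
  reads <- lapply(c("+", "-"), function(st) {
    depth <- ifelse(runif(ns) < params$p_unsequenced, 0L, rpois(ns, params$coverage))
    meth <- rbinom(ns, depth, site_level)
    keep <- depth > 0L
    data.frame(chrom = chrom[site_gene][keep],
               pos = site_pos[keep] + (st == "-"),
               strand = st, meth_reads = meth[keep],
               unmeth_reads = depth[keep] - meth[keep],
               stringsAsFactors = FALSE)
  })
  reads <- do.call(rbind, reads)
  reads <- reads[order(reads$chrom, reads$pos, reads$strand), , drop = FALSE]

  hdr <- c("methbin synthetic dataset",
           sprintf("seed: %d", params$seed),
           sprintf("model: %s", params$model),
           sprintf("n_genes: %d  cgi_fraction: %g  a: %g  b: %g  u_sat: %g  noise_sd: %g",
                   n, params$cgi_fraction, params$a, params$b, params$u_sat,
                   params$noise_sd),
           sprintf("coverage: %g  p_unsequenced: %g  site_concentration: %g",
                   params$coverage, params$p_unsequenced, params$site_concentration))

  paths <- c(cpg_reads = file.path(dir, "cpg_reads.tsv"),
             genes = file.path(dir, "genes.bed"),
             cgi = file.path(dir, "cgi.bed"),
             cpg_sites = file.path(dir, "cpg_sites.bed"),
             expression = file.path(dir, "expression.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_result_table(reads, paths[["cpg_reads"]], hdr)

  # gene models: BED6, TSS = start on '+', end - 1 on '-'
  gene_bed <- data.frame(chrom = chrom,
                         start = ifelse(strand == "+", tss, tss - 1499L),
                         end = ifelse(strand == "+", tss + 1500L, tss + 1L),
                         name = gene_id, score = 0L, strand = strand)
  write.table(gene_bed, paths[["genes"]], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  is_cgi <- cls == "CGI"
  cgi_bed <- data.frame(chrom = chrom[is_cgi],
                        start = prom_start[is_cgi] + 200L,
                        end = prom_start[is_cgi] + 800L)
  cgi_bed <- cgi_bed[order(cgi_bed$chrom, cgi_bed$start), , drop = FALSE]
  write.table(cgi_bed, paths[["cgi"]], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  census <- data.frame(chrom = chrom[site_gene], start = site_pos,
                       end = site_pos + 1L)
  census <- census[order(census$chrom, census$start), , drop = FALSE]
  write.table(census, paths[["cpg_sites"]], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  if (params$umr_fraction > 0) {
    noncgi_idx <- which(!is_cgi)
    n_umr <- floor(params$umr_fraction * length(noncgi_idx))
    umr_idx <- sort(sample(noncgi_idx, n_umr))
    umr_bed <- data.frame(chrom = chrom[umr_idx],
                          start = prom_start[umr_idx] + 400L,
                          end = prom_start[umr_idx] + 600L)
    umr_bed <- umr_bed[order(umr_bed$chrom, umr_bed$start), , drop = FALSE]
    paths[["umr"]] <- file.path(dir, "umr.bed")
    write.table(umr_bed, paths[["umr"]], sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }

  write_result_table(data.frame(gene_id = gene_id, expression = expr),
                     paths[["expression"]], hdr)
  write_result_table(truth, paths[["truth"]], hdr)

  invisible(list(paths = paths, truth = truth, params = params))
}

#' Gene records straight from generator ground truth
#'
#' Bypasses the read-level pipeline: builds the integrated gene-record table
#' from the latent per-gene counts, useful for calibrating the statistics
#' themselves (e.g. null calibration) without re-estimating the counts from
#' reads.
#'
#' @param truth data.frame from [simulate_methylome()] (`$truth`).
#' @return data.frame suitable for [run_analysis()].
#' @export
truth_gene_records <- function(truth) {
  data.frame(gene_id = truth$gene_id,
             meth_count = truth$M, unmeth_count = truth$U,
             cpg_count = truth$cpg_count,
             pct_methylation = 100 * truth$M / truth$cpg_count,
             cgi_label = truth$class, expression = truth$expression,
             stringsAsFactors = FALSE)
}

#' Predicted signs of the four class x feature trends
#'
#' Qualitative expectations under the generator's expression law, mirroring
#' the schematic predictions of the three models: with active activators
#' (`a > 0`) the non-CGI CUn-MepG trend is positive; repression (`b > 0`)
#' makes the non-CGI CMepG trend negative (weakly so when activation
#' dominates); CGI trends are flat whenever the typical CGI promoter sits
#' above the activator saturation point.
#'
#' @param params A [methylome_params()] object.
#' @return Named character vector (`nonCGI_unmeth`, `nonCGI_meth`,
#'   `CGI_unmeth`, `CGI_meth`) with values `"positive"`, `"weak_positive"`,
#'   `"negative"`, `"weak_negative"`, `"flat"`.
#' @export
expected_qualitative_pattern <- function(params = methylome_params()) {
  stopifnot(inherits(params, "methylome_params"))
  beta_mean <- function(sh) sh[1L] / (sh[1L] + sh[2L])
  mean_u_cgi <- (1 - beta_mean(params$meth_beta$CGI)) * params$cpg_mu[["CGI"]]
  cgi_saturated <- mean_u_cgi > params$u_sat
  nonCGI_unmeth <- if (params$a > 0) "positive"
    else if (params$b > 0) "weak_positive" else "flat"
  nonCGI_meth <- if (params$b > 0 && params$a == 0) "negative"
    else if (params$b > 0 || params$a > 0) "weak_negative" else "flat"
  c(nonCGI_unmeth = nonCGI_unmeth,
    nonCGI_meth = nonCGI_meth,
    CGI_unmeth = if (cgi_saturated) "flat" else nonCGI_unmeth,
    CGI_meth = if (cgi_saturated) "flat" else nonCGI_meth)
}
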