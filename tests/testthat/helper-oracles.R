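# Independent brute-force oracles used to check the package's exact
# nonparametric p-values, plus small fixture builders.

# Mann-Whitney U by direct pair counting (no rank-sum formula)
oracle_mw_U <- function(high, low) {
  sum(outer(high, low, ">")) + 0.5 * sum(outer(high, low, "=="))
}

# one-sided exact p (high stochastically greater) by enumerating every
# assignment of the pooled values to the two group labels
oracle_mw_p <- function(high, low) {
  pooled <- c(high, low)
  n1 <- length(high)
  U_obs <- oracle_mw_U(high, low)
  sel <- combn(length(pooled), n1)
  U_all <- apply(sel, 2L, function(ix) oracle_mw_U(pooled[ix], pooled[-ix]))
  mean(U_all >= U_obs - 1e-9)
}

# all permutations of a vector, by simple recursion (deliberately a
# different construction from the package's)
oracle_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(oracle_perms(v[-i]), function(p) c(v[i], p)))
  out
}

# exact permutation p for Spearman's rho via full enumeration and
# stats::cor on each permutation
oracle_spearman_p <- function(x, y, alternative = "two.sided") {
  rho_obs <- cor(x, y, method = "spearman")
  rhos <- vapply(oracle_perms(seq_along(y)),
                 function(p) cor(x, y[p], method = "spearman"), numeric(1))
  if (alternative == "two.sided") mean(abs(rhos) >= abs(rho_obs) - 1e-12)
  else mean(rhos >= rho_obs - 1e-12)
}

# minimal promoter/profile fixture: one promoter with the given census
# positions and observed site levels
profile_one <- function(levels, n_sites, chrom = "chr1") {
  stopifnot(length(levels) <= n_sites)
  prom <- data.frame(gene_id = "g1", chrom = chrom, start = 0L,
                     end = 1000L, strand = "+", clipped = FALSE)
  census <- data.frame(chrom = chrom, pos = seq_len(n_sites) * 2L)
  obs <- if (length(levels))
    data.frame(chrom = chrom, pos = seq_along(levels) * 2L, level = levels,
               strands_observed = ifelse(is.na(levels), "none", "plus"))
  else data.frame(chrom = character(), pos = integer(), level = numeric(),
                  strands_observed = character())
  profile_promoters(prom, obs, census)
}

# gene-record table with prescribed class sizes and simple features, for
# shape tests of run_analysis()
toy_records <- function(n_cgi = 60, n_noncgi = 60, seed = 1) {
  set.seed(seed)
  n <- n_cgi + n_noncgi
  cpg <- c(rpois(n_cgi, 60), rpois(n_noncgi, 15)) + 1L
  m <- c(rbeta(n_cgi, 0.6, 12), rbeta(n_noncgi, 1, 1)) * cpg
  data.frame(gene_id = sprintf("g%04d", seq_len(n)),
             meth_count = m, unmeth_count = cpg - m,
             cpg_count = as.numeric(cpg),
             pct_methylation = 100 * m / cpg,
             cgi_label = rep(c("CGI", "nonCGI"), c(n_cgi, n_noncgi)),
             expression = exp(rnorm(n)),
             stringsAsFactors = FALSE)
}
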