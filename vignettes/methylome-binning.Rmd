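---
title: "Counting methylated and unmethylated promoter CpGs: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting methylated and unmethylated promoter CpGs: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methbin)
```

## The question and the accounting model

Methylation of a promoter CpG simultaneously creates a methylated CpG
(CMepG) and removes an unmethylated one (CUn-MepG). If repression works
through methyl-CpG binding proteins, expression should fall with the CMepG
count; if it works by denying CXXC-domain activators their unmethylated
substrate, expression should rise with the CUn-MepG count. Because the two
counts are complementary (`m + u = n`, the promoter CpG census), they are
strongly anti-correlated across genes, and separating their effects requires
the bin-and-split design implemented here rather than a single regression.

The per-promoter accounting is deliberately simple. Each CpG site's
methylation level is the fraction of methylated reads, averaging the two
strands when both were sequenced. The CMepG count is the sum of levels over
the promoter's census sites; unsequenced census sites are imputed at the
mean level of the sequenced sites in the same promoter. This extrapolation
is what makes the conservation identity `m + u = n` hold exactly (to
floating tolerance) for every promoter, including partially sequenced ones —
the identity the sub-bin logic depends on, since fixing `m` within a bin
makes variation in `u` equivalent to variation in `n`.

Two assumptions are worth making explicit. First, the census denominator
`n` must come from the genome (a CpG BED or a FASTA scan), never from the
read table: inferring it from observed reads would conflate coverage with
CpG content. Second, the promoter is a fixed 1000 bp window upstream of the
TSS, excluding the TSS base itself; the minus-strand promoter mirrors the
plus-strand rule. Promoters clipped at a chromosome edge keep their genes,
flagged, with the *actual* length used as the denominator of the CGI overlap
fraction.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `upstream_len` | 1000 | bp | canonical proximal-promoter window |
| `min_fraction` | 0.5 (strict `>`) | fraction of census CpGs sequenced | excludes promoters whose imputation would dominate the counts |
| `min_sequenced` | 4 (`>=`) | CpGs | a mean over fewer than four sites is too noisy to extrapolate from |
| `cgi_threshold` | 0.10 (strict `>`) | fraction of promoter bases | CGI calls; non-CGI requires exactly zero overlap |
| `k` | 10 | bins | equal-count bins; 20 is a supported robustness variant |
| `spans` | 1.8 / 2.0 | CpGs | fixed-span variant for the CMepG / CUn-MepG features |
| `mw_alpha` | 0.001 | p-value | significance bar for the sub-bin Mann-Whitney tests |

The coverage filter applies both thresholds to *sequenced* CpGs. Whether the
count threshold should instead apply to total census CpGs is genuinely
ambiguous; we filter on sequenced sites — the quantity the filter is
protecting — and expose both thresholds as arguments. Similarly, a site
observed on only one strand contributes that strand's level as-is (no
implicit zero for the missing strand): treating absence of reads as evidence
of absence would bias levels downward exactly where coverage is poorest.

Genes whose promoter overlaps a CGI by more than zero but at most 10% belong
to neither analysis group. This three-way partition is forced by the
arithmetic of the canonical group sizes (the CGI and non-CGI groups do not
sum to the filtered total) and is reported explicitly as `excluded` rather
than silently folded into either group.

## The statistics

Both tests are rank-based throughout, so all reported p-values are invariant
under monotone transforms of expression; expression is therefore consumed
raw (no log), and the choice of FPKM versus any rescaling is immaterial.

**Trend across bins.** Spearman's rho between per-bin feature medians and
per-bin expression medians, average ranks for ties. For up to 10 bins the
p-value is exact: all `n!` permutations are enumerated (10! = 3,628,800;
enumerated in chunks over the first rank position, with the 9! table cached).
Since rho is a monotone linear function of `S = Σ r_x · r_y(π)`, the
enumeration thresholds on `S` directly. Above 10 bins the t approximation is
used. Whether the canonical analysis was one- or two-sided is not stated
anywhere we could verify, so both p-values are always computed and reported;
the two-sided one is the default headline. Medians constant on either axis
make rho undefined, and the result says so rather than emitting a p-value.

**Sub-bin comparison.** Each bin is median-split by the complementary
feature: stable sort, lower `ceil(n/2)` ranks to the low half, so halves are
exactly equal for even bins and ties at the median are resolved by rank
order, never by value. The one-sided Mann-Whitney test (high half
stochastically greater) uses midranks; with both halves of size at most 8
the p-value is exact by enumerating every `choose(n, n1)` labeling,
otherwise the normal approximation with tie and continuity correction
(delegated to `stats::wilcox.test`). At the bin sizes of a genome-scale run
(hundreds of genes per half) the approximation is the operative branch; the
exact branch matters for small studies and is the one verified against
brute-force enumeration in the tests.

**Equal-count remainder policy.** When `N` is not divisible by `k`, the
common bin size is `floor(N/k)` and the remainder genes are appended one
each to the highest-feature bins. Only the common size is externally
canonical (e.g. 765 and 429 for group sizes 7656 and 4290); the placement of
the remainder is our choice and is documented and tested. Within-bin feature
ties are broken by gene id so binning is deterministic.

**Fixed-span variant.** Windows `[lo, lo + span)` from the minimum feature
value; empty windows are dropped and windows under 50 genes (configurable)
are flagged and excluded from statistics, because a median over a handful of
genes would swamp the trend test with noise.

## What the generator emulates — and what it does not

`simulate_methylome()` produces the full input surface (strand-level read
counts at known CpG positions with dropout, gene BED, CGI BED, CpG census,
expression table) plus a latent-truth sidecar. Defaults are fixed once, as
the study conditions: 12000 genes, 64% CGI (the ratio of the canonical ES
group sizes), negative-binomial CpG counts (mean 15 non-CGI / 60 CGI;
overdispersed so equal-count bins have distinct feature ranges), promoter
methylation concentrated near 0 for CGI promoters (Beta(0.6, 12)) and broad
for non-CGI ones (Beta(0.9, 0.9)), per-site Beta jitter (concentration 12),
Poisson coverage of mean 10 reads/strand with 15% per-strand dropout.

Expression follows `log E = a·min(u, u_sat) − b·m·1(u < u_sat) + ε` with
`a = 0.15`, `b = 0.05`, `u_sat = 20`, `σ = 1`. The hard `min` is the
simplest law expressing activator saturation, and gating repression below
saturation mirrors the observation that CMepG counts matter only at moderate
CUn-MepG levels. The slopes give a log-expression dynamic range of about 3
(roughly a 20-fold FPKM spread) against unit log-noise — a realistic
signal-to-noise for bulk expression — with repression deliberately a third
as strong as activation. No functional form for the combined model is
externally fixed; ours is one admissible instance and the package treats it
as such.

The generator does *not* attempt realistic chromosome structure (genes sit
in fixed 5 kb slots on four chromosomes), real CGI length distributions,
sequence composition, or coverage heterogeneity beyond uniform dropout.
Passing the recovery tests therefore shows that the pipeline's estimator and
statistics recover a known planted structure through realistic read-level
noise — not that real methylomes obey this law.

## Numerical and degenerate-input choices

- All internal coordinates are 0-based half-open; GTF (1-based) and GRanges
  are converted at the boundary only. A minus-strand bisulfite record at
  position `p + 1` is an observation of the CpG site keyed at `p`.
- Conservation is asserted at `1e-9`; result tables are written at full
  double precision (`%.17g`) so the identity survives the TSV round-trip.
- Zero-coverage rows in read tables are legal ("not sequenced here").
  Promoters with *no* sequenced census site have undefined counts (`NA`) and
  fail the filter, rather than an arbitrary imputation.
- Annotation tracks (CGI, UMR) are merged on read, so overlap fractions
  never double count and classification is invariant to fragmentation; the
  CpG census is deliberately *not* merged (back-to-back CpGs are distinct
  sites).
- UMR exclusion removes a non-CGI gene on any overlap (>= 1 bp): the
  exclusion is a robustness guard against unannotated islands, so the
  conservative trigger is the right one. It only ever shrinks the non-CGI
  group.
- Exactly 10% CGI overlap is `excluded` (strict `>`), and exactly half the
  census sequenced fails the filter (strict `>` on the fraction); both
  boundaries are pinned by unit tests.
- The exact/approximate switch points (group size 8 for Mann-Whitney, 10
  bins for Spearman) are recorded in every result object, never silent.

## Problem sizes used by the test suite

Unit and property tests run on promoters of 4–30 sites and gene tables of a
few hundred rows. The end-to-end checks run the full read-level pipeline at
the generator's default 12000 genes for five fixed seeds, the null
calibration (both slopes zero) on latent truth for twenty seeds, and the
enumeration oracles at 200 random Mann-Whitney inputs and ten Spearman
inputs of up to 7 bins — sizes chosen so the whole suite completes in a few
minutes on one core while still exercising every branch at study scale.

## Known limitations

- Expression is consumed as a per-gene table; no transcript-level handling,
  no FPKM computation, and no multiple-testing correction (the sub-bin grid
  uses the fixed 0.001 bar by design).
- CGIs and UMRs are inputs; the package does not call islands from sequence.
- CpH methylation, read-depth weighting beyond the per-site ratio, and
  smoothing across promoters are out of scope.
- The strand encoding of external read tables varies between studies; the
  `dialect` argument makes the convention explicit rather than guessing.
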