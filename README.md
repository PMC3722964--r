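# methbin

Promoter DNA methylation is the classic mark of gene repression, but *how* it
represses is less settled. Methylating a promoter CpG does two things at once:
it creates a methylated CpG (a CMepG, a docking site for methyl-CpG binding
repressors) and it destroys an unmethylated CpG (a CUn-MepG, the binding
substrate of CXXC-domain activators such as KDM2A and CFP1). `methbin`
implements the integrative methylome–transcriptome analysis that separates
these two bookkeeping quantities and asks which one actually tracks
expression — separately for CpG-island (CGI) and non-CGI promoters, where the
answer differs sharply.

It is aimed at computational epigenomics practitioners with per-CpG bisulfite
read counts, gene models, a CGI track, and an expression table in hand.

## The method

For every gene, the promoter is the 1000 bp upstream of the TSS. From
strand-level bisulfite counts, each CpG site's methylation level is
`meth / (meth + unmeth)` (two-strand average when both strands were
sequenced). With `ℓ_i` the level of site `i` and `n` the promoter's CpG
census size,

```
CMepG count     m = Σ ℓ_i        (unsequenced sites imputed at the
CUn-MepG count  u = Σ (1 − ℓ_i)   mean level of the sequenced ones)
```

so that `m + u = n` exactly. Promoters need strictly more than 50% of their
CpGs sequenced and at least 4 sequenced CpGs to enter the analysis. A gene is
a **CGI gene** when >10% of its promoter overlaps a CpG island and a
**non-CGI gene** when there is no overlap at all; genes in between belong to
neither group.

Within each group, genes are ranked by `m` (and, separately, by `u`) and cut
into ten equal-count bins. The trend of expression across bins is tested by
Spearman correlation of per-bin feature medians against per-bin expression
medians, with an *exact permutation* p-value (all 10! orderings enumerated).
Each bin is further median-split by the complementary count and the two
halves compared with a one-sided Mann–Whitney test (exact by labeling
enumeration for small groups; significance bar p < 0.001).

A seeded synthetic generator produces methylome + expression inputs with
known ground truth under a combined activator/repressor law,

```
log E = a · min(u, u_sat) − b · m · 1(u < u_sat) + ε,   ε ~ N(0, σ²)
```

i.e. CUn-MepG-binding activators saturate at `u_sat` and methyl-binding
repressors matter only below saturation — which is exactly the regime that
makes CGI trends flat and the non-CGI CUn-MepG trend strong.

## Worked example

Simulate a 2000-gene study and run the whole pipeline:

```r
library(methbin)
sim <- simulate_methylome(methylome_params(n_genes = 2000, seed = 42),
                          dir = "methbin_demo")
cfg <- pipeline_config(
  cpg_reads  = sim$paths[["cpg_reads"]],
  genes      = sim$paths[["genes"]],
  cgi        = sim$paths[["cgi"]],
  cpg_sites  = sim$paths[["cpg_sites"]],
  expression = sim$paths[["expression"]],
  outdir     = "methbin_demo/results")
res <- run_pipeline("all", cfg)
print(res$analysis)
```

```
Bin-based methylome-expression association
  genes: 1287 CGI, 687 nonCGI; k = 10 equal-count bins

Spearman trends on bin medians:
  class      feature n_bins     rho  p_two_sided  p_one_sided            method
    CGI unmeth_count     10  0.0424 9.183763e-01 4.591882e-01 exact-permutation
    CGI   meth_count     10 -0.0667 8.651444e-01 5.808868e-01 exact-permutation
 nonCGI unmeth_count     10  1.0000 5.511464e-07 2.755732e-07 exact-permutation
 nonCGI   meth_count     10 -0.9636 4.905203e-05 9.999895e-01 exact-permutation

non-CGI sub-bin Mann-Whitney tests: 12 of 30 significant at p < 0.001
```

Read it as the two-by-two contrast at the heart of the method: in non-CGI
promoters the number of unmethylated CpGs orders expression almost perfectly
(rho = 1, exact permutation p ≈ 5.5e-7 — the smallest two-sided p ten bins
admit), while in CGI promoters — where CUn-MepG counts sit far above the
activator saturation point — both trends are indistinguishable from noise.
The result bundle under `methbin_demo/results/` contains the per-gene bin
assignments, per-bin expression ECDFs, the sub-bin Mann–Whitney table, and a
`manifest.json` with input checksums and gene counts at every filter step.

Real data run the same way: point `cpg_reads` at your bisulfite count table,
`genes` at a BED/GTF, `cgi` at a CGI BED, `expression` at a two-column TSV,
and supply the CpG census either as a BED (`cpg_sites`) or a genome FASTA
(`fasta`, scanned for CG dinucleotides). A thin command-line wrapper lives at
`inst/scripts/methbin-pipeline.R`.

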