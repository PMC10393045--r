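# tipscan

Transposon insertion polymorphisms (TIPs) — presence/absence of
transposable-element insertions segregating among accessions — are an
underused class of genetic marker: they are often closer to the causal
regulatory lesion than linked SNPs, yet standard eQTL and selection
scans ignore them. `tipscan` implements, for structured and largely
inbred plant populations (the motivating system is domesticated rice
with two crop subpopulations and a wild relative), the full inference
chain from a raw TIP zygosity matrix to:

1. a filtered, binarized, imputed TIP genotype matrix with
   per-population frequencies and specificity labels;
2. per-replicate **cis eQTL scans** with TIPs and SNPs as markers —
   OLS of normalized expression on genotype with subpopulation
   covariates, a strict < 5 kb cis window, Benjamini–Hochberg FDR per
   scan, replicate consolidation, TIP-vs-SNP variance comparison, and
   relaxed-cutoff sharing across conditions and populations;
3. a per-locus **Population Branch Statistic** scan over three
   populations, `PBS_i = (T_ij + T_iw − T_jw)/2` with
   `T = −ln(1 − F_ST)` (Hudson estimator), percentile flags, Fisher
   exact eQTL-enrichment and Wilcoxon group tests;
4. **sweep scans** around focal TIPs: nucleotide diversity π (25-SNP
   windows, step 5) and H12 haplotype homozygosity (50-SNP windows,
   step 25) over ±50 kb, computed separately for TIP carriers and
   non-carriers against a 1000-draw permutation null;
5. a **benchmark** module scoring predicted TIP calls against an
   annotated truth set (sensitivity = TP/(TP+FN),
   precision = TP/(TP+FP), per TE family);
6. a **synthetic-cohort generator** (Balding–Nichols frequency
   differentiation, planted cis effects, planted frequency shifts and
   sweeps, negative-binomial counts over 2 conditions × 3 replicates)
   that makes every stage testable without external data.

The methods vignette (`vignettes/tipscan-methods.Rmd`) documents the
models, defaults and design decisions in detail.

## Worked example

Simulate a small cohort and run the whole pipeline at a fixed seed:

```r
library(tipscan)
cfg <- pipeline_config(
  simulate = list(n_pop1 = 60, n_pop2 = 40, n_pop3 = 40, n_tips = 400,
                  n_snps = 1200, n_genes = 60, n_eqtl_tips = 12,
                  n_selected_tips = 8, n_sweep_loci = 2,
                  sweep_region_snps = 150),
  sweep = list(n_perm = 200)
)
res <- run_pipeline(cfg, out_dir = "demo_run", seed = 1)
#> simulate: 420 TIP loci, 1524 SNPs, 60 genes, 140 accessions
#> filter-tips: 377 of 420 loci past zygosity filter
#> map-eqtl: 1320 TIP and 8478 SNP tested pairs; 41 / 36 hit pairs
#> pbs: 213 loci scanned; 15 flagged eQTL
#> sweep-scan: 2 loci scanned
```

420 simulated loci (400 TIPs + 5% low-zygosity decoys) shrink to 377
after the zygosity floor; 1,320 TIP–gene and 8,478 SNP–gene cis pairs
are tested per population/condition/replicate, yielding 41 TIP and 36
SNP hit pairs at 5% FDR. The leading associations carry the effect size
(`beta`, log2-normalized expression per insertion allele), the marginal
variance explained after covariates (`r2`), and the signed distance to
the gene:

```r
res$tip_hits$leading[1:3, c("gene_id", "marker_id", "min_q", "beta", "r2", "distance")]
#>    gene_id marker_id        min_q       beta        r2 distance
#> 1 gene0005 TIP_00030 2.321756e-09 -1.8139143 0.5428756    -1230
#> 2 gene0005 TIP_00030 3.136446e-08 -1.6434289 0.4867008    -1230
#> 3 gene0009 TIP_00041 3.561377e-03  0.8116052 0.3254437     -875
```

TIPs with extreme PBS (top 5% of max-absolute PBS) are strongly
enriched for eQTL TIPs in this cohort, because half of the planted
frequency shifts were placed on expression-associated insertions:

```r
round(res$enrichment$odds_ratio, 2); signif(res$enrichment$p, 3)
#> [1] 30.31
#> [1] 0.0134
```

At a planted sweep locus the carrier group shows depressed π and a
low permutation p at the focal window, while non-carriers do not:

```r
focal_window(res$sweeps[[1]])[, c("group", "stat", "value", "perm_mean", "perm_p")]
#>           group stat     value perm_mean     perm_p
#> 67     carriers  h12 0.4809750 0.4501665 0.10447761
#> 137 noncarriers  h12 1.0000000 1.0000000 1.00000000
#> 38     carriers   pi 0.1843194 0.1909159 0.04477612
#> 108 noncarriers   pi 0.4000000 0.1910000 0.99502488
```

Every result table in `demo_run/` starts with a provenance line
(package version, configuration hash, seed); rerunning with the same
configuration and seed reproduces the files byte for byte.

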