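---
title: "Methods: TIP-eQTL mapping and selection scans in tipscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TIP-eQTL mapping and selection scans in tipscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`tipscan` implements an inference chain that links transposon insertion
polymorphisms (TIPs) in structured, largely inbred plant populations to
gene-expression variation and to signatures of selection. The chain has
four analytical stages — TIP matrix construction, cis eQTL mapping with
TIPs and SNPs as markers, a per-locus Population Branch Statistic (PBS)
scan across three populations, and locus-level sweep scans (windowed
nucleotide diversity and H12 haplotype homozygosity, TIP carriers versus
non-carriers, against a permutation null) — plus a synthetic-cohort
generator that provides ground truth for all of them, and a small
benchmark module that scores TIP calls against an annotated truth set.

This vignette is the package's account of the statistical models, the
parameters that matter, and the design choices made where the design was
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

# TIP matrix construction

The raw input is a *zygosity* matrix: per locus and accession, the
fraction of read evidence supporting the insertion, in [0, 1], with `NA`
for missing evidence (absence evidence and no evidence are distinct; the
missing sentinel is never conflated with zero).

Filtering proceeds in the published order with centralized boundary
semantics (`pipeline_defaults()`):

1. **Zygosity floor** — a locus whose zygosity never reaches 0.25 in any
   sample (non-missing samples only) is removed as a likely false
   positive. The comparison is inclusive (`>= 0.25` keeps).
2. **Binarization** — zygosity `>= 0.05` is called present, below is
   absent; inbred material is treated as haploid-equivalent, so calls are
   per accession. Missing stays missing.
3. **MAF/missingness presets** — the eQTL path keeps loci with MAF
   strictly greater than 3% and *no* missing data; the PBS path keeps
   loci with at most 5% missing data and MAF of at least 5%. The eQTL
   bound is strict ("higher than 3%") while the PBS bound is inclusive
   (the protocol removes "MAF < 5%"); both rules live in one comparison
   helper so the asymmetry is visible in a single place.
4. **Imputation** — residual missing calls after the PBS filter are
   imputed from the locus presence frequency. The published protocol
   names an algorithm whose exact definition is not public, so two modes
   are offered: `"expected"` (deterministic majority rounding, the
   default, chosen for reproducibility) and `"bernoulli"` (a seeded draw
   at the locus frequency). Observed calls are never altered.

Per-population presence frequencies, population-specificity labels
(`shared` / specific / `rare_both`, with a strict flag for loci entirely
absent from one population), and the two-population frequency histogram
used to contrast eQTL against non-eQTL loci all derive from the filtered
matrix.

# cis eQTL mapping

Expression arrives as raw 3'-mRNA-seq-like counts over accessions x
conditions x replicates. Each replicate matrix is analysed separately:

* **Expression filter** — keep genes with a nonzero count in strictly
  more than 10% of the replicate's samples.
* **Normalization** — median-of-ratios size factors (geometric-mean
  reference over genes with all-positive counts) followed by
  `log2(count / size_factor + 1)`. This is a deliberate, documented
  stand-in for a spline-based variance-stabilizing transform: it removes
  depth differences and compresses the variance-mean relationship, and
  the association model is invariant to any monotone
  variance-stabilizing choice under the null. If no gene has
  all-positive counts the size factors fall back to relative library
  size, with a warning. With very few genes the median-of-ratios factors
  absorb real signal, so scans should always run on full gene panels.
* **cis pairs** — a marker is cis to a gene iff it lies in the gene body
  or strictly less than 5,000 bp from the nearer gene edge (the
  published phrase is "less than 5 kb", hence strict bounds on both
  sides). Distances are signed negative on the strand-aware 5' side.
* **Association model** — OLS of normalized expression on an intercept,
  subpopulation dummies (treatment coding, largest group as reference)
  and the marker genotype. The implementation residualizes expression
  and genotypes against the covariates once per scan and computes the
  marker t-test via the partial correlation (Frisch–Waugh), which is
  algebraically identical to the full OLS fit and is cross-checked
  against both `lm()` and brute-force normal equations in the tests.
  The reported `r2` is the squared partial correlation — the marginal
  variance explained by the marker after covariates.
* **Multiple testing** — Benjamini-Hochberg within one replicate x
  condition x population x marker-type scan, over all tested *pairs*
  (the convention of the matrix-based eQTL tools this stage mirrors; the
  protocol itself does not specify the adjustment universe).
* **Consolidation** — a (gene, marker, condition, population) is a hit
  iff adjusted p < 0.05 in at least one replicate. The leading marker
  per gene minimizes min-q, with ties broken by smaller |distance| and
  then leftmost genomic position (an invented, deterministic rule).
  "Condition-specific" means significant in one condition and not shared
  in the other at the relaxed cutoff (unadjusted p < 0.05, same sign).

MAF filtering for the eQTL path is recomputed per population, since the
two crop populations are scanned separately.

# PBS scan

For each TIP present in all three populations after the PBS preset, the
three pairwise FSTs are transformed into branch lengths
`T = -ln(1 - FST)` and combined into the two focal-branch statistics

```
pbs_i = (t_ij + t_iw - t_jw) / 2,    pbs_j = (t_ij + t_jw - t_iw) / 2,
```

which satisfy `pbs_i + pbs_j = t_ij` identically; the wild-proxy branch
is recoverable by symmetry. Because the published analysis reports a
single "absolute PBS" per TIP without naming the branch, the scan emits
both branches and ranks loci by `abs_pbs = max(|pbs_i|, |pbs_j|)`, so
either convention is recoverable from the output.

The FST estimator is not named in the protocol. `tipscan` uses Hudson's
estimator written in heterozygosity form, `1 - Hw/Hb`, with the unbiased
`n/(n-1)` within-population correction and the between-population
heterozygosity `Hb = p1(1-p2) + p2(1-p1)`; it is the standard choice for
PBS because it is robust to unequal sample sizes, and it equals the mean
pairwise-difference computation enumerated directly from genotype tables
(the test oracle). A haploid Weir-Cockerham estimator is available via
`estimator = "wc"`. Estimates are clamped to `[0, 1 - 1e-9]` before the
log transform: the branch length of a negative FST estimate is zero, and
FST = 1 would give an infinite branch.

Percentile flags (`top5`, `top1`) mark the `ceiling(0.05 m)` /
`ceiling(0.01 m)` largest `abs_pbs` values (ties included; the ceiling
is guarded against binary floating-point noise, since `0.05 * m` can
exceed the integer it should equal by one ulp). Enrichment of eQTL TIPs
among extreme loci uses the sample odds ratio `ad/bc` (Haldane 0.5
correction when a cell is zero; the conditional-MLE odds ratio that
`fisher.test` prints is deliberately *not* reported) with the two-sided
Fisher exact p-value, and group comparisons use the two-sided
Mann-Whitney U with normal approximation, tie and continuity
corrections.

Note one property of neutral loci under symmetric drift: each focal
branch has *positive* expected PBS equal to its true branch length
(about `-ln(1 - F)/2`). "No branch bias" therefore means the two derived
branches have equal means, not that either mean is zero; the test suite
asserts exactly that.

# Sweep scans

Around a focal TIP, a ±50 kb haplotype block is extracted (0-based
half-open; complete calls required — impute first) and the accessions of
the population under study are split into carriers and non-carriers.

* **π** — in windows of 25 SNPs sliding by 5, the mean per-site pairwise
  diversity `sum(2 p (1-p) n/(n-1)) / 25`, identical to the average
  pairwise Hamming distance between distinct haplotypes divided by the
  SNP count. Windows are defined over SNP indices, exactly as in the
  protocol; the genomic span of every window is reported so per-bp
  rescaling is possible. The trailing partial window is dropped.
* **H12** — in windows of 50 SNPs sliding by 25, haplotypes are the
  allele strings over the window; with sorted haplotype frequencies,
  `H12 = (p1 + p2)^2 + sum_{i>=3} p_i^2`. Pooling the top two haplotypes
  keeps the statistic sensitive to soft as well as hard sweeps.
* **Permutation null** — 1000 draws of `group_size` accessions, sampled
  uniformly from *all* accessions of the population regardless of TIP
  state (as the protocol states), recomputing the statistic over the
  same windows. `perm_p = (1 + #{perm >= obs}) / (N + 1)` for H12 and
  with `<=` for π — one-sided toward the sweep signature (low π, high
  H12), matching the directional published claim; a two-sided variant is
  available by flag. The add-one estimator bounds p below by
  `1/(N + 1)`. Haplotype identities per window are precomputed once, so
  each permutation only re-tabulates integer ids.

`scan_locus()` requires at least two carriers and two non-carriers and at
least one full window of SNPs, and errors with the named deficiency
otherwise. `focal_window()` summarizes a scan at the window covering the
insertion.

# The synthetic-cohort generator

The generator emulates the study design the pipeline assumes: two
derived crop populations and one wild proxy (default sample sizes
126 / 82 / 82, the published design), Balding-Nichols allele-frequency
differentiation, planted cis expression effects, planted frequency
shifts ("selection") in exactly one derived population, and planted
sweeps around a subset of the shifted loci.

* **Frequencies** — ancestral `p0 ~ Beta(0.5, 0.5)` truncated to
  [0.02, 0.98]; each population draws
  `Beta(p0 (1-F)/F, (1-p0)(1-F)/F)` with `F = fst_drift`. All three
  populations drift independently — the wild proxy is a present-day
  sample that has also diverged since the split — so every pairwise
  Hudson FST is ≈ F (verified by Monte Carlo in the tests) and the
  neutral PBS tree is symmetric. Selected TIPs replace their focal-pop
  draw with a target in [0.8, 0.99] or [0.01, 0.2], the direction chosen
  away from `p0`.
* **Genotypes** — independent Bernoulli draws per locus and accession
  (binary presence/absence; inbred rice motivates the haploid-equivalent
  coding, and no heterozygotes are simulated).
* **Zygosity** — present calls get zygosity ~ U(0.3, 1), absent calls
  are 0 with a 2% chance of faint noise below the 0.05 presence cutoff;
  5% extra decoy loci never reach the 0.25 floor and must be removed by
  the zygosity filter. Missing cells (2% overall by default) are
  concentrated in a fixed 30% subset of loci: uniform per-cell
  missingness at 2% would leave almost no locus with complete data
  across 208 accessions (`0.98^208 ≈ 1.5%`), which would empty the
  complete-data eQTL path entirely; concentration keeps both that path
  and the ≤5%-missing imputation path populated, as in the real data
  where missingness clusters in hard-to-genotype loci.
* **Expression** — per gene and accession,
  `mu = exp(b0 + b_subpop + beta g)` (condition-specific effects act
  under drought only) with negative-binomial counts of dispersion 0.2
  (log-scale residual sd ≈ 0.45, typical of 3'-tag counts), two
  conditions and three replicates. Baselines `b0 ~ N(log 300, 1)`;
  subpopulation offsets `N(0, 0.2)` exercise the covariate path.
* **LD structure** — each planted eQTL TIP gets two tag SNPs inside the
  gene's cis window, constructed by symmetric flips so that `r ≈ 1-2e`
  (target r² ~ U(0.2, 0.7)). Without them the TIP-versus-SNP variance
  comparison would face no linked SNPs at all. Background SNPs are
  otherwise independent of TIPs.
* **Sweeps** — for each sweep locus the alleles of *every* SNP within
  ±50 kb collapse, for carriers only, onto `sweep_carrier_haplotypes`
  template haplotypes (1 = hard, >1 = soft) with 1% per-site divergence;
  the swept haplotype is the one carrying the insertion. Dense extra
  SNPs (250 by default) are simulated in each region so the windowed
  statistics always have material.

Locus counts (1,500 TIPs, 3,000 SNPs, 200 genes by default) are
desk-scale choices: large enough for stable percentile flags and
frequency spectra, small enough that the full pipeline runs in well
under a minute. What the generator does **not** emulate: genome-wide
linkage and recombination maps, demography and coalescent gene
genealogies, read-level artefacts, and population substructure within
the wild proxy (the real wild group pools two species; it is treated as
panmictic here). Passing tests therefore demonstrate correctness of the
statistical machinery under the stated generative model, not robustness
to every property of real resequencing data.

# Numerical and interface choices

* All published thresholds are named constants in
  `pipeline_defaults()`.
* Coordinates are 0-based half-open internally (BED native); VCF and
  GFF3 are converted at the boundary by a single helper pair.
* The VCF writer emits minimal plain-text VCFv4.2 (haploid GT) so that
  pipeline outputs are byte-stable; the reader accepts haploid and
  homozygous-diploid GT, rejects heterozygous calls unless a policy
  (`drop-site` / `drop-call`) is given, and skips multiallelic records
  with a warning.
* `run_pipeline()` derives all stage seeds from one master seed and
  writes a provenance line (package version, config hash, seed — no
  timestamps) at the top of every result table; two runs with the same
  configuration and seed are byte-identical.
* The pipeline's demo configuration used in the test suite scales the
  cohort to 60/40/40 accessions, 400 TIPs, 1,200 SNPs, 60 genes and 200
  permutations; the acceptance script runs the full default design.

# Known limitations

* trans effects, kinship/mixed-model corrections and genotype
  likelihoods are out of scope; markers are binary and complete after
  imputation.
* The normalization is a monotone stand-in, not a spline-fit variance
  stabilization; variance-explained comparisons across genes inherit
  its variance-mean profile.
* The permutation null resamples accessions without replacement from
  the whole population; with very unbalanced carrier splits its
  discreteness makes small p-values coarse (`1/(N+1)` floor).
* Greedy nearest-first matching in the benchmark is not an optimal
  bipartite matching; at the default ±100 bp tolerance the difference
  is immaterial.
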