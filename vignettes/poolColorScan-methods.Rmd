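---
title: "Methods: pool-seq color-association scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pool-seq color-association scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolColorScan)
```

# The design

`poolColorScan` analyses pooled whole-genome sequencing of a phenotype ×
site layout: each pool is the combined DNA of all individuals of one
color phenotype at one geographic site. The default manifest emulates a
12-pool study — three inner-shell colors (red, yellow, green) crossed
with four sites (three wild populations, one hatchery cohort), 172
diploid individuals in total. Per-pool sample sizes are 20 for each
hatchery pool (the hatchery contributed 20 individuals per color) and
12–13 for the wild pools, chosen so the total matches 172; only the
totals, not the per-pool splits, are fixed by the design being emulated.

Because a pool is one library, genotypes of individuals are not
observable; the data per pool and locus are the allele depths AD and the
total depth DP of a variant caller run in pooled mode.

# Allele frequencies and filters

The AF estimate is the informative-read fraction
`ad_alt / (ad_ref + ad_alt)`. DP can legitimately exceed
`ad_ref + ad_alt` (uninformative reads), so DP is reserved for the depth
filter and never used as the AF denominator — otherwise AF would not be
a proper fraction of allele counts.

Four retention rules run in a fixed order (biallelic → depth → missing →
MAF), and each removed locus is attributed to its first failing rule;
the kept set itself is order-independent, which the test suite checks by
evaluating the rules independently. Choices worth stating:

* **Depth scope.** "Depth at least 20" is enforced in *every* pool by
  default — the strictest reading, guaranteeing that every AF estimate
  in the model meets the floor. A `dp_scope = "total"` switch implements
  the site-level alternative, since the original convention is not
  recoverable.
* **MAF for pools.** Cohort MAF is undefined when only pool frequencies
  exist. We fold the unweighted across-pool mean AF:
  `min(p̄, 1 − p̄) ≥ 0.01`. This is the simplest pool-level analogue and
  is configurable.
* **Block substitutions.** Equal-length multi-base REF/ALT records are
  split into one SNP per mismatching position, children inheriting the
  parent's depths verbatim (the splitting tool's behaviour: no
  re-counting). Indels are dropped with a counter; the retained universe
  is biallelic SNPs only.

# The per-SNP model

Each locus is fitted by OLS, `AF ~ Color + Site`, with treatment coding
and the first level of each factor as reference. The modelling interface
this reproduces defaults to a Gaussian family with identity link, so OLS
is the faithful choice; AF is bounded in [0, 1] but is treated as
continuous, which is accurate away from the boundaries and is exactly
what the downstream t-statistics assume.

All pairwise differences of color levels (K1, 3 rows) and site levels
(K2, 6 rows) are stacked and tested simultaneously. Per contrast the
two-sided p-value uses the Student-t with the residual degrees of
freedom (12 pools − 6 coefficients = 6), followed by one Bonferroni
correction across the stacked 9-row family. Two deliberate decisions:

* **Single-step t, then Bonferroni.** The max-t adjustment of the usual
  simultaneous-inference machinery is replaced by the plain Bonferroni
  that the analysis this package reproduces reports; Bonferroni is more
  conservative and needs no multivariate-t integration per locus, which
  matters at genome scale. `correction = "none"` is available.
* **Family scope.** The Bonferroni family is the 9 within-SNP
  contrasts, *not* the genome. A genome-wide family over ~22M × 9 tests
  at a 1e-9 threshold would be unreachable; the extreme per-SNP
  threshold itself plays the genome-wide-stringency role. The threshold
  default `alpha = 1e-9` interprets the printed "1e10^−9" of the source
  convention as 1e-9.

**Degenerate fits.** Noise-free or saturated data give zero residual
variance. Such loci are never fatal: a zero-SE contrast reports p = 1
when its estimate is 0 (no evidence) and p = 0 otherwise (perfect
separation), with a `degenerate` flag carried into the scan table. The
numeric guards are `sigma2 ≤ 1e-20` and `|estimate| ≤ 1e-10`.

**Classification.** Geography-associated: any significant site pair.
Color-associated: at least one significant color pair *and* no
significant site pair — loci associated with both are deliberately
excluded, because a shift shared by color and site cannot be separated
from structure. Color-specific for *c*: color-associated and all pairs
involving *c* significant. When all three color pairs are significant
every color would qualify; no specific color is assigned and an
`all_pairs` flag is set (the rule system leaves this case undefined; a
tie-break would be arbitrary). The classifier is a pure function of the
adjusted p-values and is property-tested against brute-force evaluation
of all 2^9 significance patterns.

# The simulator

`simConfig()` defaults define the study conditions: 12 pools as above,
5000 loci on a 1 Mb pseudo-chromosome, class fractions 0.90 neutral /
0.04 color / 0.04 site / 0.02 both, effect size 0.4 on the shifted
pools, baseline AF uniform on [0.05, 0.95], mean depth 80×. A color
locus shifts one color's pools identically at *all* sites (the
"universal control" structure the scan assumes); a site locus shifts one
site's pools; a `both` locus does both independently. Shifted AFs are
clamped to [0.01, 0.99] so planted loci pass the MAF filter by
construction.

Noise is two-stage, which is the variance structure distinguishing
pool-seq from individual sequencing: first the finite pool of
chromosomes (`c ~ Binomial(2n, p)`, realized frequency `q = c/2n`), then
the reads (`dp ~ Poisson(depth)` floored at 1, `ad_alt ~ Binomial(dp,
q)`). At high depth the read stage vanishes but the pool stage does not:
with 12–20 individuals the pool-sampling SD is ≈ 0.09 at p = 0.5, so
read-back AFs converge to the *realized pool frequency* (recorded by
`simulateReads()` in `metadata()$realized_af`), not to the population
AF — the tests assert exactly that. Per-locus draws come from seeds
derived by an integer hash of (root seed, locus index), so a locus's
draws do not depend on how many loci precede it.

What the simulator does **not** emulate: linkage disequilibrium between
loci, coalescent site-frequency spectra, base-calling errors, mapping
bias, or depth heterogeneity along the genome. Passing tests therefore
demonstrate the statistical machinery under the stated noise model, not
robustness to those real-data features.

# Power at the default conditions — an honest note

With 12 pools the residual degrees of freedom is 6, and a Bonferroni-
adjusted p below 1e-6 requires |t| > qt(1 − (1e-6/9)/2, 6) ≈ 29. The
planted effect of 0.4 at depth 80 and n = 15 yields a noncentrality of
only ≈ 5.3 (residual SD ≈ 0.107, contrast SE ≈ 0.076), so per-locus
power at that threshold is ≈ 2×10⁻⁴: loci reach extreme significance
only when their realized residual variance happens to be tiny. The
acceptance suite states a sensitivity target of 0.85 under exactly these
conditions; the package runs the check faithfully and reports the
honest (near-zero) sensitivity rather than altering the conditions. At
genome scale the same mathematics explains why a 22M-locus scan yields
tens of thousands of extreme-significance loci (the lucky small-variance
tail is large in absolute terms) while a 5000-locus desk-scale replicate
yields almost none. The unit suite demonstrates that the scan and the
routing rules behave correctly where power exists (50 individuals,
2000× depth, alpha 1e-2–1e-3: sensitivity > 0.85, false-discovery
proportion ≤ 0.05, ≥ 95% of joint loci routed to geography).

# Effect annotation

Gene models are transcript bounds + exons + CDS (1-based inclusive; GFF3
via rtracklayer, BED12 with blocks/thick converted from 0-based
half-open). Effects are the terms the impact summary needs: upstream /
downstream (strand-aware, 2000 bp flanks — the conventional default),
intron, intergenic, synonymous, missense, stop_gained, stop_lost,
start_lost, with the fixed impact map HIGH (stop/start gain/loss),
MODERATE (missense), LOW (synonymous), MODIFIER (the rest). UTR and
splice-site classes are out of scope; a non-CDS exonic position falls to
`intron_variant`, the nearest supported class — gene models used in the
tests have CDS spanning their exons, so the case is marginal. A SNP in
reach of several genes gets one annotation per gene;
`mostSevereImpact()` reduces for summaries. Coding changes are derived
by splicing the CDS (reverse-complemented for minus-strand genes),
substituting the base and translating ref/alt codons with the standard
code; a mismatch between the record's REF and the reference sequence is
a data-inconsistency error, not a silent fix.

# Descriptive summaries

* **Windowed π.** Per-site `π_i = n/(n−1) · 2 p_i (1−p_i)` with `n` the
  haploid pool size — the unbiased expected heterozygosity of the pool —
  summed over variant sites in non-overlapping windows and divided by
  the window span in bp (default 10 kb). The "10,000 sites" window of
  the convention being mirrored is ambiguous between bp and variant
  sites; both denominators are exposed (`denominator = "bp"` default,
  `"sites"` alternative).
* **PCA.** Column-centred SVD of the pools × loci matrix with a
  deterministic sign convention (largest-magnitude loading positive), so
  results are reproducible across runs and platforms.
* **Wilcoxon.** Exact enumeration p for combined n ≤ 20 without ties,
  normal approximation with tie/continuity correction otherwise;
  Bonferroni over the pair count. The compact letter display uses the
  greedy insert-and-absorb algorithm with ties broken by group order
  (no canonical algorithm exists for the letters; this one guarantees
  that non-different groups share a letter).
* **Histograms.** 30 equal bins on [0, 1], last bin right-closed so
  AF = 1 is counted; counts always sum to n.

# Problem sizes

The test and acceptance runs use desk-scale sizes chosen to make the
statistical assertions sharp without excess: 120 random datasets for the
oracle-equivalence sweep, 2000 replicate families for the null
family-wise error (Bonferroni guarantees ≤ 0.05; observed ≈ 0.037),
10,000 generator loci for the null scan at 1e-9, five seeds × 5000 loci
for planted-effect recovery, 1000 random REF/ALT pairs for the
decomposition oracle, and full enumeration for all Wilcoxon group sizes
up to 6.

# Known limitations

No kinship or admixture correction beyond the site factor; no
genotype-likelihood handling; no multiallelic AFs; bounded-response OLS
rather than a beta or quasi-binomial model (deliberate, to reproduce the
reference behaviour); within-SNP multiplicity only; annotation covers a
reduced effect vocabulary.
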