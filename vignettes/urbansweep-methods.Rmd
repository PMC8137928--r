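---
title: "Methods: haplotype scans and genotype-environment association for paired urban-rural populations"
author: "urbansweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype scans and genotype-environment association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and data model

`urbansweep` analyses phased biallelic SNP genotypes from paired
urban-rural populations of the same species sampled at several localities.
The central container is the S4 class `HaplotypePanel`: a sites x
(2 x samples) matrix of allele codes with per-site chromosome, 1-based
position and REF/ALT alleles, plus a per-chromosome class flag
(`autosome` or `Z`). Two conventions hold everywhere:

* allele code 1 is always the ALT allele; minor/major status is computed
  per population at the point of use and never stored;
* SNP positions are 1-based; every interval (gene, window, region) is a
  `GRanges` internally and 0-based half-open in BED-style input/output.
  A SNP at 1-based position p belongs to the half-open window
  [start, end) iff p - 1 lies in it.

Missing genotypes are rejected at load time, never imputed: silently
imputed calls would contaminate haplotype-homozygosity statistics in a
way that is invisible downstream, so the loader fails fast instead.
Chromosome class is supplied by a sidecar table, not guessed from names.

# The urbanisation score

Land cover around each capture site (one 1 x 1 km square digitised as 100
cells of 100 x 100 m, with per-cell proportions of buildings, vegetation
and paved surface) is reduced to one score per site: per-site means of
the three cover variables enter a correlation-matrix PCA and the first
principal component is the urbanisation score. Correlation (rather than
covariance) PCA makes the score invariant to rescaling any one variable
and stabilises the orientation rule; the axis sign is fixed so the
building-proportion loading is positive, giving rural sites negative and
urban sites positive scores. When one population was sampled at several
locations, the population score is the arithmetic mean of its member
sites. Scorer repeatability is summarised by the two-way mixed-effects,
absolute-agreement, single-measure intraclass correlation ICC(A,1),
computed from ANOVA mean squares; this variant is the natural choice for
a single rater scoring all sites in replicate.

# Population structure

Expected heterozygosity is the per-SNP mean of `2p(1-p)` over all sites.
Pairwise differentiation is the Weir & Cockerham (1984) theta-hat from
the a/b/c variance components of genotype counts, computed per SNP for
two populations with the observed-heterozygosity correction; the pair
mean clamps negative per-SNP values to zero before averaging. Its
permutation test permutes individuals between the two populations and
recomputes the clamped mean on a thinned SNP set (the first SNP of every
50 kb bin, anchored at position 1 of each chromosome — the anchor had to
be fixed somewhere and position 1 is reproducible); p-values use the
add-one estimator (b + 1)/(n + 1) so permutation p-values are never 0.

LD pruning follows the variance-inflation-factor scheme: within sliding
windows of 50 SNPs advancing by 5, the SNP with the highest VIF (the
diagonal of the inverse dosage-correlation matrix, ridge 1e-8) is removed
until all VIFs fall below 2. VIFs are capped at 1e6 so that perfectly
collinear SNPs tie, and ties resolve to the lowest SNP index — without
this, the victim among exact duplicates would be chosen by sub-ULP
floating-point noise and the pruned set would not be reproducible across
BLAS builds. Genotype PCA uses dosages centred per SNP and scaled by
sqrt(p(1-p)); axis signs are fixed by making each axis's
largest-magnitude loading positive.

Isolation by distance uses Mantel correlations of raw (non-linearised)
pairwise FST against great-circle distance (haversine, R = 6371 km),
separately within the urban and the rural population sets. The Mantel
permutation jointly permutes rows and columns of one matrix; the test is
two-sided by default with a one-sided option used for IBD.

# Genotype-environment association

Two complementary association analyses share the urbanisation score as
the environmental variable.

The latent-factor analysis regresses each SNP's centred dosage on the
environment plus K latent factors — the top-K left singular vectors of
the dosage matrix after projecting out the environment. This is a
deterministic counterpart of MCMC latent-factor mixed models: the
inferential target (per-SNP environmental effect corrected for unobserved
structure) is the same, but the estimate is reproducible without chains,
so no median-over-runs step is needed. Residual confounding is absorbed
by genomic control (dividing z-squared by lambda = median(z^2)/0.4549)
and p-values come from the chi-square(1) distribution with
Benjamini-Hochberg FDR; SNPs with q < 0.01 are flagged. Monomorphic SNPs
are untestable and reported as NA. K defaults to the elbow of the PCA
variance-explained curve and is always configurable.

The covariance-aware analysis works at the population level: the vector
of population ALT frequencies is regressed on the population environment
by generalised least squares whose error covariance Omega-hat is the
covariance of standardised population frequencies over an LD-pruned SNP
set; this absorbs shared drift and migration structure. Evidence is the
closed-form Zellner g-prior Bayes factor (unit information, g = number of
populations), reported in deciban; dB > 20 ("decisive") flags a SNP.
Frequency vectors with no variation across populations carry no
information and are never flagged. A near-singular Omega-hat is
regularised by flooring eigenvalues at 1e-6 of the trace.

"Core" SNPs are the intersection of the two flag sets; enrichment over
independence is tested with the hypergeometric upper tail plus an
optional without-replacement resampling check. A habitat-randomisation
threshold (environment values permuted across populations, pooled
null |z|, 95th percentile) is available as a complementary
significance rule.

# Haplotype-based selection scans

All scan statistics derive from one representation: for every haplotype
pair and every core SNP, the maximal interval containing the core over
which the pair is identical (its "mismatch tract"). From these tracts:

* **EHH** (allele-conditioned) and **EHHS** (site-specific, all
  haplotypes, Tang-normalised so the curve is 1 at the core) are decay
  curves over physical distance, monotone non-increasing by construction.
* **iES** is the trapezoidal integral of EHHS over both directions,
  truncated where the curve falls below 0.05, at inter-SNP gaps wider
  than 200 kb, or at the chromosome end (cutoff and gap follow the rehh
  defaults; the curve-below-cutoff rule is the only truncation that
  discards signal).
* **Rsb** is ln(iES_urban/iES_rural), median-centred and SD-scaled
  separately for autosomes and the Z chromosome; SNPs at Rsb >= 4 are
  outliers. Positive values mean homozygosity extends further in the
  urban population (older/completed sweeps).
* **nSL-type lengths** are mean pairwise tract lengths in SNP units
  (pairs differing at the core contribute 0); **XP-nSL** is
  ln(SL_urban/SL_rural), mean-centred and SD-scaled per chromosome
  class, outliers at > 2 (ongoing/recent sweeps).

SNPs whose pooled-sample minor-allele frequency is below 0.05 are
excluded as scan cores. The pooled-sample (not per-population) MAF is the
right guard here: after a completed sweep the swept site is fixed for
different alleles in the two populations — per-population MAF 0 on both
sides — yet it is exactly the site the scan exists to find; its pooled
MAF is 0.5 and it stays in.

Degenerate standardisation (identical panels, zero SD) yields scores of
0 rather than NaN. Swapping the two panels negates the unstandardised
log-ratios exactly; all statistics ignore haplotype column order and
REF/ALT relabelling away from the core.

# Windows, outliers, regions and recombination proxies

Windows are 200 kb sliding with 50 kb steps (non-sliding for the LD and
GC proxies). Per window the scan records the SNP count, mean statistic
and the proportion of SNP-level outliers; windows with fewer than 10
SNPs are ineligible and never enter percentile computations (a 1-SNP
window would otherwise dominate the outlier-proportion percentile).
A window is a dual-criterion outlier iff both its mean statistic and its
outlier-SNP proportion reach the 95th percentile of the genome-wide
distribution, computed within chromosome class (type-7 percentiles, ties
broken by >=). The window-level ZFST variant standardises window-mean
FST within chromosome class using the population SD (denominator n) and
flags z > 4. Flagged windows merge into regions when separated by at
most 200 kb; merging is idempotent.

Windowed LD (mean pairwise dosage r-squared for SNPs up to 200 kb apart)
and mean intronic GC content (introns inferred from exon gaps per
transcript, unioned per gene; each intron assigned to the window holding
its midpoint) proxy local recombination; Pearson correlations relate them
to the window-level selection statistics.

# The paired-deme simulator

The built-in forward Wright-Fisher simulator is the package's synthetic
stand-in for the real study design: nine localities, each an urban-rural
pair, 10-16 diploids sampled per population, several autosomes plus one
Z chromosome (carried by all individuals as an ordinary chromosome — the
pipeline uses Z only as a separate standardisation class, so avian
sex-linked inheritance is deliberately out of scope). Discrete
generations; two parents per offspring drawn with probability
proportional to fitness; gametes formed by Poisson(rho x length)
crossovers; Bernoulli(mu) 0/1 mutation; symmetric migrant swaps along a
rural stepping-stone chain and within each urban-rural pair; urban demes
founded by a bottleneck from their paired rural deme. Hard sweeps plant
an advantageous allele on a chosen number of urban founder haplotypes
(fitness 1 + s x dosage, urban demes only); polygenic loci contribute to
an additive trait under Gaussian stabilising selection whose optimum is
shifted in urban demes. Initial variation is drawn from a neutral-shaped
site frequency spectrum (density proportional to 1/p) so the burn-in
only has to build linkage disequilibrium, not variation. Runs are
deterministic under the config seed; sweep conditioning (retry while the
allele is lost) is opt-in so unconditioned runs keep the null honest.

The simulator emulates drift, migration, founder effects, hitch-hiking
and polygenic shifts. It does not emulate SNP-chip ascertainment,
variable recombination maps, sex-biased processes or genotyping error;
passing tests therefore demonstrate the correctness and calibration of
the estimators under the stated model, not robustness to those
real-data features.

A light companion generator (`simulateFrequencyPanel`) draws genotypes
directly from specified population allele frequencies (no linkage); it
powers calibration and power studies of the association machinery where
forward simulation would add nothing but runtime.

## Problem sizes used by the tests and the acceptance script

All study conditions were fixed before the verification runs and are
deliberately desk-scale:

* neutral calibration: nine pairs, deme size 50, ~4,800 target sites
  (over 2,000 segregating in-sample), three chromosomes (two autosomes,
  one Z), 12 diploids per population;
* sweep recovery: one pair on a compressed 1 Mb chromosome with ~1 kb SNP
  spacing, rho = 1.5e-6 per bp per generation, deme size 100, founder
  bottleneck 50, a conditioned single-copy sweep with s = 0.5 completing
  shortly before sampling, 16 diploids sampled per deme, 50 replicates.
  The compression keeps the sweep footprint (tens of kb) an order of
  magnitude wider than the background homozygosity scale while spanning
  many SNPs — the regime in which haplotype scans are informative;
* polygenic power: |dAF| = 0.4 in all nine pairs at 12 diploids per
  site, direct frequency draws;
* sharing-null coverage: universe of 300 genes, five populations of 40
  draws, 500 inner resampling replicates, 200 outer replicates. The
  coverage experiment passes the generating draw count to the null
  (`nDraws`) so the check is self-consistent.

# Numerical and design choices

* Permutation and Monte-Carlo p-values always use (b + 1)/(n + 1).
* Percentiles are type-7; z-standardisation of window statistics uses
  the population SD.
* The per-SNP habitat/locality decomposition is a two-way fixed-effects
  ANOVA with type-II sums of squares (robust to the mildly unbalanced
  10-16 design); partial eta-squared is SS_term/(SS_term + SS_residual).
  Perfect fits (zero residual) fall back to explicit nested-model
  comparisons, where p-values are undefined. The printed interaction
  decomposition treats a SNP as habitat-consistent when its habitat
  effect exceeds its interaction effect.
* Minor-allele ties at frequency 0.5 resolve toward ALT,
  deterministically.
* Gene-sharing nulls resample genes with replacement (set sizes as draw
  counts), reduce to unique genes and count genes flagged in >= k
  populations (the >= k reading is primary; exactly-k counts are
  reported alongside).
* The pipeline expands one global seed into per-stage seeds by a fixed
  counter scheme, so stage outputs are independently reproducible.

# Known limitations

* The simulator's Z chromosome is autosomal in inheritance; only its
  standardisation class differs.
* iES integrates to the chromosome end when the EHHS curve never falls
  below the cutoff, so edge SNPs have one-sided support and noisier
  log-ratios; window-level summaries absorb most of this.
* The covariance-aware Bayes factor assumes Gaussian frequency errors, an
  approximation that weakens for populations of very few diploids or
  frequencies near 0/1.
* With few eligible windows the 95th-percentile dual criterion is
  unstable (a warning fires below 20 windows per class).
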