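---
title: "Pedigree-based recombination maps: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree-based recombination maps: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedrec)
library(data.table)
```

## The estimation problem

Meiotic crossovers can be observed directly in genotyped pedigrees: when an
offspring, one of its parents (the *donor*), and at least one grandparent are
all genotyped, the donor's two haplotypes can be phased against the
grandparents and the offspring's inherited haplotype traced along each
chromosome. Every switch in which donor haplotype the offspring carries marks
a crossover in the donor's meiosis. Aggregating many such meioses yields a
*recombination map*: the expected number of crossovers per meiosis in every
adjacent-SNP interval, whose genome-wide sum is the mean crossover count.
Dairy-cattle pedigrees are the motivating application — large
industry pedigrees yield maps for each breed and sex, sex differences of
about 10% in map length (males higher), hotspot regions at tens-of-kb
resolution, and mixed-model GWAS of recombination phenotypes.

`pedrec` implements that full chain: Mendelian trio phasing, haplotype
tracing with artifact filtering, even assignment of crossover mass to SNP
intervals, map construction and comparison, hotspot-region calling and
sharing, per-interval chi-square scans between populations, covariate
adjustment of crossover counts, hotspot-usage phenotypes, and a linear mixed
model association scan. A cohort simulator with known crossover truth makes
every stage testable without access to proprietary industry data.

## Phasing and crossover detection

Phasing is strictly single-site and Mendelian (`phase_trio()`): a homozygous
child is phased trivially; a heterozygous child is phased when one parental
genotype forces the transmitted allele (that parent homozygous, or the other
parent homozygous, including when the first parent's genotype is missing);
everything else stays unknown. Sites violating Mendelian inheritance are
flagged and set to unknown. We deliberately avoid population (LD-based)
phasing: it would change the algorithm class and make errors correlated
across families, whereas single-site rules are deterministic, order
independent and idempotent.

A site is *informative* for a donor when the donor is heterozygous and
phased; only there does the transmitted allele identify the donor haplotype.
`trace_crossovers()` follows the matched haplotype along each chromosome's
informative sites and emits a crossover between consecutive sites whose
template differs, with two numerical policies:

* **Minimum flanking support** (default 2): template runs shorter than the
  threshold are masked and tracing repeated. A single mistyped site would
  otherwise fabricate two crossovers; masking removes the dominant artifact
  at the cost of also hiding genuine tight double crossovers, which are rare
  at realistic SNP-interval rates.
* **Chromosome ends**: a switch needs evidence on both sides. Crossovers
  distal to the terminal informative site are undetectable and are not
  imputed. Detected map length is therefore biased slightly below the true
  genetic length, and the first and last few intervals of each chromosome
  are biased low.

A detected crossover is localized only to the gap between its flanking
informative sites, so its unit mass is spread evenly over the `k` underlying
SNP intervals (`1/k` each). Spreading conserves total crossover count exactly
but acts as a local smoother: per-interval mass variance is below binomial,
which makes downstream per-interval chi-square tests *conservative* when
applied to detection output at coarse panels. For calibration work the
package therefore provides `meiosis_records_from_truth()`, which carries
simulated crossovers at exact single-interval resolution; the statistical
calibration checks in the test suite run on that representation so that they
measure the test statistic, not the detection smoother.

Meiosis-level QC removes meioses with more than 45 genome-wide crossovers
(strictly greater, so 45 is kept), a tail cut against phasing blow-ups, and
drops families whose donor shows Mendelian-error sites above 2% of typed
markers (`qc_config()`; both thresholds exposed). The ">45" rule is applied
per meiosis; applying it per animal summed over meioses is a defensible
alternative reading, and users with multi-offspring donors should be aware
of the distinction.

## The simulator and what it does (not) emulate

`simulate_cohort()` draws, per breed, independent five-animal families:
grandsire and granddam, their offspring (the donor), an unrelated mate, and
one offspring of donor x mate. Exactly one (offspring, donor) pair per
family satisfies the three-generation rule, so truth bookkeeping is simple.
Defaults are chosen to be the study conditions the package targets:

* **Map lengths** 24.8 (male) and 22.5 (female) expected crossovers per
  meiosis — the genome-wide rates observed for Ayrshire pedigrees, and the
  sex ratio (about 10%) reported across dairy breeds.
* **Crossover placement**: per chromosome a Poisson count with mean equal to
  the chromosome's intensity sum, intervals chosen proportional to
  intensity, uniform in bp within an interval. No crossover interference and
  no obligate chiasma: the estimation pipeline models none, and Poisson is
  the simplest defensible null. Interference would lower the variance of
  counts, not their mean, so map construction is unaffected.
* **Hotspots**: a configured fraction of intervals (default 2%, matching the
  one-sided tail implied by a mean + 2.5 SD rule) carries a multiplied
  intensity (default 10x) before renormalization to the configured lengths.
* **Founders** have independent SNPs with allele frequencies uniform in
  [0.05, 0.95]; there is no background LD. Detection uses pedigree
  information only, so LD is irrelevant to the estimator; heterozygosity
  and hence informative-site density under these frequencies is in the
  realistic range for dense SNP panels.
* **Panels** emulate chip-density mixtures by evenly spaced SNP subsets;
  genotyping error replaces a call with one of the other two values at a
  configured rate; missingness is independent.

Passing tests on this generator demonstrate correctness of the machinery
under its own model. They do not demonstrate robustness to real-data
features the generator omits: assembly errors in SNP coordinates, LD between
SNPs, related families, non-Poisson interference, or chip-specific error
structure.

## Maps, hotspot regions and comparisons

`build_recmap()` divides summed interval masses by the number of
contributing meioses; maps merge as meiosis-count-weighted averages, and the
genome-wide sum equals the mean detected crossover count. Following the
common practice for mixed-density pedigree panels the pipeline restricts map construction to families in
the high-density panel class (the "at least 50K chip" rule; the class is
assigned from the *minimum* typed-marker count of the offspring-donor pair,
since the least-dense member limits resolution).

Hotspot regions are intervals whose rate strictly exceeds the mean plus 2.5
population standard deviations of all interval rates, zeros included (at
tens-of-kb interval widths these are "hotspot regions", not kb-scale
hotspots). Population (n-denominator) SD is fixed for determinism; at tens
of thousands of intervals the sample/population distinction is negligible.
Sharing between sets is reported Venn-style: an all-shared core, per-set
unique counts, and pairwise intersections excluding the core — the
convention used when quoting "shared in addition to the common core".

Between-population comparisons use a per-interval Pearson chi-square on the
2x2 table of crossover mass versus meioses without crossover mass in that
interval. Fractional masses enter the table unrounded; no continuity
correction is applied (meiosis counts are in the thousands). The
Bonferroni threshold is `alpha` divided by the number of *testable*
intervals (those with nonzero pooled mass), computed from the data at hand
rather than hard-coded, since reported thresholds typically round their denominator.
Equal-sample map correlations (`equal_sample_correlation()`) rebuild maps
from equal-size meiosis draws, separating genuine map differences from
sample-size artifacts. The relative-position profile normalizes rates per
Mb (interval widths vary) and fits one cubic smoothing spline across all
chromosomes pooled, GCV-selected by default with `spar` exposed.

## Phenotypes and the mixed model

The GWAS phenotype for recombination rate is the mean *residual* of
per-meiosis crossover counts after OLS adjustment for SNP density and the
informative-marker counts of donor and offspring — observation intensity,
not biology. The adjustment is fitted within breed x sex so that population
mean differences do not leak into residuals (fitting jointly is the main
alternative; within-group fitting is the conservative choice when group
means differ). Hotspot usage is the fraction of a meiosis's crossover mass
in hotspot intervals, averaged over an animal's meioses; zero-crossover
meioses are 0/0 and contribute nothing rather than being scored zero.

The association model is `y = Xg + Za + e` with a random animal effect
`a ~ N(0, sigma_a^2 K)`. `K` is the centered-cross-product genomic
relationship matrix (`compute_grm()`); a pedigree A-matrix
(`pedigree_amatrix()`) is available when genotypes are sparse. Variance
components are estimated once under the null by restricted maximum
likelihood with a single eigendecomposition of `K`; the restricted
likelihood, profiled in the residual variance, is maximized over the
variance ratio on a log scale in [1e-5, 1e5] by bounded one-dimensional
search. A flat profile (e.g. `K = I`) is flagged `indeterminate` and the
scan falls back to ordinary regression exactly. Each SNP is then tested by
generalized least squares with the correlation structure held fixed (the
usual one-step approximation — about three orders of magnitude cheaper than
per-SNP REML and immaterial for scan-level conclusions), the residual scale
re-estimated per SNP, and a 1-df Wald chi-square on the SNP effect. Sexes
are analyzed separately; the fixed effects are intercept and SNP dosage
only. Monomorphic SNPs are skipped and recorded.

## Numerical choices and degenerate inputs

* Interval convention everywhere: interval `i` is `(bp[i-1], bp[i]]`, stored
  on the row of its right SNP; chromosome-first rows carry rate 0. Map files
  are written in exactly that layout (SNP name, chromosome, bp, one rate
  column per breed x sex).
* Missing genotypes are `-1` on disk and in memory; `NA` appears only in
  haplotypes (unknown phase).
* Zero-variance maps have no defined correlation: `NA` with a warning, never
  a silent 0.
* Single-interval maps cannot be hotspot-called (SD undefined): error.
* Collinear or constant adjustment covariates are dropped by the OLS fit
  with a warning; the all-constant limit reduces to grand-mean centering.
* Eigenvalues of `K` are clipped at zero; the REML optimum at the lower
  ratio bound is reported as `boundary` with `sigma_a2 = 0`.
* All randomness flows from a single integer seed: the simulator seeds from
  `sim_config(seed=)`, the pipeline seeds once at entry, and reruns are
  byte-identical.

## Problem sizes used in validation

The test suite and the acceptance script run entirely on simulated cohorts,
sized so that sampling error, not compute, dominates: the end-to-end
sex-ratio check uses 4,000 families (2,000 detected meioses per sex), in
the test suite on a 10-chromosome, 10,000-SNP genome and in the
reproduction script on a 29-autosome, 58,986-SNP genome matching the panel
density the maps are designed for (detection losses shrink with density,
so the coarser test genome carries the wider +-2-point band);
truth-recovery checks use
5,000 single-sex meioses on a 2-chromosome, 4,000-SNP genome (2,000 SNPs
per chromosome, the per-chromosome density of a ~59k-SNP 29-autosome panel;
few, long chromosomes keep the documented chromosome-end bias confined to
under 1% of intervals); statistical calibration uses 1,200 meioses per population
for the chi-square scan, n = 500 for REML heritability recovery, and 200
animals x 2,000 SNPs for scan type-I error. The reported cohort-accounting
identities (per-breed totals, genome-wide rate = crossovers/meioses) are
checked exactly on the tabulated counts.

## Known limitations

* Detected map length underestimates true genetic length (chromosome ends,
  masked tight double crossovers, even-parity gaps); the deficit grows as
  panels get sparser and cancels in male/female ratios.
* Per-interval chi-square on detection output is conservative at coarse
  panels (mass spreading); see above.
* The simulator's independent-SNP founders cannot exercise LD-driven
  phasing pathologies, and X-chromosome handling is out of scope (autosomes
  only by construction).
* `pedigree_amatrix()` is quadratic in pedigree size and intended for
  moderate pedigrees.
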