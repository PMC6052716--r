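---
title: "Methods: selection tests for marine standing genetic variation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selection tests for marine standing genetic variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stickpop)
```

## The scientific setting

Marine threespine stickleback are often treated as a single, well-mixed
"contemporary ancestor" of the many freshwater populations derived from
them. Testing that assumption requires a chain of population-genomic
statistics: diversity summaries per sampling site, genome-wide and
per-locus F~ST~, a comparison of phenotypic divergence (P~ST~) with
neutral genetic divergence, isolation-by-distance tests, and outlier scans
whose thresholds are calibrated on simulated neutral data. `stickpop`
implements that chain as reusable, tested functions, together with an
island-model simulator that generates data with exactly the statistical
structure the analyses assume — so every stage can be exercised and
calibrated without access to any particular sequencing data set.

## The simulator and what it emulates

Genotypes are simulated under the **Balding–Nichols island model**: a
locus has an ancestral allele frequency $p$ (uniform on 0.05–0.5 by
default, mimicking an ascertained SNP panel with a 2% MAF floor), and each
deme draws its own frequency from
$\mathrm{Beta}\!\left(p\tfrac{1-F}{F},\,(1-p)\tfrac{1-F}{F}\right)$, where
$F$ is the deme's drift parameter. This model was chosen over a coalescent
because its $F$ equals the expected Weir–Cockerham $\theta$ between demes,
which turns parameter recovery into a direct, quantitative test of the
estimator (the suite demands $|\hat\theta - F| < 0.02$ for
$F \in \{0.02, 0.05, 0.10, 0.18\}$ at 8 demes × 30 diploids × 2,000 loci —
the size range typical of RAD-seq studies of this system).

Three structural features of real marine data are layered on top:

* **Hierarchical clusters** (the "one cluster from Washington to Alaska"
  pattern) via a two-stage draw: ancestral → cluster frequency at a
  between-cluster $F$, then cluster → deme at the member demes' own $F$.
  This is the simplest model with nested covariance.
* **A derived freshwater deme** drifting at a larger $F$ (default 0.22,
  inside the 0.18–0.27 range typical of marine–freshwater comparisons),
  with a configurable handful of "adaptive" loci forced near fixation for
  the minor marine allele. These planted loci exercise the outlier scan;
  their count (default 5) and frequency (default 0.98) are configuration
  parameters, not claims about nature.
* **Missing calls** placed uniformly at random. Real missingness arises
  from sequencing depth and is locus- and individual-structured; no
  published model of that structure exists for this design, so the
  simulator deliberately uses the simplest assumption. Consequences: tests
  passing under uniform missingness say nothing about informative
  missingness.

Neutral phenotypes are generated under the one-way random-effects model
used by the selection test itself: deme means
$\sim N(0, 2F\sigma^2_W/(1-F))$, individuals $\sim N(\mu_d, \sigma^2_W)$.
Within-deme phenotypic variances for plates or shape PCs are not published
for this system; the defaults ($\sigma^2_W = 1$ trait unit²) are stated in
configuration and are not claimed to match any study. Eda-linked plate
phenotypes draw Stn382 genotypes in Hardy–Weinberg proportions at each
deme's low-plated (L) allele frequency and Poisson plate counts around
genotype-specific means (defaults 62/45/8 for CC/CL/LL, reflecting the
strong decrease of plate number with L dosage).

## Weir–Cockerham θ

`wc_fst()` computes the 1984 variance components per biallelic locus —
among-deme $a$, among-individual-within-deme $b$, within-individual $c$ —
and reports per-locus $\theta = a/(a+b+c)$ plus the multilocus
ratio-of-sums $\sum a / \sum (a+b+c)$. Numerical choices:

* Negative per-locus $\theta$ is **retained**, not truncated; truncation
  would bias the ratio of sums upward. Per-locus values lie in $[-1, 1]$.
* A locus is *informative* if it has calls in ≥ 2 demes, mean sample size
  > 1, and a positive component total; monomorphic loci (all components
  zero) are skipped and listed in `$excluded`, never silently zeroed.
* Missing data are handled complete-case per locus: a deme with no calls
  at a locus simply drops out of that locus's component sums, so the
  number of demes $r$ varies by locus.

The implementation is vectorised over loci; the test suite checks it
against an independent, scalar, per-deme-loop evaluation of the same
formulas to 10⁻¹⁰ on exhaustive small instances (≤ 3 demes × ≤ 4
individuals × ≤ 3 loci), and against the simulator's known $F$ at scale.
Permutation significance of pairwise $\theta$ uses 999 label permutations
by default with the add-one rule $p = (1 + \#\{\theta^* \ge
\theta_{obs}\})/(B+1)$.

## Diversity summaries and the filter cascade

Per-deme summaries report private alleles (an allele seen in the focal
deme and in no other), percent polymorphic among variant loci, and means
of major-allele frequency, observed/expected heterozygosity, per-site
nucleotide diversity and F~IS~. Estimator choices, which the source data
format does not pin down, are fixed and documented here: expected
heterozygosity is the plain $2\hat p\hat q$; nucleotide diversity at a
variant site is the unbiased pairwise-difference form
$2\hat p\hat q \cdot 2n/(2n-1)$; per-locus
$F_{IS} = 1 - H_o/\pi$ (unbiased denominator), and the population value is
the **unweighted** mean over loci polymorphic in the deme. Only the
variant-loci block is computable from variant-only input; all-site
diversity would need the invariant site count, which genotype matrices do
not carry.

`apply_filters()` mirrors the standard RAD-seq cascade on a genotype
matrix: depth masking (calls below 4× set missing) precedes everything;
individuals below a call-count floor are dropped next (default off — the
"10,000 RAD-loci" style threshold has no natural scale on an arbitrary
matrix, so it is an explicit argument); then per locus, in reporting
order: called in ≥ 75% of individuals, called in ≥ `min_pops` demes
(presence, not segregation — this is how the "in 6 of 8 populations" rule
operates), overall MAF ≥ 2%, and overall $F_{IS} > -0.3$ (an
excess-heterozygosity guard against paralog collapse). The rejection log
names the *first* failing rule per locus. A genotype-likelihood filter is
a caller-internal quantity and is not reproducible from a genotype matrix;
it is therefore absent from the rejection-log vocabulary. Filtering is
idempotent, which the suite asserts.

Hardy–Weinberg testing is the Pearson goodness-of-fit χ² against
`hwe_expected()` counts with **1 degree of freedom** (biallelic locus, one
estimated parameter) and no continuity correction. Cells with zero
expectation contribute nothing; an expected count below 1 in a segregating
class triggers a warning rather than an automatic switch to an exact test,
because the reference analyses report the χ² form even at extreme counts
(e.g. observed 24/0/3 → expected 21.3/5.3/0.3, χ² = 27, p ≈ 2 × 10⁻⁷).

## The P~ST~–F~ST~ selection test

Phenotypic divergence is
$$P_{ST} = \frac{\sigma^2_B}{\sigma^2_B + 2\sigma^2_W},$$
with variance components from a one-way random-effects decomposition
(population as the random effect). The estimator is method-of-moments
ANOVA with the unbalanced-design correction
$n_0 = (N - \sum n_i^2/N)/(k-1)$ and $\sigma^2_B = (MS_B - MS_W)/n_0$
truncated at zero: closed-form, dependency-free, and equal in expectation
to an REML fit; the suite verifies the mean squares against `anova(lm())`
and Monte-Carlo recovery of known components. Zero within-group variance
is a degenerate input and errors rather than returning $P_{ST} = 0/0$.

Under neutral drift the between-population variance expected at a given
F~ST~ is
$$\sigma^2_{B,\,neutral} = \frac{2\,F_{ST}\,\sigma^2_W}{1 - F_{ST}},$$
i.e. the $\sigma^2_B$ at which $P_{ST} = F_{ST}$. The neutral null for
$P_{ST} - F_{ST}$ scales that variance by an independent
$\chi^2_{df}/df$ multiplier per draw (10,000 draws by default) and
converts each to $P_{ST} - F_{ST}$. Two deliberate choices:

* **Division by df.** A raw $\chi^2_{df}$ multiplier would inflate the
  null variance $df$-fold on average; dividing by $df$ gives the scaled
  variance expectation equal to the neutral $\sigma^2_B$, which is what
  the underlying sampling theory for population means intends. The
  undivided variant remains available (`scale_by_df = FALSE`) for
  sensitivity analysis.
* **df = number of phenotyped populations − 1**, passed explicitly (a
  study phenotyping 7 of its sites uses df = 6). `pst_fst()` defaults it
  from the data.

The p-value is the upper-tail exceedance fraction
$\#\{d^* \ge P_{ST} - F_{ST}\}/n_{draws}$, using **≥** (the conservative
reading of "the quantile beyond the observed value"); $p = 0$ is reported
verbatim when no draw reaches the observation, with resolution
$1/n_{draws}$ printed alongside. The same null serves F~STQ~ − F~ST~
(`fstq()` recodes a diallelic CC/CL/LL marker as allele dosages and runs
the single-locus Weir–Cockerham estimator, so F~STQ~ is directly
comparable with genome-wide $\theta$). Because $P_{ST}$ depends on
$\sigma^2_B/\sigma^2_W$ only, the null draws are invariant to
$\sigma^2_W$; the type-I calibration (500 neutral replicates at 7 demes ×
30, df = 6) must land in the 2–10% band at the nominal 5% level, and
does. Which SNPs constitute "neutral" F~ST~ is the caller's decision
(e.g. non-genic SNPs); the test accepts any F~ST~ value.

## Mantel tests and isolation by distance

`mantel_test()` is the Pearson correlation of the vectorised strict lower
triangles after aligning labels, with significance from joint row/column
permutation of the second matrix (999 permutations, add-one smoothing).
Spearman variants exist in the literature; Pearson is the convention of
the genetics packages this analysis style comes from, and is fixed here.
The default alternative is **one-sided positive association** — the
isolation-by-distance convention. That single convention reproduces both
published behaviours of the packaged coastal matrices: a negative
correlation lands deep in the upper tail ($r = -0.25$, $p \approx 0.8$),
while excluding the far-northern AK01 site yields $r = 0.46$,
$p \approx 0.02$. A two-sided option is exposed. The packaged distance
matrix cannot be re-derived (distances were measured along the coast to
bay mouths), so it is a fixture, not an output.

## POD-calibrated outlier scans

The scan statistic is per-locus Weir–Cockerham $\theta$. The published
analyses this mirrors used a Bayesian covariance-model statistic (XtX)
whose thresholds depend on that model's internals; what `stickpop`
preserves is the *decision rule* — an empirical threshold from a
pseudo-observed data set (POD) — with $\theta$ substituted as the
statistic. XtX threshold values from such analyses are therefore not
comparable with this scan's thresholds, by design.

`pod_scan()` simulates the POD under the island model with $F$ set to the
observed multilocus $\hat\theta$ (clamped to $[10^{-4}, 0.99]$), observed
deme sizes and missing rate, and ancestral frequencies resampled from the
observed pooled minor-allele-frequency spectrum (clamped to
$[0.01, 0.5]$). The threshold is the POD distribution's quantile — default
0.99, a configurable choice since no standard value exists — and flags are
exactly the loci above it, which makes flag sets monotone in the
quantile. Calibration on neutral simulations (20 seeds) must flag 0.3–3%
of loci at the 0.99 quantile; planted fixed-difference loci must be
recovered in ≥ 90% of seeds. Both hold in the suite.

`contrast_outliers()` repeats the scan per (marine, freshwater) pair over
the harmonised locus set — the intersection of loci with an informative
$\theta$ in *every* contrast, mirroring designs that require presence in
all populations — and tabulates per-locus flag counts across contrasts.
`discordant_loci()` applies the min/max rule (below 0.05 in one contrast,
above 0.25 in another) and reports the per-locus $\theta$ range, with the
mean taken over all loci.

## Plate morphs and Stn382

`classify_plate_morph()` is a total function on plate-count triples with
one documented gap: the published class definitions use "< 20 anterior
plates" for low-plated and "> 20" / "21–59 total" for partially plated,
leaving exactly 20 anterior plates (with no keel plate, or with a keel
but a total of 20) assigned to no class. Such fish are returned as
`UNCLASSIFIED` rather than silently binned — inventing a boundary rule
would fabricate data-cleaning behaviour the definitions do not license.
Two further readings are fixed and flagged: the "21–59 plates" of the
partially-plated rule is taken as the **total** count (consistent with the
fully-plated "≥ 60 plates"), and full plating (total ≥ 60) takes
precedence over anterior-based rules. Stn382 fragment sizes code
symmetrically: 218 bp = C, 158 bp = L.

## Reproducibility and problem sizes

Every stochastic function takes an explicit seed; functions restore the
caller's RNG state, and the pipeline fans a single global seed out to
per-stage seeds via a fixed affine map, so stages can be rerun in
isolation byte-identically. The suite and the acceptance script use
moderate problem sizes chosen to make the calibration bands tight enough
to be meaningful while keeping a full run in tens of seconds: 2,000 loci ×
240 diploids for drift-parameter recovery, 500 replicates for the type-I
band, 10,000 null draws (with a 10⁶-draw reference run checking tail
quantiles), 20 seeds for the POD calibration, and 1,000 random tables for
the discordance oracle.

## Known limitations

* No linkage disequilibrium, recombination, or coalescent history in the
  simulator; loci are exchangeable draws. Window- or haplotype-based
  analyses are out of scope.
* Uniform missingness only (see above).
* P~ST~ is single-trait and assumes the between-population additive
  proportion equals the within ( no $c/h^2$ sensitivity curve).
* The outlier scan's $\theta$ statistic ignores the covariance structure
  among demes that the hierarchical model-based statistic captures; in
  strongly clustered data the POD (which is exchangeable-island) is
  conservative for within-cluster contrasts and liberal for
  between-cluster ones.
* Biallelic loci only; multi-allelic records are skipped at import.
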