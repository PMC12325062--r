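---
title: "Methods: likelihood-ratio kinship testing with dynamic SNP selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: likelihood-ratio kinship testing with dynamic SNP selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpkin)
```

# The statistical model

`snpkin` performs pairwise relationship testing with the classical
likelihood-ratio machinery of kinship analysis, applied to biallelic SNPs.
A relationship hypothesis $R$ is summarised by its Cotterman coefficients
$(\varphi_2, \varphi_1, \varphi_0)$ — the probabilities that the pair
shares 2, 1 or 0 alleles identical by descent (IBD) at an autosomal
locus. The per-locus likelihood of an unordered genotype pair $(X, Y)$ is

$$\Pr(X,Y \mid R) \;=\; \varphi_2\,\Pr(X,Y \mid \mathrm{IBD}{=}2)
 \;+\; \varphi_1\,\Pr(X,Y \mid \mathrm{IBD}{=}1)
 \;+\; \varphi_0\,\Pr(X,Y \mid \mathrm{IBD}{=}0).$$

The IBD-conditional terms are generated from three primitives rather than
a table of nine special cases, which keeps the implementation uniform for
loci with up to four observed alleles:

* $\Pr(X,Y\mid \mathrm{IBD}{=}0) = \mathrm{HWE}(X)\,\mathrm{HWE}(Y)$,
* $\Pr(X,Y\mid \mathrm{IBD}{=}2) = \mathrm{HWE}(X)\,\mathbf 1[X{=}Y]$,
* $\Pr(X,Y\mid \mathrm{IBD}{=}1) = \mathrm{HWE}(X)\,T(X \to Y)$,

where $\mathrm{HWE}(\cdot)$ is the Hardy–Weinberg genotype probability and
$T(X \to Y)$ is the probability that $Y$ is formed from one allele of $X$
(each transmitted with weight ½) plus an allele drawn from the
population. The test suite verifies that these primitives reproduce every
entry of the classical joint-probability table, sum to one over all
ordered genotype pairs for every IBD state, and marginalise back to
Hardy–Weinberg.

Assumptions inherited from this framework: Hardy–Weinberg proportions at
the supplied allele frequencies, a known population (frequencies are
taken from the panel column the caller selects), no population
substructure correction (no $F_{st}$/theta), and independence of the
markers used — which is exactly what the selection stage is for.

## The parent–child mutation model

Under strict Mendelian transmission, a single opposite-homozygote locus
(e.g. AA vs GG) makes the parent–child likelihood exactly zero, however
many other loci agree. Genotyping error is far more common than true
mutation in sequencing data, so the parent–child IBD = 1 kernel uses a
transmission substitution rate $\mu$: the transmitted allele is delivered
intact with probability $1-\mu$ and substituted to each of the three
other nucleotides with probability $\mu/3$ (transitions and transversions
equally likely). The default $\mu = 10^{-3}$ corresponds to a Q30-quality
view of the data; it should be raised (e.g. to $10^{-2}$) for lower
quality genotypes. At $\mu = 0$ the kernel reduces exactly to the
IBD = 1 column of the classical table (tested on all nine genotype
configurations).

Because a pairwise comparison does not reveal which sample is the parent,
the likelihood is symmetrised as the equal-weight average of the two
directional assignments. The two directions coincide at $\mu = 0$ and
differ only at order $\mu$; symmetry of every per-locus likelihood in
$(X, Y)$ is property-tested.

The mutation model applies only to the parent–child hypothesis by
default: the other hypotheses place no probability mass exclusively on
IBD-sharing configurations that a single error can annihilate.

## The genotype-observation error channel

Separately from $\mu$, `locus_likelihood()`, `kinship_test()` and
`classify_study()` accept a `genotyping_error` rate $e$. When $e > 0$,
the observed genotypes are treated as noisy reads of latent true
genotypes on the panel's two alleles: the likelihood sums over the nine
latent genotype-pair combinations, weighting each by the per-allele
channel (an allele is mis-called with probability $e$, uniformly over the
other three nucleotides), and applies the relationship model to the
latent pair. This applies error to *every* hypothesis and is switched off
by default.

The distinction matters for error-prone data. In the package's own
simulation experiments (below), classifying data carrying 5% per-allele
error with a parent-child-only error model gives ~0.79 accuracy whether
or not $\mu$ is raised to match; turning on the observation channel at
the matching rate recovers ~0.88, and a mismatched channel (0.001 against
data at 0.05) costs several points. The validation experiments therefore
interpret "the error rate used in likelihood calculation" as this
all-hypotheses channel with $\mu$ left at its default — raising only the
parent-child transmission rate cannot help the other three hypotheses,
and empirically does not reproduce the matched-beats-mismatched ordering
that motivates modelling error in the first place.

## Cumulative likelihoods, calls and margins

Log-likelihoods are accumulated in natural-log space (no underflow at any
realistic locus count) and reported as log10. The call is the
maximum-likelihood hypothesis among, by default, unrelated, parent–child,
full siblings and second degree — in that fixed order, which also breaks
exact ties deterministically (ties are flagged). The margin is
$\log_{10}$ of the ratio between the best and second-best cumulative
likelihoods; it is the package's confidence measure, and in simulations
incorrect calls concentrate at small margins.

Loci are skipped pairwise when either genotype is missing. When the
observation channel is off, loci where either sample carries an allele
with no panel frequency (which per-allele error injection can create) are
skipped the same way — every hypothesis would otherwise score an exact
zero; with the channel on, such loci are retained and explained by the
channel. The number of loci actually used is always reported.

# Dynamic marker selection

Selection is two-stage and case-specific:

1. **MAF filter.** Keep markers whose minor allele frequency is strictly
   above `maf_min` in *every* requested population. Heterozygosity — and
   with it the expected per-locus log-LR — is maximal at MAF 0.5, so a
   threshold of 0.3–0.4 concentrates information in few markers.
2. **MGD sweep.** Per chromosome, sweep from the lowest genetic position
   inward, keeping the first marker and every marker at least `mgd_cm`
   centimorgans beyond the last kept one. On an ordered line this greedy
   rule attains the exact maximum number of markers compatible with the
   spacing constraint; the test suite verifies this against an
   independent dynamic-programming maximiser on hundreds of random
   instances. Ties in genetic position are broken by physical position,
   then marker id, so selection is fully deterministic.

Spacings of 30 cM or more make residual linkage negligible for the
product-of-likelihoods approximation; 10–20 cM buys more markers at the
cost of some dependence. Genotype availability in the two compared
samples does not feed back into selection — missing loci are skipped at
comparison time — so the selected panel depends only on the candidate
panel and the configuration.

Physical positions are mapped to genetic positions with a sex-averaged
map: exact at map knots, linearly interpolated between them, and
linearly extrapolated beyond the terminal knots using the terminal
interval's slope, floored at 0 cM. Clamping to the terminal knot value
instead would stack all telomeric markers at one genetic position and
defeat the spacing constraint; the extrapolation rule is a declared
design choice, not an inference about any particular reference map.
Chromosome names are normalised (`chr1` ≡ `1`); only autosomes are used.

# The pedigree simulator

`simulate_study()` provides the validation data: founders drawn under
Hardy–Weinberg at the panel frequencies, genotypes gene-dropped through a
three-generation family template, and per-allele genotyping error
injected at a configurable rate (each allele substituted with the stated
probability, uniformly over the other three nucleotides — deliberately
the same channel the likelihood error model assumes, so matched/mismatched
experiments are interpretable).

The template has fifteen members: a founder couple with five children, a
second founder couple with one child, one marriage between the two
sibships, and five grandchildren. Labeling every pair by its pedigree
relationship — and excluding the one in-family married couple, who are
neither blood relatives nor independent founders — gives exactly 22
parent–child, 20 full-sibling, 40 second-degree and 22 unrelated pairs
per family (104 labeled pairs), the bookkeeping used throughout the
validation experiments. Unrelated pairs here are *truly* unrelated
(fresh founders), unlike "unrelated" pairs drawn from population
reference panels, which are often distantly related.

Two transmission modes are available. The default, independent loci,
draws each transmitted allele independently per locus; it is the correct
model for panels thinned to ≥ 30 cM, where per-meiosis linkage is weak,
and it is what the validation experiments use. The `haldane` mode
transmits per-chromosome haplotypes with crossovers as a Poisson process
on the cM scale (no interference), for probing residual-linkage effects
on denser selections. Crossover interference, sex-specific maps and
IBD-segment tracking are out of scope.

An exhaustive-enumeration utility (`enumerate_ibd()`) recovers IBD
coefficients exactly from small pedigrees by enumerating all gamete
transmissions, and gene-dropped genotype pair distributions are checked
against the $\sum_k \varphi_k \Pr(X,Y\mid k)$ mixture within three
binomial standard errors at $10^5$ loci for every built-in relationship —
tying the simulator and the likelihood model to each other through two
independent routes.

## What the simulator does and does not emulate

The simulator gives clean ground truth: exact Hardy–Weinberg founders,
the exact frequencies used by the likelihoods, error from the same
channel the model assumes, and no cryptic relatedness. Real casework
data differ in all four respects (frequency mismatch between panel and
population, substructure, platform-specific error, background
relatedness). Passing the simulation benchmarks therefore demonstrates
the correctness and internal calibration of the machinery, not field
performance; accuracies on idealised synthetic data should be read as
upper bounds for comparable marker counts.

# Validation experiments and problem sizes

The shipped experiments (`scripts/acceptance.R`, mirrored in the test
suite) use 50 families per replicate (5,200 labeled pairs), 130
independent biallelic markers with MAF uniform on (0.4, 0.5), and
per-allele error rates 0.001, 0.01 and 0.05 matched by the likelihood
observation channel, averaged over three replicate seeds — sizes chosen
to estimate four-class accuracy to well under a percentage point while
keeping a full run in minutes on one core. Under these conditions
overall accuracy is ≈ 0.94 at error 0.001, ≈ 0.93 at 0.01 and ≈ 0.88 at
matched 0.05, with errors concentrated between unrelated and second
degree and between the two first-degree classes. Scoring uses the
standard definitions: accuracy as the confusion-matrix trace over the
total, and weighted F1 as the support-weighted mean of one-vs-rest F1
over classes with non-zero support (equal to macro F1 when supports are
balanced; both are cross-checked in the tests against a
plain-definition scorer).

# Numerical and interface choices

* All accumulation in natural logs; user-facing quantities in log10.
  Raw likelihood ratios overflow/underflow at a few hundred loci.
* Panel QC rejects frequencies outside the open interval (0, 1);
  monomorphic markers carry no pairwise information and break the MAF
  fold.
* Results round-trip at 12 significant digits through the two output
  files (per-population summary, per-marker detail), and re-summing the
  per-marker file reproduces the summary log-likelihoods.
* VCF input decodes the `GT` field only; half calls, non-ACGT alleles
  and indels become missing. Panel matching is by (chromosome,
  position) with ref/alt accepted in either orientation (swap-folded,
  with a message).
* The command-line wrapper exits 0 on success, 1 on classed user errors
  (bad options, missing files, unknown samples), 2 on anything else.

# Known limitations

Pairwise comparisons only (no multi-reference pedigree likelihoods); no
$F_{st}$/substructure correction; no linked-marker HMM, so relationships
beyond second degree are out of reach by design; population labels must
be supplied, not inferred. These are the standard extension points for
this class of tool.
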