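---
title: "Normal-referenced methylation calling and group screens: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normal-referenced methylation calling and group screens: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methcall)
```

This vignette is the package's account of its statistical model: what each
stage assumes, which parameters matter, what the synthetic-data generator
does and does not emulate, and where the design was genuinely open.

## The measurement model

Bisulfite pyrosequencing quantifies, for each assayed CpG position `c` of a
gene `g` in a sample `s`, a methylation percentage `m_sgc` in [0, 100]. The
package consumes these already-quantified percentages (pyrogram
deconvolution belongs to the instrument software) as a tidy one-row-per-CpG
table, because genes have different numbers of assayed CpGs. Assay failures
are whole-gene per sample: either all CpGs of an assay are measured or none
is, which is how pyrosequencing assays fail in practice; isolated missing
CpGs are nevertheless tolerated and simply skipped by the averaging rule

```
M_sg = mean over non-missing CpGs of m_sgc .
```

A sample whose assay failed entirely gets a missing average and a missing
call, and drops out of that gene's denominator.

## Aberrant-methylation calling

For each gene the normal-tissue averages define a reference band
`mu_g ± k * sigma_g` with `k = 2` by default. A tumour sample is
hypermethylated when its average lies strictly above the band and
hypomethylated strictly below it; values exactly on a threshold are in
range, because the rule is a strict exceedance rule. Under a Gaussian null
with a well-estimated reference this misclassifies about
`2 * pnorm(-2) ≈ 4.6%` of null samples, which the test suite checks as a
[3%, 7%] band on large simulated cohorts.

Two numerical choices are exposed because they are material at the actual
reference sizes:

* `sigma_g` uses the sample standard deviation (denominator `n - 1`) by
  default; with only five normal controls per gene for most of the panel
  the population-SD alternative visibly narrows the band, so it is a
  config option (`sd_denominator`) rather than a silent constant.
* Each gene's reference uses all normals actually measured for that gene.
  In the emulated design most genes have 5 normal controls while FOXC1,
  ABCB1, PPP2R2B and PTEN have 28. With `n = 5` the estimated band is
  itself noisy: a gene can draw an unluckily tight reference and show
  double-digit false-positive frequencies even when nothing is programmed.
  This is a property of the 2·SD design at small `n`, not of the
  implementation, and it is why the calibration-sensitive acceptance
  checks use large simulated reference sets.

The imprinted gene IGF2 sits near 50% methylation in normal tissue
(allele-specific methylation), so deviations in either direction are
biologically aberrant: default reports show hypermethylation only for
non-imprinted genes and both states for imprinted ones. Hypo states are
computed and stored for every gene regardless.

Frequencies are `100 * n_called / n_valid`, rounded half away from zero to
one decimal, with `n_valid` (non-missing calls) printed alongside: with
per-gene assay failures the denominator is not the group size, and a
frequency without its denominator is not auditable.

Technical controls (unmethylated commercial DNA, mixed lymphocyte DNA) are
recorded and can optionally be subtracted (per-gene unmethylated-control
mean, floored at zero); subtraction is off by default because background
controls define the noise floor rather than a calibrated offset.

## Permutation tests and FDR

Methylation levels are compared with rank tests whose p-values come from
the permutation distribution of the statistic rather than asymptotic
approximations, which matters at group sizes of 20–30 with ties:

* Mann-Whitney U with midranks; two-sided significance is the proportion
  of label assignments whose `|U - n_a n_b / 2|` reaches the observed
  deviation. Two-sidedness by deviation (not p-doubling) is symmetric and
  well-defined under ties.
* Kruskal-Wallis H with the tie-corrected statistic; upper-tail
  permutation p. The tie correction rescales H identically for every
  permutation, so it never changes the p-value — it is kept so reported H
  matches the conventional statistic.
* Spearman rho as the Pearson correlation of midranks, permuting one
  vector; rho² is reported alongside rho since co-methylation strength is
  conventionally quoted squared.

When the number of distinct assignments is at most `exact_cap` (default
10,000) the tests enumerate them all and the p-value is exact. Otherwise
`n_perm` (default 100,000) random permutations are sampled and the observed
arrangement is included: `p = (b + 1) / (n_perm + 1)`, the standard
unbiased Monte-Carlo p that can never be zero. Every test derives its own
seed from a single root seed and a test label (a 31-bit string hash), so
adding, removing or reordering tests never perturbs the permutation stream
of the others, and sample order is irrelevant.

A practical floor follows from the construction: the smallest attainable p
is `1/(n_perm + 1)`. Screens that feed Benjamini-Hochberg must keep this
floor well below `alpha / m` (m = family size), otherwise no test can
survive adjustment; the defaults do, and scaled-down test runs choose
`n_perm` accordingly.

BH is the step-up procedure (`q_(i) = min_{j>=i} m p_(j) / j`, capped at
1). The family is a genuine modelling choice the data do not dictate: the
package adjusts the clinicopathological screen over all gene-by-factor
tests it ran, and the co-methylation analysis over all gene pairs, both
config-exposed. Untestable cells (a factor level empty after dropping
unknowns) are reported as missing and excluded from the family rather than
imputed.

## Expression by the standard-curve method

Relative expression uses the standard-curve method, not ΔΔCt: Ct is
regressed on log10 input quantity over a dilution series (≥ 3 points;
less than two decades of range draws a warning), quantities are
interpolated as `10^((Ct - intercept)/slope)`, and the target quantity is
divided by the reference-gene quantity. Efficiency is
`10^(-1/slope) - 1`; a perfect doubling per cycle is slope −3.3219. The
reference gene (PGK1 in the emulated design) is chosen for stable
expression across groups. Triplicates are aggregated by mean Ct and a QC
flag is raised above a replicate SD of 0.5 cycles — a declared default, as
no universal QC rule exists. Relative levels are kept unlogged for
median-based group comparisons; only plots would log them.

## The synthetic-cohort generator

The generator exists so every stage can be validated without external
data. It draws, per gene and sample, a latent gene-level methylation from
a two-component Gaussian model — a baseline (unmethylated) population and
a shifted hypermethylated subpopulation (plus a hypomethylated one for
IGF2) — then adds per-CpG Gaussian jitter and clips to [0, 100]. Defaults
were chosen once:

* group sizes 27 DCIS / 28 invasive / 34 mixed / 28 normals; most genes
  measured in 5 normals, FOXC1/ABCB1/PPP2R2B/PTEN in all 28;
* baseline means 6–8% with SDs 1.5–2.5% and jitter SD 1.5% — tightly low
  normals, as pyrosequencing background sits at a few percent, and low
  enough clipping (< 1%, reported as `clipped_fraction`) for the Gaussian
  model to be honest;
* hyper shifts +30 to +40 points, giving near-complete separation from
  the reference band so that programmed fractions are recoverable;
* per-gene hyper fractions that emulate the qualitative published pattern
  (a RASSF1A-like gene high in every group, FOXC1-like rising from DCIS
  to invasive disease, CDKN2A-like near zero, IGF2 with both aberrant
  directions);
* whole-assay missingness at 3% (15% for the PPP2R2B-like assay, whose
  reported denominators imply more failures);
* expression: log-normal quantities with a 2-fold tumour down-shift
  applied to all tumours regardless of their methylation call — the
  early-silencing pattern — with Ct noise SD 0.1 cycles on triplicates.

A beta-distributed latent model was considered and rejected: the
two-component Gaussian keeps the per-sample ground truth (component +
latent value) trivially exportable, which is what the calling-accuracy
tests consume; clipping is monitored instead.

What the generator does **not** emulate — and therefore what passing tests
do not show about real data: tumour-purity dilution (real tumour averages
are mixtures with stroma), correlated methylation across genes (defaults
draw genes independently, so co-methylation rho² is near zero by
construction and the correlation machinery is validated on its own exact
and invariance properties), clinicopathological factor effects (defaults
are null; power tests inject shifts explicitly via `factor_effects`),
batch or run effects, and any pyrogram-level artefacts. Defaults are
qualitative emulations, not estimates of any study's data.

## Pipeline determinism and problem sizes

`run_pipeline()` is deterministic given config and seed: report TSVs and
the JSON manifest (package version, seed, config hash) are byte-identical
across re-runs, which the suite asserts file by file. The test suite and
the acceptance script scale simulations to sizes chosen for tight
Monte-Carlo error at interactive runtimes: 5,200 null samples against a
1,000-normal reference for the false-positive band, 100 generator seeds
for frequency recovery, 2,000 null replicates at 399 permutations for the
type-I error of the Mann-Whitney test (the permutation p is valid at any
permutation count), 1,000 random vectors for the BH cross-check, and
9,999 permutations where single p-values are quoted.

## Known limitations

* With five normal controls the 2·SD band is itself a random quantity;
  per-gene false-positive rates on real data can deviate substantially
  from the nominal 4.6% in either direction.
* Calling is per gene; per-CpG calling and clustering of call matrices
  are out of scope.
* Permutation tests treat samples as exchangeable under the null; no
  adjustment for covariates or tumour purity is attempted.
* The BH family boundaries are configuration, not inference; q-values are
  only comparable within the family they were computed in.
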