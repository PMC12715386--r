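---
title: "Estimating population sex ratios from eDNA allele quantification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating population sex ratios from eDNA allele quantification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ednasex)
```

## The problem

In species with genetic sex determination, a sex-linked locus can carry one
allele shared by both sexes (the *common* allele) and one carried only by
males (the *male-specific* allele). In a pooled DNA sample — a mixture of
tissue extracts, or environmental DNA (eDNA) filtered from the water a
population lives in — the concentration ratio of these two alleles encodes
the sex composition of the contributing individuals. `ednasex` implements
the full chain from droplet digital PCR (ddPCR) droplet counts to a
male-proportion estimate, together with the detection/quantification limits
and group statistics needed to interpret such estimates, and a simulator
that generates every input the pipeline consumes.

The motivating system is an XY-determined newt in which a male-specific SNP
allele at a validated locus occurs at roughly one copy per seven copies of
the common allele within a male (with substantial between-male variation),
while females carry the common allele only.

## Poisson quantification of droplet counts

A ddPCR reaction is partitioned into $n$ droplets of volume $V_d$; $k$ of
them fluoresce above threshold. Because a droplet can contain several
template copies, the mean copies per droplet is

$$\hat\lambda = -\ln(1 - k/n),$$

giving a reaction concentration $\hat\lambda / V_d$ (copies/µL) and, after
correcting for the template fraction of the mix, a starting-material
concentration

$$\hat c = \frac{\hat\lambda}{V_d} \cdot \frac{V_\mathrm{mix}}{V_t},$$

with $V_\mathrm{mix} = 22$ µL and $V_t \in \{2, 4\}$ µL in the assay this
package models. The droplet volume defaults to $V_d = 0.85$ nL, the QX200
standard; it is a configurable parameter because instruments differ.

**Confidence intervals.** The delta method on $\hat\lambda$ gives
$\mathrm{SE}(\hat\lambda) = \sqrt{\hat p / (n(1-\hat p))}$ with
$\hat p = k/n$; a symmetric 95% normal interval is clamped at zero. For
$k = 0$ the point estimate is zero and the upper bound is the rule-of-three
limit $-\ln(1 - 3/n)$ rescaled to concentration. This choice is fully
reproducible and closely tracks published single-well ddPCR statistics;
commercial software applies an undocumented internal variant, so small
discrepancies against instrument output are expected. Simulation (and the
test suite) puts empirical coverage at 93–97% for $\lambda$ from 0.001
to 1.

**Merged wells.** Replicate wells are pooled by summing $k$ and $n$ before
the Poisson correction — a "meta-well" — rather than averaging per-well
concentrations. Pooling is exactly invariant to how droplets are
partitioned into wells and is what lets rare alleles (a handful of positive
droplets spread over six wells) be quantified at all. Saturated wells
($k = n$, unbounded $\hat\lambda$) are flagged and excluded from pooling
with a warning, mirroring the exclusion of over-concentrated samples in
practice.

**Ratios.** The common-to-male ratio divides two merged concentrations; its
interval comes from the delta method on the log ratio assuming independent
numerator and denominator (the two targets are read in different channels).
Per-well ratios are retained only to compute the replicate relative
standard deviation (RSD, $100 \cdot s/\bar x$). Fieller-type intervals were
considered and left out: at the droplet counts involved the log-normal
approximation is adequate and simpler to reason about.

**Droplet classification.** When per-droplet amplitudes are available,
1-D per-channel thresholds are applied inclusively (a droplet exactly at
threshold is positive). Defaults are 2400 for the male channel (HEX) and
3000 for the common channel (FAM): cross-reactive droplets produced by
female DNA sit below 2000 HEX while true positives sit at 3000–4000, so the
conservative threshold excludes cross-reactivity by construction. The
channel→target mapping is configuration, not hard-coded.

## Limits of detection and quantification

Both limits are decision rules over a dilution series measured in
replicate (six wells per level by default):

* **LoD** — walking from the most dilute level upwards, the most dilute
  level whose per-replicate starting-material concentrations differ
  significantly (default $\alpha = 0.05$) from the negative (female)
  replicates. When the negatives are all zero a one-sample *t*-test
  against zero is used; otherwise a Welch two-sample test. Zero-valued
  replicates are *included* in the test sample — the sampling noise of
  empty wells is part of the measurement. Shapiro–Wilk normality of the
  positive replicates is reported as a flag, not used as a gate. The
  reported LoD concentration is the merged-well estimate at that level. If
  significance is non-monotone across levels the result is flagged.
* **LoQ** — the lowest concentration at which the common-to-male ratio is
  measured within an acceptable RSD, default 30% (a deliberate ceiling for
  low-template eDNA work). Two assessments are reported: per-well mode
  (RSD over single-well replicate ratios at each level) and merged mode
  (RSD of the merged ratios across levels). Single-well ratio RSD blows up
  at low copy numbers from subsampling error alone, while merged ratios
  stay far tighter — so the merged-mode LoQ typically reaches the deepest
  tested level provided enough replicates are merged.

`apply_limits()` removes samples whose merged male-allele concentration is
below the LoD and logs every exclusion with its reason; the pipeline
refuses to return a silently empty result if everything is excluded.

## From allele ratio to sex ratio

Let $\rho$ be the per-male common-to-male copy ratio (default 7, a
population calibration parameter). With $M$ males and $F$ females each
contributing equal DNA, the expected common-to-male ratio is

$$E[R_{c:m}] = \rho \, \frac{M + F}{M},$$

and with biomass-proportional contributions the head-count fraction is
replaced by the mass fraction. Inverting the equal-contribution model, an
observed male-to-common ratio $r$ maps to a male-proportion estimate

$$\hat p_\mathrm{male} = \rho \, r,$$

reported both raw (it can exceed 1 when a high-copy male dominates a small
pool) and clamped to $[0, 1]$; calibration regressions use the raw value so
clamping cannot flatter the fit.

**Per-individual expected values.** Between-male copy-number variation is
large (CV ≈ 0.38). When the individuals in a sample are genotyped and
their $\rho_i$ measured — as in mock validation experiments —
`expected_ratio_individuals()` pools their contributions harmonically,
$E[R_{c:m}] = (M+F) \big/ \sum_\mathrm{males} \rho_i^{-1}$, which is the
appropriate hypothesised value for observed-versus-expected comparisons.
Using the population average $\rho$ instead leaves the between-male
variation in the residuals; with shared individuals across samples those
residuals are correlated and regression intervals become anti-conservative.
Both modes are exposed; `run_pipeline(expected = …)` accepts per-sample
hypothesised values.

**Mass correction.** Observed eDNA ratios can be rescaled by the sample's
body-mass composition (male-to-common ratios multiplied by the
male-to-total mass proportion; common-to-male by its inverse), converting a
biomass-weighted signal toward the per-capita scale. It is the identity
when males are the entire biomass. Whether eDNA contribution is better
modelled per-capita or per-mass is left as this mode switch; the simulator
exposes an allometric exponent $b$ (contribution $\propto \mathrm{mass}^b$,
default 1) but the estimator deliberately does not — allometry is a
hypothesis to explore in simulation, not an estimation parameter.

**Group statistics.** The standard analysis of a designed sex-ratio
experiment is implemented as `compare_groups()` (one-way ANOVA with
Tukey HSD on log10 ratios when Shapiro–Wilk residual normality and Levene
homoscedasticity hold, otherwise Kruskal–Wallis with Dunn's test under
Benjamini–Hochberg adjustment; the Dunn z uses the tie-corrected
large-sample variance), `accuracy_vs_expected()` (per-group one-sample
Wilcoxon signed-rank against the hypothesised ratio; exact null for
n ≤ 25 without ties), and `calibrate()` with two variants: the
dose-response of $\log_{10}(r + 1)$ on $\log_{10}(p_\mathrm{male} + 1)$,
and the observed-versus-expected regression on the $\log_{10}$ scale whose
slope-equals-one test is the accuracy criterion.

## What the simulator emulates

`simulate_individuals()` draws per-male $\rho_i$ from a lognormal with
arithmetic mean 7 and CV 0.38 — the scale on which per-individual ratios
were averaged — clipped to the observed range (3, 14) (clipping is
configurable off). Body masses are lognormal around sex-specific means,
females slightly heavier than males (defaults 7 g and 6 g, CV 0.15, the
realistic direction for crested newts).

`simulate_sample()` composes a pool: in mock mode every individual
contributes the same common-allele concentration (default 50 copies/µL,
the scale of a normalised, 1:10-diluted extract mixture); in eDNA mode
contributions are $\mathrm{mass}^b \times$ a shedding rate (default
5 copies/µL per gram) $\times$ lognormal noise with CV 0.5. The shedding
CV is a tuning default — eDNA variability beyond "greater than mock" is
not quantified in the motivating data — chosen so simulated eDNA
calibration $R^2$ lands in the 0.4–0.7 band reported for real tank
experiments. A male's male-allele contribution is its common contribution
divided by its $\rho_i$; females contribute none.

`simulate_droplets()` partitions a true concentration into wells: accepted
droplets uniform on 14,000–20,000 (typical QX200 yields), positives
binomial with per-droplet probability $1 - e^{-\lambda}$. The male channel
adds cross-reactive false positives at `false_pos_rate` (default
$3 \times 10^{-4}$) per unit of common-allele $\lambda$ — calibrated so an
undiluted female sample yields a handful of droplets across six wells, the
observed magnitude of probe cross-reactivity — and in amplitude mode those
droplets are drawn below 2000 HEX so the conservative threshold removes
them. `simulate_experiment()` assembles the full mock/eDNA design: seven
sex-ratio groups × three series × three technical replicates by default,
with one shared male and one shared female re-entering designated groups
in every series (the design feature that lets a single low-$\rho$ male
depress every one-male sample it enters), plus an all-female control and a
no-template control per series.

All randomness flows through an optional per-call seed that is applied
locally and restores the caller's RNG state, so identical seed + config
give byte-identical outputs without global side effects.

**What the simulator does not model** — and what passing tests therefore
do not show about field data: eDNA transport, degradation and spatial
heterogeneity; time dynamics of shedding (stress, acclimation); uneven
filtration or extraction recovery; PCR inhibition; multiple life stages.
Simulated eDNA noise is a single lognormal per individual; real tank data
show heavier tails (occasional samples with almost no nuclear DNA), which
is why the LoD exclusion step exists.

## Numerical and design choices

* Threshold comparisons are inclusive (`amplitude >= threshold`).
* $k = 0$ wells quantify as exactly 0 with a rule-of-three upper bound;
  $k = n$ wells flag saturation and are excluded from merges.
* A ratio with zero male concentration returns an infinity sentinel with
  `male_to_common = 0`; both targets zero is an error, not a number.
* The LoD search reports the most dilute significant level even when an
  intermediate level is non-significant, with a non-monotonicity flag.
* Degenerate inputs are errors with named causes (empty wells, inconsistent
  merge metadata, single-valued regression designs, empty groups), never
  silent NA propagation.
* Group labels follow the `"xM:yF"` convention; `"1M"` means `"1M:0F"`.

Stochastic properties are verified at fixed seeds with problem sizes chosen
to make the checks sharp but quick: 2,000 simulated wells per $\lambda$ for
estimator coverage, 2,000 merged six-well estimates for bias, 100 full
experiment simulations for the slope-coverage and group-separation
operating characteristics, 40–60 simulated dilution series for the
LoD/LoQ behaviour properties, and 200 simulated tanks per composition for
male-proportion recovery.

## Known limitations

* $\rho$ is a population parameter; transferring it between populations
  without re-calibration biases $\hat p_\mathrm{male}$ proportionally.
* The raw estimator inherits harmonic-pooling bias from between-male
  copy-number variation (about +14% at CV 0.38); it shrinks as the number
  of contributing males grows and is partly offset in practice by clamping
  and by female-biased biomass.
* Confidence intervals are large-sample approximations; at a handful of
  positive droplets the LoD *t*-test, not the interval, is the reliable
  detection decision.
* Only 1-D per-channel thresholds are supported, not 2-D cluster gating;
  droplet input is CSV, never proprietary instrument files.
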