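# ednasex

Sex-ratio estimation from environmental DNA (eDNA) by droplet digital PCR
(ddPCR) allele quantification.

## The problem

Adult sex ratios drive population dynamics, yet measuring them usually
means catching and sexing animals. For species with genetic sex
determination, a sex-linked SNP locus offers a non-invasive route: one
allele (*common*) is carried by both sexes, the other (*male-specific*)
only by males. In any pooled DNA sample — a mixture of tissue extracts
from known individuals, or eDNA filtered from a pond — the concentration
ratio of the two alleles encodes the sex composition of the contributors.
ddPCR can quantify both alleles down to a handful of template copies,
which is the regime nuclear eDNA lives in.

`ednasex` is for molecular ecologists running such assays: it turns
per-well droplet counts (or raw droplet amplitudes) into Poisson-corrected
allele concentrations, pools replicate wells into merged "meta-wells" for
rare-allele work, derives limits of detection and quantification from a
dilution series, and maps allele ratios onto male-proportion estimates
with optional biomass correction — plus a complete simulator of
individuals, eDNA shedding and droplet partitioning, so every step can be
exercised and power-checked without laboratory data.

## The model in brief

With `k` positive of `n` droplets of volume `V_d`, the mean copies per
droplet is `λ = -ln(1 - k/n)`; the starting-material concentration is
`λ / V_d × V_mix / V_t` (mix volume 22 µL, template 2 or 4 µL). Replicate
wells are merged by *pooling counts*, not averaging concentrations.
If each male carries `ρ` common copies per male-specific copy (default
`ρ = 7`), a sample of `M` males and `F` females with equal contributions
is expected to show a common-to-male ratio `ρ(M + F)/M`; inverting, an
observed male-to-common ratio `r` gives the male-proportion estimate
`p̂ = ρ·r`. The LoD is the most dilute level of a replicate dilution
series whose concentrations differ significantly from female negatives
(t-test, α = 0.05); the LoQ is the lowest concentration whose ratio RSD
stays under 30%. See the methods vignette
(`vignettes/ednasex-methods.Rmd`) for the full account.

## Worked example

Quantify a rare allele from six replicate wells (six positive droplets in
~99,000), as in a deep dilution-series level:

```r
library(ednasex)
w <- data.frame(positives = c(2, 1, 0, 1, 1, 1), accepted = 16500,
                template_volume_ul = 4, dilution_factor = 256)
merge_wells(w)
#>        lambda conc_reaction conc_start     ci_low   ci_high wells_merged
#> 1 6.06079e-05    0.07130341  0.3921687 0.07837416 0.7059633            6
#>   k_total n_total dilution_factor saturated
#> 1       6   99000             256     FALSE
```

0.39 copies/µL in the starting material, with a 95% interval that excludes
zero only because the six wells were pooled — no single well could make
that call.

Simulate a full mock experiment (7 sex-ratio groups × 3 series × 3
technical replicates, with per-male copy-ratio variation) and run the
pipeline:

```r
ex  <- simulate_experiment(seed = 42)
res <- run_pipeline(ex$droplets, ex$metadata)
res
#> ednasex pipeline result: 21 samples, 6 exclusion(s)
#> ANOVA F(6) = 4.50, p = 0.0096  [anova_tukey]
#> Calibration (proportion): slope = 0.182 (95% CI 0.084-0.281), R2 = 0.441, F(19) = 14.98, p = 0.00103
#> Calibration (expected): slope = 0.742 (95% CI 0.435-1.048), R2 = 0.575, F(19) = 25.67, p = 6.85e-05
#>   slope-equals-one test: p = 0.0941

head(res$estimates[, c("sample_id", "group", "common_to_male", "p_male")])
#>   sample_id group common_to_male    p_male
#> 1   1M_serA    1M       9.880824 0.7084429
#> 2 3M1F_serA 3M:1F      11.416008 0.6131741
#> 3 2M1F_serA 2M:1F       5.438261 1.0000000
#> 4 1M1F_serA 1M:1F      13.552481 0.5165106
#> 5 2M2F_serA 2M:2F       9.344433 0.7491092
#> 6 1M2F_serA 1M:2F      20.941057 0.3342716
```

The omnibus ANOVA separates the sex-ratio groups; common-to-male ratios
fall as the male proportion rises; the observed-versus-expected slope is
statistically compatible with 1 (the accuracy criterion); and the six
exclusions are the per-series all-female and no-template controls, each
logged in `res$exclusions`. Per-sample `p_male` is noisy at this scale —
one male's copy number can dominate a two-animal pool — which is exactly
the behaviour the simulator is there to quantify.

Limits from a simulated 4-fold dilution series:

```r
series <- simulate_dilution_series(c(common = 686, male = 98), seed = 1)
negs   <- data.frame(sample_id = "neg", target = "male", positives = 0L,
                     accepted = 16500L, template_volume_ul = 4,
                     dilution_factor = 1)[rep(1, 6), ]
detect_lod(series, negs)
detect_loq(series)
```

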