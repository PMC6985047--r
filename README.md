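# agemix

Two-component mixture analysis of age-at-diagnosis distributions in
molecularly stratified cancer case series.

## The problem

Breast-cancer age-at-diagnosis distributions are often *bimodal* — an
early-onset peak near 45 and a late-onset peak near 65 years — and the
balance between the two peaks shifts with tumor biology (ER protein
expression, *ESR1* RNA, PAM50 intrinsic subtype), while the peak locations
stay put. `agemix` formalizes this: within each molecular stratum it fits
four models to the ages,

| model | density | free parameters k |
|---|---|---|
| single normal | N(mu, sigma^2) | 2 |
| single SNP | P(z)^2 phi(z) / (sigma C), z = (x-mu)/sigma | 2 + K |
| normal mixture | pi N1 + (1-pi) N2 | 5 |
| SNP mixture | pi SNP1 + (1-pi) SNP2 | 2(2+K) + 1 |

where the semi-nonparametric (SNP) density multiplies a Gaussian kernel by
a squared polynomial of degree K (a_0 = 1, C the closed-form moment
normalizer), allowing skewness and heavy tails. The best single and best
mixture model are compared by
`delta_AIC = AIC(top single) - AIC(top mixture)`; delta > 10 is substantial
support for two components, 4-10 supported with less confidence, < 0
favors one component. For each stratum the package reports n, median age,
early/late modes (integer years) and mixing proportions p-early/p-late
(two decimals, summing to 1).

A synthetic-cohort generator stands in for study data: truncated ([20, 74]
years) two-component age mixtures whose mixing proportion varies by
stratum, with ER%, *ESR1* and PAM50 linked to the latent onset class.

## Worked example

```r
library(agemix)

# the "overall" world: early/late components N(46, 9^2) / N(67, 7^2),
# early weight 0.72, ages truncated to the 20-74 ascertainment window
truth <- mixture_params(normal_params(46, 9), normal_params(67, 7), 0.72)
co <- generate_cohort(cohort_spec(5000, list(stratum_spec("overall", 1, truth)),
                                  seed = 1))

cmp <- run_tournament(co$age, degree = 0, config = fit_config(seed = 1))
cmp
#> <model_comparison>  top single: single_normal (AIC 38745.85)  top mixture: mixture_snp (AIC 38382.13)
#>   delta_AIC = 363.72  verdict = substantial_mixture

summarize_stratum("Overall", co$age, cmp)[, c("n", "median_age", "mode_early",
                                              "mode_late", "p_early", "p_late")]
#>      n median_age mode_early mode_late p_early p_late
#> 1 5000         50         47        66    0.82   0.18
```

The tournament overwhelmingly prefers two components (delta_AIC = 363.7 at
n = 5000) and the fitted modes, 47 and 66, sit within a year of the
generative component means. The default fit treats the observed ages as
untruncated, so `p_early = 0.82` overshoots the effective early share
(~0.75): the late component's upper tail is clipped at 74 and the plain
mixture compensates. Passing `fit_config(truncation = c(20, 74))`
renormalizes every density to the ascertainment window inside the
likelihood and targets the nominal weight 0.72 instead (replicate-mean
recovery 0.70 over 50 cohorts; single-cohort estimates are heavy-tailed —
see the vignette). `degree = 2` adds the SNP families to the tournament;
`table1_like_spec(n, seed)` builds the full six-stratum ER cohort.

The full pipeline — read a case CSV, stratify, run every tournament, write
summaries/curves/manifest — is one call:

```r
run_analysis("cases.csv", stratify = "er_category", degree = 2,
             config = fit_config(seed = 1), out_dir = "results/")
```

or from the shell:

```sh
Rscript inst/cli/agemix.R simulate --preset table1 --n 20000 --seed 1 --out cohort.csv
Rscript inst/cli/agemix.R fit --input cohort.csv --stratify er_category --seed 1 --out results/
```

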