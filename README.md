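# cobaltperm

Quantifying intestinal hyperpermeability ("leaky gut") in cattle from
sequential **spot urine samples** after an oral dose of the indigestible,
nonmetabolizable marker **Co-EDTA** — without total urine collection — and
linking the quantified permeability to serum inflammatory markers.

The package is for researchers running marker-based permeability studies:
it provides the kinetic model, the population fit, the scaling from spot
samples to total marker excretion, the model-adequacy diagnostics, and the
downstream group statistics, plus a synthetic-cohort generator with known
truth so the whole pipeline can be validated end to end.

## The model

Urinary Co:creatinine ratios after dosing follow a double-exponential
excretion curve

```
f(t) = A e^{-k1 t} · exp(-B e^{-k2 t})
```

with amplitude `A` (mg Co/mg creatinine), lag-shape `B`, terminal decay
rate `k1` (1/d) and rise rate `k2` (1/d). All animals are fitted
simultaneously with a nonlinear mixed-effects model — log-normal
between-animal random effects on all four parameters, proportional
residual error — estimated by **SAEM** (stochastic-approximation EM with
Metropolis-within-Gibbs sampling of the random effects). Adequacy is
checked with **normalized prediction distribution errors** (npde): under a
correct model they are standard normal, tested by Shapiro–Wilk (normality),
Wilcoxon signed-rank (zero median) and a chi-square variance test (unit
variance).

Because urinary creatinine is excreted at a near-constant 29 mg/kg BW/day
in cattle, each animal's curve converts to total urinary Co without urine
collection:

```
total Co (mg) = AUC[f] ((mg/mg)·d) × BW (kg) × 29 (mg/kg/d)
```

and to a recovered fraction of the elemental Co dose (6.9 g per 50 g
Co-EDTA). The AUC is computed by the trapezoidal rule (default 10,001
points over the 36-h window), with a lower-incomplete-gamma closed form as
the analytic reference. Group inference follows the study design: 2×2
factorial ANOVA (aspirin × breed) per outcome, and stepwise backward
ANCOVA (Type II tests, marginality-respecting) of each serum marker on
quantified Co excretion.

## Worked example

```r
library(cobaltperm)

sim <- simulate_cohort(seed = 2026)          # 2 breeds x 2 aspirin x 3 heifers
fit <- fit_population(sim$urine, seed = 2026)
fit
#> <saem_fit>  12 animals, 108 observations, error model 'proportional'
#>   population estimates (between-animal SD of log parameter):
#>     A   = 0.091839  (omega 0.149)
#>     B   = 4.4083  (omega 0.224)
#>     k1  = 2.4337  (omega 0.171)
#>     k2  = 13.832  (omega 0.0795)
#>   sigma = 0.1189,  converged: TRUE
```

The population-typical curve peaks near 5 h post-dose and has essentially
decayed by 36 h; `sigma` is the proportional assay CV (~12%).

```r
compute_npde(fit, n_sim = 1000, seed = 2027)
#> <npde_report>  108 observations, 1000 simulations
#>   normality (Shapiro-Wilk)     p = 0.253
#>   zero median (Wilcoxon)       p = 0.799
#>   unit variance (chi-square)   p = 0.876
```

All three adequacy tests are comfortably nonsignificant: the fitted model
reproduces its own data-generating process.

```r
exc <- cohort_excretion(fit)   # AUC x BW x 29 -> mg Co, % of 6.9 g dose
dplyr::summarise(exc, mean_total_mg = mean(total_co_mg),
                 mean_pct = mean(dose_fraction_pct), .by = breed)
#>   breed    mean_total_mg mean_pct
#> 1 Holstein          269.     3.89
#> 2 Jersey            196.     2.85
```

Mean recovery sits in the few-percent range expected for this marker.
Finally, the stepwise ANCOVA finds the TNF–excretion relationship that the
generator built in (slope truth 0.5 pg/mL per mg) and discards every
interaction:

```r
dat <- dplyr::left_join(sim$serum, exc[, c("animal_id", "total_co_mg")],
                        by = "animal_id")
ancova_stepwise(dat, "tnf_pg_ml")
#> <ancova_fit>  tnf_pg_ml ~ ... + total_co_mg (alpha = 0.05)
#>   dropped:
#>     treatment:breed:total_co_mg  p = 0.529
#>     treatment:breed              p = 0.682
#>     treatment:total_co_mg        p = 0.292
#>     breed:total_co_mg            p = 0.157
#>     breed                        p = 0.795
#>   retained:
#>     treatment                    F = 10.03, p = 0.0114
#>     total_co_mg                  F = 25.2, p = 0.000719
#>   covariate slope: 0.8145 per mg Co
```

Published tables can be re-analyzed from summary statistics alone:
`anova_from_summary(c(210, 239, 292, 274), sem = 16.5, n_per_cell = 3)`
rebuilds the full 2×2 ANOVA (F and p per term) from cell means and SEM.

A command-line wrapper for the whole pipeline lives at
`inst/cli/cobaltperm.R` (subcommands `simulate`, `fit`, `quantify`,
`stats`, `run`).

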