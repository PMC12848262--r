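---
title: "Quantifying intestinal permeability from spot-urine cobalt excretion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intestinal permeability from spot-urine cobalt excretion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cobaltperm)
```

## The measurement problem

Intestinal hyperpermeability lets indigestible markers such as Co-EDTA
cross the epithelium and appear in urine. Total urine collection quantifies
that recovery directly but is laborious and risky; single spot samples are
easy but confounded by urine concentration. `cobaltperm` implements the
middle road: sequential **spot** samples expressed as Co:creatinine ratios,
a population fit of an excretion curve, and scaling to total excretion via
the near-constant daily creatinine output of cattle (29 mg/kg BW/day, a
dairy-cattle constant that `creatinine_rate` lets you override for other
populations).

## Excretion curve

Each animal's ratio-versus-time profile is modelled as

$$f(t) = A\,e^{-k_1 t}\,\exp\!\left(-B\,e^{-k_2 t}\right),$$

a first-order washout (rate $k_1$, 1/d) multiplied by a saturating
appearance term ($B$ dimensionless, $k_2$ 1/d). The curve starts at
$A e^{-B}$, peaks at $t^\* = \ln(B k_2/k_1)/k_2$ when $B k_2 > k_1$, and is
monotone otherwise. Time is handled in **days** internally (hours at the
file boundary, divided by 24) so that the AUC carries the units
(mg/mg)·day used by the excretion formula.

Integration uses two routes. The trapezoidal rule on a uniform grid
(default 10,001 points — far beyond the accuracy any downstream statistic
can resolve) is the production path. The analytic reference follows from
the substitution $u = B e^{-k_2 t}$:

$$\int_0^T f\,dt = \frac{A}{k_2\,B^{k_1/k_2}}\left[\gamma\!\left(\tfrac{k_1}{k_2}, B\right) -
\gamma\!\left(\tfrac{k_1}{k_2}, B e^{-k_2 T}\right)\right],$$

with $\gamma$ the lower incomplete gamma function, evaluated through
`pgamma()` on the log scale so small $B$ cannot overflow $B^{-k_1/k_2}$;
$B = 0$ falls back to the elementary exponential integral. The default
integration window is $[0, 1.5\,\mathrm{d}]$ — the 36-h sampling span —
because the recovered dose fraction is defined over the observed excretion
period; `t_end = Inf` with the closed form documents the full-curve
alternative (the difference is a few percent at the default kinetics).

## Population fit (SAEM)

All animals are fitted jointly: individual log-parameters
$\phi_i = \log(A_i, B_i, k_{1i}, k_{2i})$ are normal around population
means with **diagonal** covariance (the minimal structure guaranteeing
positivity; correlated random effects are out of scope), and residuals
follow a **proportional** error model by default — ratio data span two
orders of magnitude within a profile, so constant relative error is the
natural choice; additive and combined variants are selectable.

Estimation is stochastic-approximation EM:

* **E-step**: Metropolis-within-Gibbs per animal — an independence
  proposal from the current population distribution, a full-vector random
  walk, and a componentwise random walk, three sweeps per iteration.
  Proposal scales adapt toward ~30% acceptance during exploration.
* **SA step**: sufficient statistics ($\phi$, $\phi^2$, the residual sum)
  with step size 1 through 300 exploratory iterations, then $1/k$ over 100
  smoothing iterations.
* **M-step**: closed-form updates of means, variances and the residual
  parameter. During the exploratory phase variances may shrink by at most
  5% per iteration (simulated annealing). Without this constraint the
  first iterations — when the chains still sit near the population mean —
  drive the between-animal variances toward zero, after which the
  tightened prior pins the chains there permanently; with it, variance
  components are recovered reliably.

Initialization is a deterministic pooled grid search over the four
parameters minimizing pooled least squares, so no user tuning is needed.
Animals are processed in `animal_id` order and all randomness derives from
one seed, making fits bit-reproducible and independent of input row order.

The pre-dose (t = 0) sample is **excluded** from the likelihood by default:
the model predicts $A e^{-B} > 0$ at $t = 0$ while true pre-dose Co is
assay background, so the sample informs background, not kinetics
(`include_predose` re-admits it).

Convergence is flagged by comparing the average parameter vector over the
first and second halves of the smoothing phase; the default tolerance of
10% relative drift is a stall detector, not a precision claim — with 12
animals the variance sufficient statistics carry roughly 40% relative
Monte-Carlo noise per iteration, so half-phase averages of well-behaved
fits still differ by a few percent, while collapsed or still-moving runs
show an order of magnitude more.

Per-animal curves are empirical-Bayes posterior modes under the final
population estimates, found by direct optimization from each chain's last
state.

## Model adequacy: npde

`compute_npde()` simulates `n_sim` (default 1000) replicate datasets from
the fitted model at the observed design points, decorrelates observed and
simulated values within each animal using the inverse Cholesky factor of
the empirical simulated covariance (falling back to marginal
standardization, with a warning, if that covariance is singular), and maps
each observation's rank among its simulated counterparts through
$\Phi^{-1}$ with a $(k + 0.5)/(n_{sim}+1)$ continuity correction. Three
tests summarize the pooled npde: Shapiro–Wilk for normality, Wilcoxon
signed-rank for zero median, and a two-sided chi-square test of unit
variance on $n-1$ degrees of freedom (implemented directly; base R has no
fixed-value variance test).

## Excretion and dose fraction

`total Co = AUC × BW × creatinine_rate`, and
`dose fraction = 100 × total / dose`. The elemental-Co content of the
standard 50 g Co-EDTA dose, 6.9 g, is configuration data, not chemistry
computed here. Although excretion is conventionally labelled "mg/d", the
quantity is the total over the integration window (~1.5 d); the two
coincide because excretion is essentially complete within the window.

## Group statistics

`factorial_anova()` is the 2×2 OLS ANOVA (aspirin × breed) with term
F-tests against the residual mean square. A term whose sum of squares is
zero at the numerical scale of the data reports F = 0, p = 1 — this keeps
the constant-response edge case (where the MSE is also zero) well defined.
For balanced designs the pooled SEM of a cell mean is $\sqrt{MSE/n}$,
which makes published tables invertible: `anova_from_summary()` rebuilds
every sum of squares from the four cell means via single-df contrasts
($SS = n c^2/4$) and $MSE = n\,SEM^2$, reproducing the raw-data ANOVA
exactly in the balanced case.

`ancova_stepwise()` starts from `response ~ aspirin * breed * covariate`
and eliminates backward: among terms not contained in any retained
higher-order term (marginality), the highest-order term with the largest
Type II p-value above 0.05 is dropped, one per step, until every droppable
term is significant. Type II sums of squares (via `car::Anova`) respect
marginality and coincide with Type I/III in the balanced factorial case.
Ties are broken by the larger p-value — deterministic standard backward
elimination.

A property worth knowing at this sample size (n = 12, 4–8 error df): the
final surviving null interaction is the *minimum* of several correlated
p-values sharing one volatile MSE, so some interaction survives
elimination in roughly 15–20% of null datasets — far above the nominal 5%
per-test rate — and a null covariate stays in the final model (mostly
frozen by marginality under such an interaction) in ~20% of runs, even
though its own false-significance rate is the nominal ~5%. This is
intrinsic to stepwise selection on small factorial designs, not an
implementation artifact; the test suite measures it.

## Synthetic cohorts

`simulate_cohort()` emulates the study design: 2 breeds × 2 aspirin levels
× 3 heifers, body weights Holstein 362 ± 25 kg and Jersey 269 ± 21 kg
(truncated positive), sampling at 0, 1, 3, 6, 8, 12, 18, 24, 30, 36 h, and
a 6.9 g elemental-Co dose. The default kinetic truth
(A = 0.0953, B = 4, k1 = 2.5/d, k2 = 15/d; log-SDs 0.12/0.25/0.20/0.15;
proportional sigma 0.12) was calibrated **once** through the closed-form
AUC so the population curve peaks near 5 h, decays to under 5% of peak by
36 h, and yields ≈3.6% mean dose recovery at the design's mean body
weight; the log-SDs are loosely matched to the between-animal spread
implied by a published SEM of 16.5 mg at n = 3, and sigma to the reported
<12% inter-assay CV. Serum markers are log-normal around
`baseline + breed effect + aspirin effect`, TNF additionally carrying
`slope × (true excretion − 250 mg)`; centring the covariate keeps
baselines interpretable as control-Holstein means at typical excretion.
The pre-dose sample is background noise only; negative draws are truncated
at zero and counted.

What passing tests on these cohorts do **not** show: robustness to
kinetics outside this family (multi-compartment behavior), correlated
random effects, assay drift over the sampling day, or creatinine output
that deviates from the constant-rate assumption — on real data those
appear as npde failures, which is exactly what the adequacy layer is for.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: all-zero animals are excluded
with a warning, predictions are floored at 1e-300 before logs, variance
components at 1e-6, and the B = 0 AUC path avoids the $B^{-k_1/k_2}$
division. Validation simulations in the test suite use 12-animal cohorts
(20 seeds for recovery, 200 Monte-Carlo repetitions for npde calibration
at 300 simulation replicates and for elimination behavior) — sizes chosen
so each property is measured with useful binomial precision while a full
check remains an everyday, minutes-scale run.

## Known limitations

* Random effects are diagonal; genuine A–k1 correlation will partly load
  onto the residual error.
* The npde calibration is assessed with the generating model as the
  simulating model; refitting 200 cohorts would confound npde calibration
  with estimation noise.
* Stepwise selection at n = 12 over-retains interactions (see above);
  treat retained interactions with corresponding skepticism.
* The creatinine-excretion constant is a population average; per-animal
  deviation propagates linearly into total excretion.
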