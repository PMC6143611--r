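---
title: "Methods: quantifying rod outer segment renewal in a stripe-based screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying rod outer segment renewal in a stripe-based screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rosrenew)
```

## The measurement model

Rod outer segments (ROS) renew continuously: membranous discs are added at
the base and shed from the tip, where the retinal pigment epithelium
phagocytoses them. A heat-shock-induced, membrane-tethered fluorescent
stripe marks the disc layer formed at induction and therefore acts as a
pulse label. Two distances are measured per rod in confocal stacks:

* **D^G** (growth distance), base → stripe: growth after induction;
* **D^S** (shedding distance), stripe → tip: growth before induction
  minus material shed after it.

With the default timeline — rod births from 3 dpf, heat shock at 6 dpf,
fixation at 10 dpf, pre-label growth at 1.6 μm/day — the model is

$$D^G = 4\,g, \qquad D^S = \max(0,\; 4.8 - 4\,s),$$

with $g$ and $s$ the post-induction growth and shedding rates in μm/day.
`expected_distances()` and `infer_rates()` implement the two directions;
the D^S floor (a stripe cannot sit beyond the tip) is reported as a
truncation flag, and a negative *inferred* shedding rate — possible when a
treated D^S exceeds the assumed 4.8 μm pre-label growth — is returned
flagged rather than clamped, so that simulation-vs-inference round trips
remain exact. All four timeline parameters are configurable
(`study_timeline()`); 1.6 μm/day is the literature value for the rearing
conditions before induction and is deliberately not estimated from screen
data.

Control benchmarks (`pool_controls()`) summarise all vehicle-control fish
of a study. Because the fish is the unit of replication, the benchmark
mean is the grand mean of fish-level means and the benchmark SD the
standard deviation across fish means; rod-level statistics are reported
alongside. Whether a published dispersion is fish- or rod-level is often
ambiguous — both are exposed so either convention can be matched.

## Per-week estimation

Screens are run in weekly batches: 8–32 compounds share one DMSO control
raised from the same clutch. Between-week variation (clutch, food,
temperature) is large, so compounds are only ever compared with their
week-matched control. Within a week the data are modelled as

$$y_{ij} = \beta_{t(i)} + b_i + e_{ij}, \qquad
  b_i \sim N(0, \tau^2), \quad e_{ij} \sim N(0, \sigma^2),$$

for rod $j$ of fish $i$, with fish nested in treatment $t(i)$: one fixed
cell mean per treatment, a random intercept per fish. Estimation
(`fit_random_intercept()`) is restricted maximum likelihood, written from
first principles:

* the variance ratio $\theta = \tau^2/\sigma^2$ is profiled, reducing the
  problem to per-fish sufficient statistics (count, mean, within-fish sum
  of squares) with GLS weights $w_i = n_i/(1+\theta n_i)$ — fits are
  $O(\#\text{fish})$ per objective evaluation regardless of rod counts;
* $\theta$ is located by bounded 1-D search (`optimize` on
  $[0, 10^6]$, tolerance $10^{-10}$) and then polished to a root of the
  analytic profile derivative, which uses $dw/d\theta = -w^2$ and the GLS
  orthogonality $\sum_{i \in t} w_i(\bar y_i - \hat\beta_t) = 0$; on
  balanced designs the result agrees with the classical nested-ANOVA
  closed forms to $10^{-8}$;
* a negative between-fish moment is truncated at $\tau^2 = 0$ (flagged),
  standard practice for boundary estimates;
* REML rather than ML matches the default of the mixed-model software
  family this design is normally analysed with, and is the right choice
  with as few as 3 fish per group.

Degenerate inputs: a fish listed under two treatments is a lineage error;
all-identical observations trigger a flagged residual-variance floor
($10^{-10}$) so downstream contrast machinery stays finite.

`contrast_control()` forms each compound-minus-control contrast with its
standard error. Given the variance components, group estimates are
independent, so the contrast correlation matrix has the classical
many-to-one product form $\rho_{jk} = \lambda_j\lambda_k$ with
$\lambda_j = \sqrt{v_0/(v_j+v_0)}$ ($v$ = estimate variances, 0 =
control); with equal group sizes all off-diagonals are 0.5.

Degrees of freedom (`satterthwaite_df()`) use the Satterthwaite
moment-matching approximation: $df = 2v_c^2/\widehat{\mathrm{Var}}(v_c)$,
with the gradient of the contrast variance in $(\sigma^2, \tau^2)$ taken
analytically and the variance of the component estimates from the inverse
observed REML information (central-difference Hessian of the exact
restricted deviance, relative step $10^{-4}$). This is the default df
method of the software stack such screens are usually analysed with;
containment-type alternatives could be plugged in at the same interface.
Two limits anchor the approximation: at $\tau^2 = 0$ it collapses to the
ordinary residual df (rods − levels), and when fish variance dominates it
approaches the fish-level df (fish − levels); a singular information
matrix falls back to the latter, flagged.

## Dunnett many-to-one comparisons

Adjusted p-values (`dunnett_adjust()`) are single-step and two-sided (the
screen reports both increases and decreases):

$$p^{adj}_i = 1 - \Pr\!\big(\max_j |T_j| \le |t_i|\big),$$

under the $k$-variate central t with the contrast correlation matrix and
a common df — the minimum Satterthwaite df across the week's contrasts, a
conservative tie-break for the joint distribution. The multivariate t
(rather than normal) matters because fish-level replication is small; for
df > 500 the normal limit is used.

The equicoordinate probability is evaluated by randomized quasi-Monte
Carlo. For product-form correlation matrices the probability conditions
on the shared factor $U \sim N(0,1)$ and the scale
$s=\sqrt{\chi^2_\nu/\nu}$, leaving a smooth two-dimensional integrand

$$\Pr = \mathbb{E}_{U,s} \prod_j \Big[\Phi\Big(\tfrac{cs-\lambda_j U}{\eta_j}\Big)
 - \Phi\Big(\tfrac{-cs-\lambda_j U}{\eta_j}\Big)\Big],
 \qquad \eta_j = \sqrt{1-\lambda_j^2},$$

integrated over shifted Halton points (bases 2, 3; default $2\times10^5$
points in 8 independently shifted batches). The batch spread yields a
reported Monte-Carlo half-width `mc_error`, typically $10^{-5}$ at the
defaults — against a $10^7$-point brute-force oracle the adjusted
p-values agree to a few $10^{-4}$. Shifts are drawn from a locally seeded
generator (default seed 1), so identical inputs reproduce identical
p-values to the last bit and the caller's RNG stream is untouched. A
correlation matrix without product structure (not produced by this
pipeline, but accepted) falls back to simulating $\max_j |T_j|$ from the
same point set, with a correspondingly larger `mc_error`.

Significance tiers follow the screen's ladder — `***` p < 0.001, `**`
p < 0.01, `*` p < 0.05, strict boundaries — via `significance_tier()`.

## Hit calling

A **primary** call requires both thresholds (`hit_thresholds()`): an
absolute percent change of at least 20 % relative to the week-matched
control (non-strict, computed from full-precision model estimates;
integer rounding — half away from zero — is reporting-only) *and*
adjusted p < 0.001 (strict). The 20 % default corresponds to a 1 μm shift
of the ~5 μm growth benchmark; on the shedding side, a +20 % D^S equates
to halving the shedding event (0.72 μm instead of 1.4 μm shed over the
window — `suppression_equivalent()`). Comparisons significant at the
secondary/tertiary tiers are **tiered** calls with direction; a
sub-threshold comparison that is significant at any tier *and* shares
target and direction with an existing primary hit becomes a
**same-target follow-up** — the redundancy of the compound library is
part of the screen's design. "Similarly affected" is not quantified in
prose anywhere, so requiring any tier better than `ns` plus direction
match is an interpretive choice, documented here.

Qualitative content areas (phagosome accumulation, Rhodopsin
mislocalization, CMZ disruption) are scored by the at-least-one-image
rule (`qualitative_hit()`): three photoreceptor-layer images for the
first two, one representative CMZ image. A D^S direction label worth
remembering: *increased* D^S means shedding was suppressed, *decreased*
D^S means shedding was promoted.

`build_report()` chains everything per week — fit, contrasts, common df,
Dunnett, calls — then pools benchmarks, resolves same-target follow-ups,
and tallies pathways per content area (primary calls for the four
distance areas, flags for the qualitative ones; counts descending, label
as tie-break; missing annotations under "unannotated"). Compounds
annotated but absent from the measurements are marked lethal and receive
no calls; a week without its control is a hard error naming the week.

## The synthetic-screen generator

`simulate_screen()` exists so the estimation and calling machinery can be
validated against known truth. It reproduces the screen's hierarchy:

| parameter | default | origin |
|---|---|---|
| compounds per week | 8–32 | screen design |
| fish per treatment | 3 | screen design |
| rods per fish, D^G | 33–149 | observed range |
| rods per fish, D^S | 24–105 | observed range |
| lethality | 0.30 | observed fraction |
| control rates | 1.25 / 0.35 μm/day | control benchmarks |
| week SD | 0.55 μm | calibrated (see below) |
| fish SD | 0.35 μm | calibrated (see below) |
| rod SD | 1.0 μm | calibrated (see below) |

Weekly baselines are drawn for both rates (normal, `week_sd` on the
distance scale, i.e. divided by the 4-day window on the rate scale);
compound effects multiply the rates (multiplicative effects keep
percent-change semantics scale-free); fish get normal intercepts; rods
normal residuals floored at 0; D^S is missing for a random subset of rods
so missingness is independent of treatment (the real mechanism — stripes
unmeasurable near tips — is unknown, so an uninformative mechanism is the
defensible default). Lethal compounds contribute no rows but stay in the
truth table. Each week draws from a child stream derived deterministically
from the screen seed, so any week can be regenerated independently and
identical seeds give byte-identical tables.

**Calibration.** Published control dispersion is pooled, not decomposed,
so the week/fish/rod split is an assumption: 0.55/0.35/1.0 μm makes the
pooled fish-level control SD $\sqrt{0.55^2+0.35^2} \approx 0.65$ μm,
matching the growth-distance benchmark, and lets weekly control means
span roughly 4–6.2 μm as reported. The split is tunable; every validation
result below depends on it.

**What passing tests do not show.** The generator is normal, homoscedastic
and symmetric; real measurement distributions are skewed with outliers
(manual 3-D tracing), fish intercepts need not be normal, lethality may
correlate with effect size (simulated independent), and real D^S
missingness may be informative. Recovery rates measured on synthetic
screens therefore characterise the pipeline under the stated model, not
the biology.

## Validation results and problem sizes

The test suite computes, among others (sizes chosen to keep a full run
around ten minutes):

* REML agreement with the balanced closed forms to $10^{-8}$ and with an
  established reference implementation to $10^{-4}$ on 20 random
  unbalanced fixtures (the reference is a cross-check only; the package
  never calls it);
* Dunnett agreement with a $10^7$-point Monte-Carlo oracle within
  $5\times10^{-4}$ on 10 random fixtures, plus the classical equal-n
  critical values;
* a 500-week null screen (reduced rods, 20–40 per fish) with a primary
  false-call rate well under 1 %;
* a 200-week recovery screen: one +35 % and one −35 % growth-rate
  compound among six nulls per week, default rod counts.

The recovery experiment deserves a caveat. Under the default calibration,
three fish per group put a floor of $\sqrt{2\cdot0.35^2/3} \approx 0.29$
μm on any contrast SE, so a ±35 % growth effect (1.75 μm at the 5 μm
benchmark) yields $|t| \approx 6$ against a k = 8 Dunnett critical value
of ≈ 4.7 at df ≈ 17. The resulting probability that such a compound
clears *both* primary thresholds is 0.799 ± 0.005 (measured over 1,200
simulated effect compounds) — the nominal 80 % recovery target sits
exactly on this power curve, so individual 200-week estimates scatter on
both sides of it. This is a property of the screen design (3 fish,
week-matched control, family-wise error control), not of the estimation
machinery: the same simulations show the estimated percent change is
unbiased (mean +35.4 at truth +35) and its 95 % intervals cover the truth
at nominal rate.

## Known limitations

* One concentration, one time window: no dose–response or time-course
  modelling.
* The model is strictly nested (rods in fish in treatment in week): no
  crossed random effects, random slopes, or heteroscedastic residuals.
* Shedding-rate inference leans on the assumed 4.8 μm pre-label growth;
  errors in that constant shift all inferred shedding rates additively.
* Whether published per-compound analyses fit one joint model per week or
  separate pairwise models is not always documented; the joint fit is the
  natural reading of week-level modelling and is what `build_report()`
  does, but `fit_random_intercept()` accepts any subset of a week if the
  pairwise variant is wanted.
* Image analysis is out of scope: qualitative flags enter as booleans,
  distances as measured tables.
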