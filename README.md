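# rosrenew

Analysis of stripe-based (pulse-chase) screens of **rod photoreceptor outer
segment (ROS) renewal** in larval zebrafish.

The ROS is a stacked-disc cilium that is renewed continuously: new discs are
added at the base while the retinal pigment epithelium phagocytoses old
material from the tip. A heat-shock-induced, membrane-tethered fluorescent
stripe acts as a pulse label: in a fish heat shocked at 6 dpf and fixed at
10 dpf, the distance from the ROS base to the stripe (D^G) is the growth
that occurred during the 4-day treatment window, and the distance from the
stripe to the tip (D^S) is the pre-label growth minus whatever was shed.
With pre-label growth at rate *r* over *t₁* days and a treatment window of
*t₂* days,

    D^G = g · t₂            (growth rate g)
    D^S = max(0, r·t₁ − s·t₂)   (shedding rate s)

`rosrenew` implements the full quantitative pipeline of such a screen for
users analysing per-rod measurement tables (or validating the design by
simulation):

* **Kinetics** — conversion between stripe distances and renewal rates,
  control benchmarks pooled at the fish level, percent-change arithmetic
  (`infer_rates()`, `expected_distances()`, `suppression_equivalent()`,
  `pool_controls()`, `percent_change()`).
* **Mixed model** — per-week random-intercept model (rods nested in fish,
  one fixed effect per treatment) estimated from scratch by profiled REML
  (`fit_random_intercept()`), with many-to-one contrasts
  (`contrast_control()`) and Satterthwaite degrees of freedom
  (`satterthwaite_df()`).
* **Dunnett comparisons** — single-step two-sided adjusted p-values for all
  compounds against the week-matched vehicle control, computed by seeded
  randomized quasi-Monte-Carlo under the multivariate t
  (`dunnett_adjust()`, `significance_tier()`).
* **Hit calling** — the dual biological (≥ 20 % vs. matched control) and
  statistical (p < 0.001, with 0.01 / 0.05 tiers) thresholds, same-target
  follow-up, qualitative at-least-one-image rules, and pathway tallies
  across five content areas (`build_report()`, `call_distance_hit()`,
  `qualitative_hit()`, `tally_by_pathway()`).
* **Synthetic screens** — a hierarchical generator (week baselines, fish
  intercepts, rod noise, unbalanced rod counts, ~30 % lethality, Bernoulli
  image flags) with a recorded ground truth (`simulate_screen()`).
* **I/O and CLI** — CSV table formats, YAML configuration, and the
  `rosscreen` command-line tool (`screen_cli()`,
  `system.file("scripts", "rosscreen", package = "rosrenew")`).

## Worked example

Simulate one screening week with six compounds — one growth promoter
(+34 % on the growth rate), one growth suppressor (−34 %), four nulls —
and run the full pipeline:

```r
library(rosrenew)

cfg <- simulation_config(n_weeks = 1, compounds_per_week = c(6, 6),
                         lethality_prob = 0, seed = 42)
eff <- compound_effects(
  c("etodolac-like", "null-1", "null-2", "aurora-like", "null-3", "null-4"),
  growth_multiplier = c(1.34, 1, 1, 0.66, 1, 1),
  target  = c("COX", "none", "none", "AURK", "none", "none"),
  pathway = c("Neuronal Signaling", "unannotated", "unannotated",
              "Cell Cycle", "unannotated", "unannotated"))
scr <- simulate_screen(cfg, eff)
rep <- build_report(scr$measurements, scr$annotations, scr$qualitative)
print(rep)
```

```
Renewal screen report: 6 compound(s), 0 lethal
  D^G (growth): 2 primary, 0 tiered, 0 same-target follow-up
  D^S (shedding): 0 primary, 0 tiered, 0 same-target follow-up
  qualitative hits: phagosome 0, mislocalization 0, CMZ 0
Control benchmark [growth]: mean 5.268 um (fish-level SD 0.409 um), 302 rods from 3 fish
  rod-level: mean 5.272 um, SD 1.097 um
Control benchmark [shed]: mean 3.691 um (fish-level SD 0.231 um), 223 rods from 3 fish
  rod-level: mean 3.677 um, SD 1.017 um
```

Both planted compounds — and only they — are recovered as primary hits:

```r
cm <- subset(rep$comparisons, metric == "growth",
             select = c(compound_id, percent_change, p_adj, tier))
cm$percent_change <- round_percent(cm$percent_change)
print(cm, row.names = FALSE, digits = 3)
```

```
   compound_id percent_change    p_adj tier
 etodolac-like             39 1.88e-05  ***
        null-1             13 1.08e-01   ns
        null-2              8 4.99e-01   ns
   aurora-like            -30 2.28e-04  ***
        null-3              8 5.04e-01   ns
        null-4              1 1.00e+00   ns
```

The estimated percent changes (+39 %, −30 %) scatter around the planted
±34 % because a week has only three fish per group — exactly the
uncertainty the mixed model propagates into the adjusted p-values. The
`***` tier marks p < 0.001 by Dunnett's comparison against the shared
weekly DMSO control.

The same pipeline runs from the shell:

```sh
rosscreen=$(Rscript -e 'cat(system.file("scripts", "rosscreen", package = "rosrenew"))')
$rosscreen kinetics --dg 5.01 --ds 3.40
# growth rate: 1.25 um/day
# shed rate: 0.35 um/day
$rosscreen simulate --out screen/ --seed 7 --weeks 2
$rosscreen call-hits --measurements screen/measurements.csv \
    --annotations screen/annotations.csv \
    --qualitative screen/qualitative.csv --out hits.csv
```

## Documentation

The methods vignette (`vignettes/renewal-screen-analysis.Rmd`) describes
the model, the estimation and multiple-comparison machinery, the
synthetic-data calibration, numerical choices, and known limitations.
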