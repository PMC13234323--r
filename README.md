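# sitr — Simulation and Analysis Engine for the Speeded Inference Task

`sitr` is a headless R implementation of the Speeded Inference Task (SIT),
a four-target, two-rule speeded decision paradigm for studying **error
awareness**: how often people notice their own mistakes, and how noticing
(or not) shapes subsequent behaviour. The package is aimed at
experimental-psychology and cognitive-neuroscience researchers who want to
pilot design variants of the paradigm, generate realistic synthetic data
for analysis-pipeline development, or score trial logs with the paradigm's
standard behavioural measures — all without a display, response pads, or
human participants.

## The task in brief

Four constant targets are category–colour pairings (e.g. a blue ball, a
green ice cream, a red chair, a yellow bird; the colour↔category
assignment is counterbalanced across participants, the spatial order is
fixed). Each trial shows two items, each a mixture of target features, and
two rules apply in strict hierarchy:

* **Rule 1** — if an item matches a target in *both* category and colour,
  choose that target.
* **Rule 2** — only if no item fully matches: choose the target whose
  category and colour are both absent from the stimulus.

Every well-formed stimulus contains exactly one fully-absent target (the
*lure*). On rule-1 trials, choosing the lure means rule 2 was applied
although rule 1 took precedence — a *rule-2 misapplication*, the
paradigm's signature (and rarely detected) error source. After each
response, participants rate their own decision ("Was the chosen target
correct?" — yes / maybe yes / maybe not / no), which yields trial-wise
error-awareness measures.

Speed pressure comes from an adaptive response deadline: with windowed
accuracy `a` over the last 16 trials and timeout threshold `t` (start:
2000 ms),

```
t ← 1.1 t   if a < 0.60
t ← 0.9 t   if a > 0.90        (unchanged for 0.60 ≤ a ≤ 0.90)
```

Trials slower than `t` become timeouts; the software then auto-selects a
target drawn without replacement from a balanced pool (eight targets, each
twice, refilled when empty). Correct responses earn 10 points, correct
self-evaluations 3.

The analysis suite computes the paradigm's standard measures: response
rates (correct/error/timeout), error and correct detection rates
(detected = rated "no"/"maybe not"), rule-wise splits, post-error slowing
(PES) versus post-correct slowing (PCS) with an Augmented Dickey-Fuller
stationarity gate choosing between the traditional and the matched
(robust) estimator, post-error/post-correct accuracy (PEA/PCA),
post-timeout speeding, the ≥ 6-errors-per-type inclusion criterion, and
rule-misapplication classification.

## Worked example

Simulate one synthetic participant on the canonical 14-block × 32-trial,
50:50-rule design and score the log:

```r
library(sitr)
cfg <- study1_config(seed = 7)
log <- simulate_participant(cfg, agent_params(), seed = 7)

response_rates(log)$overall
#> # A tibble: 1 × 6
#>   n_trials correct_rate error_rate timeout_rate error_detection_rate
#>      <int>        <dbl>      <dbl>        <dbl>                <dbl>
#> 1      448        0.795      0.154       0.0513                0.725

split_by_rule(log)[, c("rule", "n_errors", "error_share", "detection_rate")]
#> # A tibble: 2 × 4
#>    rule n_errors error_share detection_rate
#>   <int>    <int>       <dbl>          <dbl>
#> 1     1       29       0.420          0.517
#> 2     2       40       0.580          0.875

post_error_measures(log)
#> <sit_post_error> PES 1326.4 ms, PCS 1285.0 ms (diff 41.4; traditional), PEA 0.831, PCA 0.795

classify_error_sources(log)$misapplication_share
#> [1] 0.7586207
```

Reading the output: about 15% of trials are errors and 5% timeouts — the
deadline controller holds accuracy inside its 60–90% band. Rule-2 errors
are detected far more often (87%) than rule-1 errors (52%), and ~76% of
rule-1 errors are lure choices (rule-2 misapplications). Responses after
errors are slower than after correct responses (PES − PCS ≈ 41 ms here),
while post-error accuracy is not worse — the characteristic behavioural
signature the synthetic agents are built to emulate.

Cohorts and the three-part rule-frequency design (50/25/75% rule 1):

```r
logs <- simulate_cohort(study2_config(seed = 1), default_cohort(20, seed = 1), seed = 2)
part_contrasts(logs, "1-5,6-10,11-15")$contrasts
```

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/sit.R plan     --study 1 --seed 7 --out plan.csv
Rscript inst/cli/sit.R simulate --study 2 --n-agents 20 --seed 1 --out logs/
Rscript inst/cli/sit.R analyze  --logs logs/ --parts 1-5,6-10,11-15 --out report/
```

## Acceptance script

`scripts/acceptance.R` re-runs the whole pipeline from scratch — builds
both canonical designs, simulates fresh cohorts against the adaptive
engine, and computes the full analysis suite (rates, rule-wise detection,
gated PES/PCS, PEA/PCA, post-timeout speeding, misapplication share, part
contrasts) — printing a summary and writing its JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Package layout

* `R/targets.R` — counterbalanced target sets, session configurations,
  balanced trial-plan generation
* `R/stimulus.R` — stimulus composition and the normative rule classifier
* `R/engine.R` — adaptive deadline, timeout pool, scoring, session loop
* `R/agents.R` — parametric synthetic participants and cohorts
* `R/analysis.R`, `R/adf.R` — behavioural measures and the stationarity gate
* `R/io.R` — trial-log CSV schema, JSON configs, cohort reports
* `vignettes/speeded-inference-task.Rmd` — the methods vignette (model,
  parameter choices, generator scope, numerical conventions)
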