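---
title: "The Speeded Inference Task engine: model, parameters, and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Speeded Inference Task engine: model, parameters, and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`sitr` implements the Speeded Inference Task (SIT) as a headless engine:
trial-plan generation under the paradigm's balancing constraints,
stimulus composition with normative rule semantics, the adaptive
response-deadline algorithm, parametric synthetic participants, and the
behavioural-analysis suite. This vignette documents the model, the
parameters that matter, what the synthetic-data generator does and does
not emulate, and the numerical conventions adopted where the paradigm's
published description leaves room.

## The task model

Four targets are category–colour pairings over the fixed spatial category
order *ball, ice cream, chair, bird* (left→right, mapped position-wise to
left-middle, left-index, right-index and right-middle fingers). Only the
colour assignment rotates across participants: `build_target_set(id)`
indexes the 24 colour bijections in lexicographic order of the colour
sequence (colours sorted alphabetically), so id 0 is the canonical blue
ball / green ice cream / red chair / yellow bird set. The spatial category
order is nowhere stated explicitly in the paradigm's description; the
order above follows the canonical illustration and is a fixed convention
here (the counterbalance id only rotates colours, never positions).

Each stimulus is an ordered pair of items, each a (category, colour)
mixture of target features plus non-semantic visual metadata (exemplar
1–7, scale 0.4–1.0, tilt ±40°) that is sampled, logged, and never used in
correctness logic. Two rules apply hierarchically:

* **Rule 1**: an item that matches a target in both features designates
  that target.
* **Rule 2**: only when rule 1 is inapplicable, the correct target is the
  one whose category *and* colour are absent from both items.

Two structural invariants are imposed on composed stimuli:

1. *Distinct item categories.* Allowing duplicate categories can create
   stimuli with zero or two fully-absent targets, contradicting the
   paradigm's property that every stimulus has exactly one such target.
   All published stimulus illustrations satisfy the constraint.
2. *Unique fully-absent (lure) target.* On rule-1 trials the second
   item's colour must differ from the matched target's colour — this is a
   derived consequence of lure uniqueness, not a free choice: if the
   second item carried the matched target's colour, two targets would be
   fully absent.

`stimulus_support()` materialises the feasible set by brute-force
enumeration of all 256 ordered feature assignments (classification plus
invariants); `compose_stimulus()` draws uniformly from that support, so
left/right placement and feature combinations are exactly equiprobable
within a (rule, target) cell. The classifier accepts arbitrary item
pairs and reports ill-formedness (`multiple_matches`, `no_unique_lure`)
as a value rather than an error, because log-replay must tolerate
malformed input.

## Trial-plan balancing

Within every block each target is the correct response exactly
`trials_per_block / 4` times, and the rule-1 count is exactly
`rule1_fraction × trials_per_block` (configurations violating integer
balance are rejected). The published constraints leave the joint
rule×target table free; we additionally balance it as evenly as
arithmetic allows (4 per cell in 50:50 blocks of 32; remainder cells
assigned at random). This strictly refines the stated constraints and
removes a potential confound between rule and response finger.

Randomisation is seeded per block (`seed + block_index`), so truncating
or extending a session leaves earlier blocks byte-identical. Exemplar
choice is uniform over the seven exemplars per category; whether the
original software balanced exemplars is unstated, and uniformity is the
neutral choice.

## Engine parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `threshold_start_ms` | 2000 | ms | published start value |
| `window_len` | 16 | trials | published cadence (twice per 32-trial block) |
| `acc_low`, `acc_high` | 0.60, 0.90 | — | published band; boundaries count as *inside* (the published wording is "below 60%" / "higher than 90%", i.e. strict) |
| `step_frac` | 0.10 | — | published ±10% step |
| `threshold_floor_ms` | 300 | ms | unpublished safety clamp; prevents degenerate all-timeout sessions with very fast responders |
| `rating_deadline_ms` | 4000 | ms | published |
| `highlight_ms`, `blank_ms` | 700, 1000 | ms | published trial course |
| `iti_range_ms` | 600–1000 | ms | published |
| `points_correct`, `points_eval` | 10, 3 | points | published scoring |

Two conventions deserve emphasis. First, timeouts count as *not correct*
in the adaptive window: timeouts are too-slow, hence incorrect, events,
and difficulty regulation only works if they depress windowed accuracy.
Second, windows are non-overlapping and block-aligned (the buffer resets
after each adjustment), matching the stated "adjusted after 16 trials,
thus twice per block"; whether the original window was sliding is
unstated, and the non-overlapping reading is the only one consistent
with a twice-per-block cadence.

Timeout displays come from a balanced pool of eight targets (each twice),
drawn without replacement and refilled on exhaustion. Pool draws are
independent of the trial's correct target, so the auto-chosen target is
correct at the pool's marginal rate; the paradigm states only that it
"could be correct or incorrect".

The virtual clock accumulates ITI, response (or threshold) time,
highlight, blank, and rating durations; it provides plausible log
timestamps but no analysis depends on it.

## Synthetic participants

Agents are parametric generative models, not mechanistic decision models
(drift-diffusion fitting is explicitly out of scope). Per trial:

* correctness is Bernoulli with a per-rule probability (defaults 0.84 /
  0.80 for rules 1 / 2, chosen so that under the adaptive deadline the
  correct/error/timeout mix lands near the reported ~73/18/9%);
* on rule-1 errors the lure is chosen with `p_misapply` (default 0.76,
  the reported misapplication share), otherwise the two remaining wrong
  targets are equiprobable; rule-2 errors are uniform over wrong targets;
* RT is log-normal — positive support and right skew typical of RT data;
  only means/SDs are published, so the family is a documented free choice
  — with arithmetic means 1400 ms (correct) and 1675 ms (error) and
  log-SD 0.25, scaled by `learning_slope^(block−1)` (default 0.99:
  improvement is RT decline and timeout avoidance, not accuracy drift);
* trials after an error gain `pes_delta_ms` (default +30 ms, matching the
  reported PES−PCS gap) and trials after a timeout gain
  `post_timeout_delta_ms` (default −60 ms; post-timeout RT adjustments
  are described as roughly twice the post-error ones);
* ratings are Bernoulli detections with kind-matched probabilities —
  0.36 for misapplied rule-1 errors, 0.89 for other rule-1 errors (the
  mixture reproduces the observed ~48.7% rule-1 detection at a 76%
  misapplication share), 0.87 for rule-2 errors, 0.982 confirmation of
  correct responses — with a 4% "maybe" substitution and 1% missing
  ratings. Awareness depends on error kind only, not on RT; an RT
  coupling is not quantified in the published data and is deliberately
  absent.

**Rule-frequency practice gain.** With frequency-invariant accuracies,
mixture arithmetic forces the error-detection rate *down* when rule-1
trials dominate (rule-1 errors, poorly detected, would swamp the error
pool), contradicting the observed pattern in the three-part design:
detection rises when rule 1 is rare, and returns to baseline — with a
*lower* error rate — when rule 1 dominates. The paradigm's own piloting
is reported to show lower error rates when most trials demand rule 1.
Agents therefore carry a one-sided practice gain: when the planned rule-1
fraction `f` of a block exceeds 0.5, the log-odds of answering rule-1
trials correctly increase by `freq_gain × (f − 0.5)`. The default
`freq_gain = 5` was calibrated once, at design time, against the
published part-wise descriptives (part-3 error-rate drop with detection
at baseline); detection (awareness) parameters remain kind-fixed
throughout. Setting `freq_gain = 0` recovers a frequency-invariant agent.

`default_cohort()` jitters probabilities on the log-odds scale (accuracy
SD 0.35, detection SD 0.7, misapplication SD 0.5 logits) and RT means
additively (SD 120 ms), chosen to resemble the reported between-subject
SDs (~5 percentage points for error rate, ~15 for detection, ~125 ms for
RT).

**What the generator does not emulate.** Trials are conditionally
independent given the agent: there is no trial-level autocorrelation
beyond the injected post-error/post-timeout increments, no fatigue, no
strategic speed–accuracy trade-off, and no perceptual difficulty (visual
metadata is decorative). A green simulation-based test therefore
establishes that the *pipeline* recovers the generative structure — not
that the generator captures every property of human data.

## Analysis conventions

* Detection collapses the four-point rating at analysis time: detected =
  "no"/"maybe not", undetected = "yes"/"maybe yes"; raw ratings stay in
  the log. Missing ratings are excluded from every detection denominator,
  and empty denominators yield `NA`, never 0.
* PES/PCS are the traditional estimators (mean RT of trials following
  errors / correct responses). Post-trials that are timeouts are excluded
  from RT means but count as *not correct* in PEA/PCA — the reported
  PEA deficit is attributed to timeouts after errors, which requires this
  convention. Post-trials that are themselves errors are included (only
  timeouts are stated as excluded); this is implemented as stated and
  flagged for sensitivity analysis.
* Pairs spanning block breaks are excluded (breaks disrupt RT
  continuity; the published description is silent). The engine's agents
  likewise reset their previous-trial carry-over at block starts.
* The robust PES variant is the matched pre/post difference per error
  episode (episodes with valid flanking responses in the same block);
  the exact formula behind the cited recommendation is not reproduced in
  the published description, so this is labelled an interpretation. It
  is selected when the Augmented Dickey-Fuller gate fails to reject the
  unit root at α = 0.05.
* The ADF test is implemented in-package (no unit-root package is
  available in the target environment): OLS Dickey-Fuller regression,
  AIC lag selection over 0..maxlag with Schwert's rule for maxlag (ties
  resolved toward fewer lags), MacKinnon (1994) response-surface
  p-values. It reproduces the reference implementation's statistic,
  chosen lag and p-value to ~10⁻⁶ on fixed test series. Constant series
  are stationary by convention and flagged.
* The inclusion criterion is inclusive: at least 6 detected *and* 6
  undetected errors.
* Part contrasts use paired t-tests against the baseline part with
  Cohen's d for paired designs; the omnibus repeated-measures ANOVA
  battery is intentionally out of scope (standard statistics software
  does that better).

## File formats

Trial logs are UTF-8 CSV with a schema-version comment line
(`# sit-trial-log v1`) and optional seed provenance; flags are 0/1, times
are milliseconds, missing values are empty fields. Session
configurations and cohort reports are JSON. YAML input was considered
and dropped — no YAML parser is available in the target environment, and
JSON is lossless for every configuration object. The command-line front
end (`inst/cli/sit.R`) exposes `plan`, `simulate` and `analyze` verbs
over the same functions; identical invocations are byte-identical in
output.

## Known limitations

* The engine models no display or input latency; RTs are generative,
  not psychophysically grounded.
* The agents' awareness model is deliberately minimal (kind-matched
  Bernoulli); confidence dynamics, RT–awareness coupling and
  evaluation-RT modelling are absent.
* The practice gain is a phenomenological calibration to reproduce the
  part-wise pattern, not a learning model.
* The threshold floor (300 ms) is an engineering guard with no published
  counterpart; analyses of extremely fast agents should treat behaviour
  near the floor with caution.
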