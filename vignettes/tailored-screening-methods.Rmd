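---
title: "Methods: tailored CRC screening messages and factorial trial analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tailored CRC screening messages and factorial trial analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crctailor)
```

## The problem and the models

Fecal occult blood testing (FOBT) is the standard population screening test
for colorectal cancer, and participation — requesting a kit and returning
it — is the behavioural bottleneck. `crctailor` implements the measurement,
message-generation and analysis machinery of an exploratory factorial trial
that crossed message *modality* (paper vs web) with message *type* (tailored
vs generic) and measured attitudes before and after the intervention.

Two behavioural models drive the design:

* the **Preventive Health Model (PHM)**, a continuum theory whose constructs
  (salience and coherence, perceived susceptibility, response efficacy,
  cancer worries, social influence — here augmented by self-efficacy and
  fecal aversion) predict the intention to screen; and
* the **Precaution Adoption Process Model (PAPM)**, a stage theory placing a
  person at one of five decision stages: never heard of FOBT, not
  considered, decided against, undecided, decided to act.

Tailoring joins them: a respondent's PAPM stage determines *which* PHM
factors their feedback leads with, and their own Likert answers determine
*which variant* of each factor's message they receive.

## Scale scoring

Each of the seven scales is a sum of 1–5 Likert items (4, 4, 2, 4, 2, 3 and
3 items respectively), so a k-item scale ranges over [k, 5k]. Reverse-coded
items enter as `6 − v`; this is the standard recode for a 1–5 response
format and is the only choice consistent with the published score ranges
(e.g. a 4-item scale with mean 16.0 is a sum, not a mean). Missing item
responses are an error rather than imputed: the analyses this package
reproduces were complete-case. Internal consistency uses Cronbach's alpha in
its variance form, `k/(k−1) · (1 − Σ σ²ᵢ / σ²ₜₒₜ)`, computed on whatever
(recoded) matrix it is given; the registry records the instrument's reported
alphas as metadata but the package makes no claim to reproduce them, since
the timepoint behind each published value is not recorded.

One registry choice deserves a note: the instrument flags *two* social
influence statements as tailoring statements. A message library keys one
variant set per factor to one statement, so the registry designates the
first flagged statement (immediate family) and records the ambiguity in the
resource file.

## Tailoring rules

`priority_factors()` maps each PAPM stage to the two PHM factors most
strongly associated with movement out of that stage (susceptibility and
response efficacy for "not considered", response efficacy and self-efficacy
for "decided to act", and so on). Those two factors form chunk 1 of the
bundle — the primacy position — and the remaining four tailorable factors
form chunk 2 in instrument listing order (the source material does not
specify a chunk-2 order, so a fixed, documented order was chosen for
reproducibility).

Within chunk 1 the package presents a reinforcing-tone message before a
motivating one, with ties keeping the rule's order. This is a deliberate
design choice: the published worked example opens with the respondent's
screening-consistent belief ("you believe that colon cancer screening is
effective — you're right") before correcting the inconsistent one, and
leading with affirmation before correction is the natural reading of a
reinforce-then-motivate message strategy. With both chunk-1 responses at the
same tone the rule order is preserved, so the choice only affects
mixed-tone respondents.

Variant selection uses the raw response to the factor's designated tailoring
statement, not the scale total — variants are written against agreement
levels of a single statement. Fecal aversion's tailoring statement is itself
reverse keyed (agreeing that sampling is "distasteful" is
screening-inconsistent), so its response is direction-corrected through
`6 − v` before lookup; screening-consistent answers therefore always receive
reinforcing tone, which the tone-monotonicity validation enforces for every
factor. Personalization supports exactly the tokens `[Name]` and `[age]`;
any other bracketed token is an error, and an assembled bundle is checked to
contain no brackets at all.

Only the response-efficacy variants of the original library are published;
they ship verbatim. The other five factors' variants in the default library
are **synthetic** paraphrases assembled from the generic information
statements, marked as such in the resource file — replaceable content, not
ground truth. The original workflow hand-edited concatenated messages for
flow; the package instead concatenates deterministically (one message per
paragraph) and offers an `override` field for curated copy, because a manual
editing step cannot be reproduced.

## The analysis battery

**Chi-square.** Pearson's statistic with the Yates continuity correction
(`Σ (max(|O−E| − ½, 0))²/E`) on 2 × 2 tables, uncorrected otherwise. The
package applies the correction to all 2 × 2 trial comparisons: the
published movement analysis states it explicitly, and the published FOBT
statistics are only consistent with it. The published baseline comparability
tables (2 × 5 and 3 × 5) are only consistent with no correction, matching
the 2 × 2-only convention. The "returned" comparisons use full group sizes
(41/43 by modality, 42/42 by message) as denominators — not requesters —
again because only that choice reproduces the printed 0.0 and 2.4.

**One-way ANOVA and paired t.** Classical equal-variance decompositions via
base R's linear-model machinery. `groups_from_summary()` rebuilds group
samples with exact published means and SDs (a standardized equispaced grid
rescaled to the target moments); since the F statistic depends on the data
only through means, SDs and sizes, this reproduces the F implied by a
summary table — up to the table's own rounding, which is why the baseline
age check carries a ±0.05 tolerance around the printed 0.75.

**Mixed 2 × 2 × 2 ANOVA.** With a two-level within factor the mixed design
decomposes exactly into two one-way layouts on derived scores: the
within-subject terms (time, time × modality, time × message,
time × modality × message) are tests on the per-subject difference
`post − pre`, and the between-subject terms on the per-subject mean. Each
term is a 1-df Type III contrast on the four cell means
(`F = θ² / (MSE · Σ c²/n)` with sum-to-zero coefficients), pooled within-cell
variance as error, df (1, N − 4) — the published (1, 80) with 84
intervention participants in four unbalanced cells (22/21/20/21). Type III
with sum-to-zero coding is the only convention consistent with those dfs in
an unbalanced design. The test suite verifies equality (to 1e-8) with an
independent regression oracle (`car::Anova`, type III, on sum-coded fits)
across hundreds of random unbalanced datasets. Sphericity corrections are
moot with a two-level within factor, and no multiple-testing adjustment is
applied, matching the original analysis (two-sided α = .05 throughout).

Degenerate input: if all subjects have `post == pre` the time numerator and
error are both zero and the package reports F = 0 rather than 0/0.

## The cohort simulator

The simulator exists so the analysis battery can be exercised — and its
error rates calibrated — without access to the raw trial data.

**Latent model.** For each scale and participant, pre and post latent scores
are bivariate normal with the published per-cell pre-intervention means and
SDs, the published post SDs, and a pre–post correlation ρ. ρ is not
published; the default 0.6 is a typical attitude-scale test–retest value,
and it is a config field treated as a nuisance parameter — no analysis
depends on its value.

**Effect map.** Post-intervention shifts are additive on the latent scale
and are stored as sum-to-zero coded components (time, time × message,
time × modality × message; m = +1 tailored, o = +1 web), with non-zero
entries *only* for the terms the original study found significant: a time
main effect for every scale, time × message for perceived susceptibility
(+0.575) and self-efficacy (+0.375), and the three-way term for social
influence (+0.8) and salience and coherence (+0.45). The components are
projected from the published cell-mean shifts at package load, not
hard-coded. A fully saturated calibration (reproducing every published post
mean exactly) was rejected deliberately: the published non-significant terms
have small non-zero sample components (e.g. a −0.075 time × message
residual for response efficacy), and a generator that bakes those in turns
nominal nulls into true effects at any sample size large enough to power
the real ones — the calibrated significance pattern would be unrecoverable
by construction. The cost is that config-implied cell means differ slightly
from the published post means (e.g. web/tailored social influence 14.4
implied vs 14.9 printed); the simulator's mean-recovery test therefore
targets the config-implied mean, which is what the generator actually
promises.

**Discretization.** The latent score is rounded, clipped to [k, 5k], and
split into k item responses: an equal base value with the remainder added to
the leading items, then reverse-coded items are stored unreversed so that
scoring the survey back recovers the score exactly. Clipping is reported as
an attribute; at the default calibration it runs at about 2.7%, because
several published cell means sit only ~1.3–1.6 SD below a scale maximum
(salience and coherence, self-efficacy, response efficacy). That truncation
is a property of a normal latent meeting a bounded scale, not a bug; it
slightly shrinks extreme-cell means, which is why mean-recovery tolerances
allow a fraction of a point. A side effect of the even split is that items
within a scale are nearly equal for a given respondent, so Cronbach's alpha
on simulated data is near 1 — the simulator targets scale-level, not
item-level, covariance structure.

**Stages and FOBT.** Stage transitions are synthetic: the published figure
gives no counts, so the defaults are plausible matrices anchored to the
printed facts (a material fraction decided at both timepoints; control
movement essentially limited to never-heard → not-considered; tailored
arms move more). FOBT requests are Bernoulli by message type (34/42
tailored, 28/42 non-tailored — the per-arm probabilities are
under-determined by the printed margins); control participants count as
requesters exactly when their post stage is decided-to-act, mirroring the
original phase rule. Returns are Bernoulli given request (22/34, 14/28,
5/8 control) and return weeks are gamma(shape 2, mean 4.9 weeks) truncated
at 12 — giving P(≤ 6 weeks) ≈ 0.70 against the published 65.9% early
fraction.

## Calibration studies and their interpretation

`parameter_recovery_study()` repeatedly simulates and analyses. The package
uses it for two standing checks, run at sizes chosen to make the Monte Carlo
error negligible relative to the bands while keeping the default suite fast:

* **Type-I error.** Under `zero_effect_config()`, the time × message
  rejection rate over 1000 replicates at trial size must lie in the binomial
  95% band around .05, [0.037, 0.064].
* **Significance pattern.** Under the calibrated config at 200 subjects per
  cell (chosen so the smallest true component, +0.45 three-way for salience
  and coherence, has noncentrality z ≈ 6 and essentially full power), the
  four true-effect terms must reject in ≥ 95% of 200 replicates. For the
  terms the study found *null* (the response-efficacy and fecal-aversion
  three-way terms, and time × modality everywhere), a per-replicate
  non-rejection guarantee above 1 − α is impossible — an exact-null term
  rejects 5% of the time by design, so demanding ≥ 95% joint non-rejection
  is a coin flip on the Monte Carlo draw. The meaningful property of a null
  term is *calibration*, so the check requires its rejection rate to lie in
  the binomial 95% band around .05 for 200 replicates, [0.0198, 0.0802].

What these checks do and do not show: they validate the analysis code and
the generator's effect structure against each other at scale; they do not
reproduce the original F values (impossible without the raw data, and
explicitly not a goal), and passing them on synthetic cohorts says nothing
about features the generator does not model — item-level covariance,
floor/ceiling response styles, missingness, or correlated stage-and-score
dynamics.

## Numerical and formatting conventions

* Percentages print half-up to one decimal (`104/119 → 87.4`), matching
  every published flow percentage checked; base R's banker's rounding would
  differ on exact halves.
* FOBT cut-offs are inclusive: week 6.0 is early, week 12.0 is late. The
  source states the cut-off without specifying the side; the boundary is
  fixed, documented and tested.
* Randomization sorts ids before assignment, so allocation is a function of
  the id *set* and the seed; balance is exact to within one participant.
* All simulator randomness flows from a single integer seed; identical
  config and seed give byte-identical datasets.

## Known limitations

* The default message library outside response efficacy is placeholder
  content; substantive use requires a curated library
  (`read_message_library()` + `validate_library()`).
* The simulator's stage process and its scale process are independent given
  arm, which is weaker than reality (stage movement surely correlates with
  attitude change).
* Snowball recruits, which broke strict randomization in the original trial,
  are not modelled as a distinct inflow in the simulator; the funnel
  accounting records them but simulated cohorts are fully randomized.
* Sum scoring weights every item equally; no factor-analytic weighting is
  offered (or needed for reproduction).
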