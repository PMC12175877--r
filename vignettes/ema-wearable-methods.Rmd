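---
title: "Methods: simulating and analysing smartphone EMA with wearable sleep and activity data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing smartphone EMA with wearable sleep and activity data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emawear)
```

## The study design the package models

The package targets a common digital-phenotyping design for adolescent
depression: a two-week protocol in which participants (cases with major
depressive disorder and unaffected controls) answer a smartphone check-in
twice a day and wear an activity tracker throughout. Each check-in presents
8 slider items scored 0–100 — five worded around mood (sadness,
irritability, anhedonia, energy, appetite) and three around anxiety
(tension, nervousness, worry) — inside two prompt windows, one in the
morning and one in the afternoon/evening. Once a week an afternoon check-in
additionally offers a 12-item checklist of stressful life events. The
wearable contributes a per-participant sleep log (onset/offset plus
deep/light/REM/wake stage segments) and minute-level step counts.

Three analysis questions structure the pipeline: was the protocol feasible
(compliance accounting); how severe and variable are symptoms over time
(descriptive and variability statistics per group and item); and what
predicts symptom severity (a registry of linear mixed-effects models with
lagged mood, stress, sleep and activity terms).

## The synthetic cohort generator

No participant-level data are distributed with this design, so the
generator is a first-class module: it emulates the study's statistical
structure well enough that every downstream stage — parsers, statistics,
models — can be tested against known ground truth.

**Response model.** For participant $i$, item $j$ and prompt $t$ the latent
score is

$$y_{ijt} = \mu_{gj} + b_{ij} + \delta_{g}(t) + s_{g}(w_t) + e_{ijt},$$

truncated to the slider range $[0, 100]$ and rounded. $b_{ij}$ is a
person-level intercept with a one-factor structure across items (loading
`item_corr_between`, default 0.7), so a generally severe participant is
severe on all items; $e_{ijt}$ is stationary AR(1) noise on the ordered
prompt sequence (lag-1 correlation `ar1_rho`, default 0.3) composed of a
check-in-shared component (`item_corr_within`, default 0.4 of the within
variance) and an item-specific component. $\delta_g(t)$ is a case-only
diurnal contrast (`diurnal_effect_mdd`, default 2.5 score units AM−PM,
applied as ±half) and $s_g(w_t)$ a stress-week contrast (`stress_effect`,
default 3 units in weeks with at least one checklist event). Control item
responses are additionally zero-inflated (`zero_inflation_ctrl`, default
0.7), reflecting the large floor mass healthy adolescents show on symptom
sliders.

**Calibration.** The configured item means are *marginal* means. Both
contrasts are centered (e.g. stress contributes
$e\,(S_w - p_s)$ with $p_s = 1 - e^{-\text{rate}}$), and the latent mean of
each group × item cell is moment-matched through the $[0,100]$ clipping
(and, for controls, the zero-inflation) by solving
$(1-\pi_0)\,\mathbb{E}[\mathrm{clip}(N(\mu_{\text{lat}}, \sigma_{\text{tot}}))] = \mu_{\text{target}}$
with a closed-form clipped-normal mean and root-finding. This is what makes
the generator's marginals track the configured targets closely enough for
2-standard-error calibration checks across seeds.

**Defaults.** Group sizes (23/13), duration (14 days), windows
(06:00–10:00, 16:00–22:00) and the ~8.4% miss rate mirror the emulated
design. Item means, total SDs and between-person variance shares per group
follow the published descriptive scale of such cohorts (case sum-score mean
≈ 282 of 800, control ≈ 47); the within/between split uses per-item
intraclass correlations ≈ 0.5–0.6. Sleep defaults give both groups a modal
onset hour of 23:00 but cases a wider onset SD (200 vs 120 minutes on the
minutes-from-noon axis), shorter main sleeps (370 vs 420 min TST) and many
more afternoon naps (0.57 vs 0.084 naps/day, 30–150 min in bed); with naps
included this yields case vs control all-sleep TST means near 275 vs 390
minutes and CoV of TST near 57% vs 28%. Daily step targets are 5828.64
(cases) vs 7088.47 (controls) with a lognormal person-level multiplier.
Missingness is applied after score generation, completely at random, since
nothing in the design identifies a missingness mechanism; check-in response
times are uniform within their window.

**Determinism.** Every participant × component stream (roster, EMA, sleep,
steps) draws from its own generator seeded by a hash of
`(seed, participant_id, component)`. Identical configs and seeds give
byte-identical serialized datasets, and adding participants does not
perturb existing streams.

**What the generator does *not* emulate.** Items are conditionally
Gaussian (clipped), not the lumpy slider distributions real adolescents
produce; missingness is never mood-reactive; there is no device non-wear,
time-zone travel, or Fitbit staging error; step counts have no
weekday/weekend structure. Passing recovery tests on this cohort therefore
shows the *estimators* are correct and calibrated under the assumed
structure — not that real data meet those assumptions.

## Compliance accounting

Compliance is defined against the schedule: `participants × days × 2`
prompts. A check-in counts toward the numerator only if its local clock
time falls in a window — half-open intervals `[06:00, 10:00)` and
`[16:00, 22:00)`, so 06:00 counts and 10:00 does not. Duplicates within the
same participant/day/window collapse to the earliest (the later ones are
logged); out-of-window check-ins are kept for modelling but never counted.
Study day indices are relative to each participant's first observed
check-in date, and all timestamps are treated as local wall-clock with no
time-zone arithmetic. With the canonical worked numbers — 923 observed of
1008 scheduled — the report shows 91.57% compliance, 13.50 unique
assessment days per participant (486/36) and 1.90 check-ins per participant
per day (923/486).

## Variability statistics

RMSSD uses consecutive *observed* check-ins; by default gaps from missed
prompts are ignored (an optional `max_gap_hours` breaks chains at long
gaps). CoV is SD/mean and is undefined (flagged `NA`) for zero means, which
genuinely occur in all-zero control series. Skewness is the unadjusted
moment coefficient $g_1 = m_3/m_2^{3/2}$; alternatives differ by $O(1/n)$
factors and nothing in the design picks one. The ICC comes from a one-way
random-intercept variance decomposition estimated by restricted maximum
likelihood — implemented as a profiled 1-parameter REML criterion solved by
root-finding on its stationarity condition, which is valid for unbalanced
participant counts, reduces exactly to the balanced ANOVA moment estimator
when interior, and truncates the between-person variance at zero on the
boundary. The reported within-person share is exactly 1 − ICC.

In the group × item table the pooled moments (mean, SD, range, skewness,
%>0) use all of a group's responses, while RMSSD and CoV are computed per
participant and averaged within group; whether a published table of this
kind pools or averages is typically not decidable from its text, so the
pooled CoV variant is available (`cov_mode = "pooled"`) and the mode in
effect is recorded in the output metadata footer.

## Sleep and activity features

A **nap** is an episode with time in bed strictly under 180 minutes;
such episodes carry no deep/light/REM breakdown (consumer trackers do not
stage short sleeps), so naps contribute to TST/TIB/TAB statistics and to
the CoV of TST but are excluded from stage statistics. TST for a staged
episode is the sum of non-wake stage minutes; TAB = TIB − TST holds
exactly. Stage percentages divide by total stage-classified
(deep+light+rem) minutes — published stage percentages are often internally
inconsistent with TST because of device rounding, so the denominator choice
is recorded in metadata rather than matched to any particular table.
Efficiency is the per-episode TST/TIB ratio averaged over episodes. Wake
bouts are wake segments ≥ 5 minutes within main sleeps. A *hypersomnia
night* is a main sleep with TST above a threshold the design leaves
undefined; the default is 600 minutes, exposed as `hypersomnia_min` and
documented as a convention. Onset/offset dispersion is summarised on the
minutes-from-noon axis (minutes since the preceding 12:00), which avoids
midnight wraparound; modes are clock-hour bins with ties broken toward the
smaller hour.

Step minutes inside any `[onset, offset)` sleep interval are recoded to 0
and flagged — in-bed movement is not ambulation. Masking is idempotent and
never increases a count. Daily totals are calendar-day sums of the masked
stream. For day-level joins, an episode belongs to the calendar date of its
*onset* (an episode starting after midnight is attributed to the previous
date); "previous night's sleep" for day $d$ is the main sleep of night
$d-1$, the longest if several.

## The model registry

EMA observations are nested: item responses within check-ins within days
within participants. After an intercept-only screen of candidate random
terms (single-term likelihood-ratio deletions on the REML fit), the
retained structure for item-level models is random intercepts for
participant, day-within-participant and item-type-within-participant;
time of day is treated as fixed-only thereafter. Nesting is encoded as
`participant:unit` interaction intercepts rather than crossed terms, and
each result records that convention.

The registry fits, in order: the unconditioned model; item score on MDD
with age, sex, item type and time of day; the same plus MDD × time-of-day
and MDD × item-type interactions; baseline PHQ-9 convergence; concurrent
mood ~ anxiety; plus lag-1 anxiety; mood on its own T-1..T-3 lags; weekly
stress (concurrent and one-week lagged together — lagged stress is missing
in week 1, so that model effectively conditions on week 2+); an ordinary
linear model of total stress counts on group; daily steps on MDD and score
on daily steps; TST and TIB on MDD (episode-level, random participant
intercept); nap counts and CoV of TST on MDD (one value per participant, so
ordinary linear models, although narratively these sit alongside the mixed
models); and next-day score on previous-night TST. Age and sex are
covariates throughout because the emulated design's groups differ on both.

Inference conventions: fixed-effect p-values and 95% CIs use the Wald
normal approximation (the appropriate degrees-of-freedom method for such
designs is genuinely ambiguous; the approximation is reported as such);
partial $\eta_p^2$ per fixed term comes from type-III F statistics with
Satterthwaite denominator df, via $(F \cdot df_1)/(F \cdot df_1 + df_2)$;
marginal/conditional $R^2$ use the variance-partition (Nakagawa)
definitions. Fits use REML except where models are compared by likelihood
ratio. Singular or non-converged fits are flagged, never silently dropped;
a zero-variance response short-circuits to a flagged degenerate result. A
model whose input table is absent (e.g. no wearable data) is reported with
an explanatory error while the registry continues.

## Numerical and degenerate-input conventions

Prompt windows are half-open `[start, end)`. RMSSD/CoV/skewness flag
undefined inputs with `NA` plus a warning instead of erroring. The ICC
root-finder brackets from a coarse log-scale optimum and falls back to the
boundary when the stationarity condition has no interior root. Sleep
parsing rejects overlapping episodes (naming the timestamps), inverted
intervals and unknown stage names; stage detail on a sub-180-minute episode
is discarded with a warning since naps are stage-free by definition.
Report CSVs round to 2 decimals and append `#`-commented metadata footers
(ICC estimator, CoV mode, hypersomnia threshold, window convention).

## Validation strategy and problem sizes

The suite checks each statistic against an independent brute-force oracle
(explicit loops for RMSSD/CoV/skewness on 1000 random series at 1e-12; the
balanced ANOVA moment estimator for the ICC at 1e-8, and an lme4 REML fit
as a second route on unbalanced data), rule application (nap boundary,
stage exclusion, step recoding) against serialized generator truth, and
estimator calibration by simulation at the design scale of 36 participants
× 28 prompts: 200 seeds for the type-I error of the group test under a
null effect and for CI coverage of an injected +35 sum-score effect, 100
seeds for sign recovery of the case-only diurnal interaction and for the
four group-direction contrasts (higher case sum scores, higher CoV of TST,
more naps, shorter TST). These replication counts keep the full suite
comfortably within a desktop run while leaving Monte-Carlo error well below
the tested margins.

## Known limitations

Beyond the generator simplifications listed above: the Wald-z p-values are
mildly anticonservative at 36 participants (the type-I band in the
calibration test reflects that); nap counts are modelled linearly although
counts are discrete; the stress checklist rides on observed PM check-ins,
so a fully missed week silently drops that week's stress covariate; and the
pipeline performs no multiple-testing correction across the registry, which
mirrors how such exploratory model suites are usually reported — readers
should treat the registry's p-values accordingly.
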