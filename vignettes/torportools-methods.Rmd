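---
title: "Detecting torpor bouts and arousals from skin temperature: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting torpor bouts and arousals from skin temperature: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(torportools)
library(dplyr)
```

torportools analyses hibernation records of heterothermic mammals — here
calibrated to captive big brown bats (*Eptesicus fuscus*) held at 8 °C under
two humidity treatments — in which each animal alternates multi-day torpor
bouts with brief, energetically expensive arousals to normothermy. The
package covers the full chain: a synthetic cohort generator, two independent
bout detectors (skin temperature and behaviour), a calibration procedure
that chooses the operating skin-temperature threshold, cohort-level
statistics, and a huddle-compaction index from infrared images.

## The detection model

Skin temperature (T_sk) is logged every 15 min at ±0.5 °C resolution. The
threshold detector declares an animal normothermic from the first sample of
a run of **at least two consecutive valid samples strictly above** the
threshold, and torpid from the first sample of a run of at least two
samples at or below it. Single-sample excursions never flip the state: at a
15-min cadence a one-sample spike is indistinguishable from sensor noise or
transient heating by a neighbour. "Above" is strict (>) and "below" is
at-or-below (≤); with 0.5 °C-quantized data any other convention is
ambiguous at the threshold itself. Intervals are half-open `[start, end)`.
The state before the first qualifying run belongs to a censored bout of the
initial state's kind; bouts touching a record edge or an invalid gap are
flagged censored and excluded from duration statistics (they are truncated,
so their durations are biased low).

The behavioural detector needs no threshold: any observed movement marks an
arousal, and an arousal ends once the animal has been motionless for longer
than the termination window (90 min by default). Movement bouts separated
by stillness shorter than that window merge into one arousal. We end the
arousal at the **last merged movement**, not at movement + 90 min: including
the stillness window would add a constant ~1.5 h to every duration, and the
window exists to terminate the event, not to describe it. Users who prefer
the other convention can set `end_rule = "movement_plus_gap"`; the choice is
exposed because observational studies differ on whether quiet rewarmed rest
belongs to the arousal.

## Threshold calibration

Thresholds from 13 to 27 °C are swept in 1 °C steps. Two criteria pick the
operating value:

1. **Frequency.** Total arousal count as a function of threshold is fitted
   with a continuous two-segment (breakpoint) regression,
   `y = b0 + b1 x + b2 (x − psi)+`, with `psi` found by grid search at
   0.1 °C resolution minimizing the residual sum of squares; the breakpoint
   is retained only if the two-segment model beats a single line in an
   F-test (2 extra parameters) at α = 0.05. Below the breakpoint, shallow
   heat excursions (warming by huddle-mates) inflate counts; above it the
   count is insensitive to the threshold. Thresholds at or above
   `ceiling(psi)` are frequency-valid.
2. **Duration.** Arousal durations at each threshold are compared with the
   behavioural reference by a many-to-one (Dunnett-type) test on
   square-root-transformed durations (the transform symmetrizes the
   right-skewed duration distribution). The repeated-measures structure is
   handled by subtracting per-animal means of the transformed values before
   the comparison, with the pooled-error degrees of freedom reduced by the
   number of animals minus one; the exact repeated-measures ANOVA for
   unbalanced per-animal bout counts is under-determined, and within-animal
   centering is the transparent approximation. Family-wise adjusted
   p-values integrate the exact many-to-one multivariate-t distribution
   with the unbalanced correlation structure (`mvtnorm`, seeded quasi-Monte
   Carlo, hence deterministic); a Bonferroni fallback is available.
   Thresholds whose comparison is non-significant are duration-valid.

The selected threshold is the **minimum of the intersection** of the two
valid sets: among reliable thresholds, the lowest is the most sensitive to
shallow rewarming. Reporting per-segment regressions allocates points with
`x ≤ floor(psi)` to the left segment — an explicit convention, since the
point at the break belongs cleanly to neither side.

A note on uncertainty of `psi`: sweep counts at neighbouring thresholds
re-count the same events, so their errors are strongly positively
correlated. Simulating the faithful mechanism (a Poisson base count visible
across the grid plus Poisson shallow events visible only below their peaks)
puts the mean absolute error of `psi` below 0.5 °C at this study's count
scale; treating the counts as independent Poisson draws would overstate the
error several-fold.

## Cohort statistics

Bout durations (arousals in hours, torpor in days, square-root transformed)
are modelled with linear mixed models: humidity treatment and initial body
mass as fixed effects and a random intercept per animal, fitted by REML
with Satterthwaite degrees of freedom (lme4/lmerTest). Because animals are
removed while torpid, the final truncated torpor bout of each record is
omitted. Repeatability is `R = V_I / (V_I + V_Res)` from the
random-intercept model, with the individual effect tested by a
likelihood-ratio test of ML fits against χ² with 1 d.f. — the naive
reference, conservative for a boundary variance, reported as such. A
moment (one-way ANOVA, Searle's coefficient) estimator is available and is
exact on balanced data.

Per-animal totals use GLMs: Poisson (log link) for arousal and drink
counts, with the Pearson overdispersion statistic always reported; binomial
(logit link) on the (arousals-with-drinking, arousals-without) composite;
gamma with log link for overwinter mass loss on initial mass, treatment,
total drinks and total arousals — log link because mass loss is positive
and covariate effects are naturally multiplicative (the distribution family
is stated by the design; the link is not, so it is our choice). Welch's
t-test checks baseline mass balance; Cohen's d (pooled n−1 s.d., no
small-sample correction) grades treatment contrasts with the conventional
0.2/0.5/0.8 cut-points.

## Huddle-size index

The huddle-size index (HSI) is the percentage of image area occupied by the
huddle in a 352×238-pixel binary mask — exact integer arithmetic, no
tolerance. The data contract starts at the mask: outlining huddles in
infrared frames is manual, and segmentation of raw video is out of scope.
Masks are scored blind: `randomize_blind()` produces a seeded random
presentation order with uninformative labels and a separate key.
Dual-observer agreement is quantified by Pearson correlation plus a Welch
check for systematic offset. The treatment contrast uses a quasi-Poisson
GLM (variance proportional to the mean, dispersion estimated), which is
well-defined for non-integer percentage responses.

## The synthetic cohort generator

The generator is first-class, tested code: it defines the study conditions
under which every downstream stage is validated. Defaults reproduce the
target experiment: 10 humid + 9 dry bats, 110 days, 8 °C ambient, 15-min
sampling, 0.5 °C quantization.

* **Bout-length law.** Torpor and arousal durations are shifted gammas:
  torpor = 0.5 d + gamma(shape 4), arousal = 60 min + gamma(shape 1.3),
  scaled so the means equal the configured values (8.3/7.9 days and
  134/106 min by treatment). Gammas are strictly positive and right-skewed;
  the shifts guarantee every event is long enough to be physically
  expressible at the logger cadence, since a sub-30-min "arousal" could
  never satisfy the two-reading rule.
* **Individual differences.** Each bat carries log-normal duration
  multipliers (mean-corrected so cohort means stay at the configured
  values) with s.d. 0.12 (arousal) and 0.10 (torpor) on the log scale —
  the dispersion scale at which a ~28-min treatment difference in arousal
  duration is detectable at the reported significance with 19 animals, and
  which yields positive repeatability.
* **Trace shape.** Torpid plateau at ambient + 1 °C; exponential-approach
  rewarming with initial rate 1.0 °C/min and cooling at 0.5 °C/min (no
  rates are reported for this system; these sit in the range typical of
  small vespertilionid bats and are config parameters, not inferences);
  normothermic plateau at 30 °C with ±0.5 °C uniform jitter, which keeps
  the plateau unambiguously above the 20 °C operating threshold. With the
  default rates the detector's measured duration exceeds the true arousal
  duration by the difference of the down- and up-crossing times, about one
  sample interval — the closed-form crossing times are asserted in tests.
* **Artifacts.** Three classes, at rates derived from the reconciliation
  counts of the target study (per 100 bat-days: heating 1.3, shallow
  heating 4.6, sub-threshold movement 1.1): heating artifacts push T_sk
  above 20 °C for ≥2 samples (peak ≤ 23.2 °C) with no movement — the
  threshold detector over-counts; sub-threshold movements add motion whose
  T_sk response peaks at 11.3–18.6 °C — the behavioural detector
  over-counts; shallow heating bumps (same physics as heating, peaks below
  18.6 °C) touch neither detector at 20 °C but inflate low-threshold sweep
  counts, creating the breakpoint. Placement avoids true arousals by a
  2-h margin; an artifact that cannot be placed is skipped and logged.
  Loggers are shed mid-study with probability 0.3 and fail outright with
  probability 0.1, truncating T_sk validity while behavioural records
  continue.
* **Drinking and mass.** Each completed arousal includes drinking with
  probability 0.5 (humid) / 0.85 (dry); drinking arousals add
  1 + Poisson(0.3 / 0.7) dish visits. These reproduce the observed per-bat
  drink-count ranges (4–12 and 10–28); the study's prose "52% higher"
  conflicts with its own ranges, and the ranges win. Initial masses are
  uniform on 22.4–29.5 g; mass loss is (−17.8 + 0.93 × initial mass) g —
  the line through the reported extremes (3.0 g at 22.4 g, 9.6 g at
  29.5 g) — times gamma noise with CV 0.12.
* **Huddle masks.** Filled axis-aligned ellipses (single 4-connected
  region) with area fractions normal about 2.14% (humid) and 1.81% (dry),
  s.d. 0.11/0.19. The s.d. is calibrated to the reported effect size
  (d ≈ 2.1): back-computing s.d. from the printed standard errors assumes
  independent photos, but serial IR frames are positively autocorrelated,
  and the effect size pins the pooled dispersion directly.
* **Determinism.** All randomness flows from one root seed through
  per-treatment, per-bat substreams: identical configs are bit-identical,
  and enlarging one treatment's roster never perturbs the other animals.
* **Arousal cascades** (several bats rewarming together) are available as
  an option (`cascade_sync`): a shared latent onset schedule per treatment
  with per-bat jitter. Off by default — the target experiment describes
  cascades only qualitatively, and synchrony changes none of the per-bat
  statistics analysed here.

### What the generator does and does not emulate

It reproduces renewal-style bout alternation, logger quantization and loss,
detector-facing artifacts, treatment contrasts in drinking and huddle
area, and mass-loss structure. It does **not** model heat exchange,
evaporative water loss, humidity dynamics, social thermoregulation, or
within-huddle position. Tests passing on generated cohorts therefore
validate the *pipeline's* correctness and calibration under known truth;
they cannot certify behaviour on pathologies the generator omits (e.g.
drifting sensor bias, irregular sampling, partially shed loggers that
reattach).

One property worth knowing: cohort summaries of *interior* (uncensored)
bouts underestimate the process mean slightly (~4–6% for 8-day bouts in a
110-day window) because long bouts are more likely to touch a record edge
and be excluded. This is a property of any censored renewal record, not a
bug; the generator's configured means are process means.

## Numerical choices and degenerate inputs

* Breakpoint grid resolution 0.1 °C (matching the precision at which such
  breakpoints are conventionally reported); ties in RSS resolve to the
  lowest candidate; exact fits short-circuit the F-test rather than divide
  by a zero residual.
* Candidate breakpoints need ≥3 points per segment; fewer than 5 points is
  an error.
* The Dunnett integration uses a fixed internal seed, so adjusted p-values
  are reproducible to quasi-Monte-Carlo accuracy (~1e-4).
* Welch's test on two constant groups short-circuits to exact equality
  (t = 0, p = 1, or ±Inf, 0) instead of erroring; Cohen's d with zero
  pooled variance is an error unless the means are equal (then 0).
* Bats with zero arousals are excluded from the drinking-proportion model
  with a warning; all-zero counts or one-sided drinking outcomes raise
  separation warnings but do not halt.
* A singular mixed-model fit (zero between-bat variance) is reported via
  `glance()`, not treated as an error.
* The pipeline's stats stage records models that cannot be fitted on a
  given record (e.g. no complete torpor bout in a very short study) as
  notes in the report rather than failing the run.

## Problem sizes

The test-suite simulations use: 10,000 random quantized traces for the
detector/oracle equivalence; 200 replicates each for breakpoint recovery,
repeatability calibration (50 bats × 10 observations), and GLM effect
recovery (50 per group; n = 19 for the mass-loss regime); and 50 seeded
default cohorts (19 bats, 110 days) for end-to-end calibration stability.
These sizes give Monte-Carlo standard errors comfortably inside the
asserted tolerances while keeping the full suite fast on a single CPU.

## Known limitations

* The behavioural detector trusts the movement log; it has no access to
  video and cannot arbitrate ambiguous stillness (the optional
  T_sk-assisted reconciliation pass is deliberately off by default).
* The within-bat-centering approximation to the repeated-measures Dunnett
  comparison slightly miscounts error degrees of freedom for very
  unbalanced designs; with this study's bout counts the effect is
  negligible.
* Repeatability's χ²₁ likelihood-ratio reference is conservative at the
  variance boundary; a 50:50 mixture reference would be sharper.
* The gamma mass-loss model with four predictors on 19 animals is as
  fragile as it sounds; the package fits what the design specifies and
  reports it, but the simulation tests show only the initial-mass effect
  is reliably recoverable at that n.
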