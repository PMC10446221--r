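---
title: "Quality-of-breathing analysis for closed-loop ventilation trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality-of-breathing analysis for closed-loop ventilation trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventzones)
```

## The analysis problem

Closed-loop ventilation modes adjust minute ventilation, PEEP and FiO2
breath by breath from capnography and pulse oximetry. Trials of such
modes in postoperative cardiac-surgery patients score the *quality of
breathing* by classifying every recorded breath into one of three
predefined zones — optimal, acceptable, critical — from four
measurements: tidal volume normalised to predicted body weight (VT,
mL/kg PBW), maximum airway pressure (Pmax, cm H2O), end-tidal CO2
(etCO2, mmHg) and pulse-oximetry saturation (SpO2, %). The primary
endpoint is the per-subject proportion of breaths in the optimal zone
during the first three hours of postoperative ventilation, compared
between arms as a ratio of means under a non-inferiority design.

`ventzones` implements that pipeline end to end: reading and validating
breath-level exports, zone classification, per-subject endpoint
construction, arm-level inference, the design arithmetic, and a
synthetic trial generator for testing the whole chain.

## Zone classification

Each parameter maps to a band:

| Parameter | Critical | Acceptable | Optimal |
|---|---|---|---|
| VT, mL/kg PBW | > 12 | (8, 12] | <= 8 |
| Pmax, cm H2O | >= 36 | (30, 36) | <= 30 |
| etCO2, mmHg | < 25 or >= 51 | [25, 30) or (46, 51) | [30, 46] |
| SpO2, % | < 85 | [85, 93) or > 98 | [93, 98], or >= 93 if FiO2 <= 0.40 |

The breath-level combination rule: any available critical band makes
the breath critical; all four bands available and optimal makes it
optimal; all four available with none critical makes it acceptable.
With partial data, one available critical band still forces critical;
otherwise the zone is *missing* and the breath is excluded from the
zone denominators (its count is always reported).

The published band table prints integer boundaries that overlap (VT 8
appears in both the optimal and acceptable columns; Pmax 36 and etCO2
51 in both acceptable and critical) or leave gaps (Pmax 30–31). This
package resolves the seams once, as a deliberate design choice: the
optimal band is closed on boundaries it shares with the acceptable
band (VT 8; etCO2 30 and 46; SpO2 93 and 98), the critical band is
closed on boundaries it shares with the acceptable band (Pmax 36;
etCO2 51), and the Pmax gap is closed into the acceptable interval.
The resolution is generous at the optimal/acceptable seam and
conservative at the safety seam. Because the original study's
treatment of exact boundary values cannot be established, every seam
can be flipped through `zone_boundaries()`; boundary values are rare
in continuous data, so the choice has negligible numerical influence.

Two further choices: the SpO2 quality index gates only the hypoxemia
endpoint (SpO2 < 85 % counted only when the quality index exceeds
50 %), not zone classification; and a missing FiO2 does not trigger
the SpO2 optimal-extension clause — the relaxation requires positive
evidence that FiO2 is at or below 0.40.

## Endpoints

Per subject, within the window `[0, min(extubation, 3 h))`:

* **Proportion of breaths per zone** — zone count over classified
  (non-missing-zone) breaths. Keeping missing-zone breaths out of the
  denominator is what makes the three proportions sum to 1; the
  missing count is reported alongside, and the alternative denominator
  is available via `include_missing = TRUE`.
* **Proportion of time per zone** — each breath weighted by the time
  to the next breath; the final breath is weighted by 60/RR seconds
  (the reciprocal of the instantaneous rate), falling back to the
  median observed inter-breath interval, then to a 4 s nominal breath
  (15/min) if neither is available. With uniform breath durations this
  reduces exactly to the by-breaths proportion.
* **Hypoxemia** — hypoxemic breaths over quality-gated breaths. The
  denominator uses the gated count because the endpoint's own validity
  rule defines which SpO2 readings are interpretable.
* **Durations** — total postoperative ventilation (start of ICU
  ventilation to extubation) and weaning (sedation stop to
  extubation), in hours.
* **Binned series** — every parameter averaged over half-open 5-minute
  bins until extubation or 180 min, with minute ventilation derived as
  VT x RR / 1000 L/min. These are descriptive summaries; longitudinal
  mixed-model inference on them is out of scope.

Eligibility follows the trial's rules: subjects extubated before 90
minutes are per-protocol drop-outs (exactly 90 minutes is eligible),
crossovers (ventilated with the non-assigned sensor) are excluded from
the per-protocol set but analysed as treated in the ITT set, and
subjects with no recorded breaths are outside both.

## Inference

The primary contrast is the ratio of arm means of the optimal-zone
proportion (sidestream over mainstream), tested for non-inferiority
against a margin of 0.80 (a 20 % relative deficit) at one-sided
alpha 0.05. The default confidence interval is a linear-scale delta
method: for arm means $m_x, m_y$, SDs $s_x, s_y$ and sizes
$n_x, n_y$, the ratio $R = m_x/m_y$ has

$$\mathrm{SE}(R) = R\sqrt{\frac{s_x^2}{n_x m_x^2} +
\frac{s_y^2}{n_y m_y^2}},$$

with a one-sided lower bound $R - t_{1-\alpha,\nu}\,\mathrm{SE}$ using
a Welch–Satterthwaite $\nu$ built from the same two variance
components. Non-inferiority is declared when the lower bound exceeds
the margin; only then is superiority examined at the conventional
two-sided level (hierarchical closed testing). The linear-scale t
version is the default because, applied to the published summary
statistics (means 0.69 vs 0.79, SDs 0.26 vs 0.16, n 39/39), it
reproduces the published one-sided lower bound of 0.77, whereas the
log-scale delta method gives 0.78; both, plus a normal-quantile
variant and a percentile bootstrap, are selectable via `ni_config()`.

Secondary endpoints use two-sided versions of the same ratio (zone and
hypoxemia proportions), Welch mean differences (time proportions,
durations — equivalent to univariate linear regression on the arm
indicator), Wald odds ratios with the Haldane–Anscombe correction for
zero cells (binary endpoints; the published intervals for these appear
to be profile-likelihood, so only point estimates are comparable), and
Kaplan–Meier curves with the log-rank test (time-to-event, deaths
censored). Subgroup analyses split at the in-sample median and test
the arm-by-subgroup interaction as a z-test on the difference of log
mean ratios with delta-method standard errors.

## Design arithmetic

The design module reproduces the trial's sample-size reasoning: a 20 %
relative margin at an expected 69 % optimal-zone proportion is 13.8
(rounds to 14) percentage points; with SD 23 that is a standardized
effect of d = 0.6, and the smallest per-arm n whose exact noncentral-t
one-sided power reaches 0.80 at alpha 0.05 is 36, i.e. 72 subjects in
total. The exact noncentral-t power function is used rather than the
normal approximation, which yields only 70; the published total of 72
is consistent with the exact calculation. `simulate_power()`
cross-checks the analytic power by Monte Carlo, drawing both arms from
Normal(69, 23²) without truncation to [0, 100] — the design statement
itself presupposes the normal approximation — and applying the pooled
one-sided t-test of the mean difference against the absolute margin.

## The synthetic trial generator

No raw breath-level data from such trials are public, so the package
ships a generator whose defaults encode the study conditions: 39
subjects per arm; recording up to 6 h; lognormal extubation times with
medians 4.5 h (sidestream) and 4.2 h (mainstream) and log-SDs 0.63 /
0.50 back-solved from the published interquartile ranges; weaning
medians 1.2 / 1.7 h; between-subject optimal-proportion distributions
with means 0.69 / 0.79 and SDs 0.26 / 0.16 (Beta, truncated to
[0.02, 0.995]); a +2 mmHg mainstream etCO2 sensor offset; transient
first-hour sidestream effects (RR +2/min, VT −0.5 mL/kg, FiO2 +0.05);
hypoxemic-dip rates 0.33 % / 0.13 % of breaths; 1 % per-parameter
missingness and a 5 % SpO2 quality-index dropout rate.

Breath streams are AR(1) fluctuations (coefficient 0.9) around
per-subject setpoints drawn from between-subject distributions;
setpoints (VT 6.8 mL/kg, Pmax 18 cm H2O, etCO2 38 mmHg, SpO2 96.5 %,
FiO2 0.35, RR 14/min, PEEP 5 cm H2O) are standard values for sedated
postoperative cardiac-surgery patients under lung-protective
closed-loop ventilation. Non-optimal breaths arise from persistent
excursion episodes — etCO2 drifting into the acceptable or, in a
quarter of episodes, the critical band, with geometric sojourns of
mean length 60 breaths — rather than i.i.d. noise, so proportions by
breaths and by time differ realistically and between-subject
heterogeneity dominates the variance, matching the large published
between-subject SDs. Each subject's stationary excursion fraction is
one minus a true optimal proportion drawn from the arm's Beta
distribution, so arm-level means are directly interpretable and
recoverable. `calibrate_to_target()` closes the loop: it measures the
arm means through the actual classify-and-summarise pipeline over
replicate trials and nudges logit-scale offsets until both are within
0.03 of their targets.

What the generator does *not* emulate: the closed-loop controller's
actual adjustment law (its effects are represented statistically, not
mechanistically), physiological gas exchange, ventilator-specific
artefacts such as suctioning or disconnection episodes, and the true
(unknown) autocorrelation and missingness structure of real ventilator
exports. Passing recovery tests therefore demonstrates that the
pipeline is statistically faithful under the declared data model, not
that it has been validated against real recordings.

## Numerical choices and problem sizes

Determinism: every generator and simulation call is reproducible from
a single integer seed; identical configurations produce byte-identical
CSV output. Degenerate inputs are handled explicitly: empty breath
files abort the pipeline at the read stage; all-missing subjects get
null proportions with counts preserved; endpoints with no usable data
are dropped from the report rather than failing the run; a control-arm
mean of zero is an explicit undefined-ratio error.

The test suite exercises structural properties on reduced problem
sizes (a few subjects, 1–3 h horizons) and reserves the full study
conditions — calibration over 20 replicate trials and a 20-seed
parameter-recovery run at 39 subjects per arm, plus a 10,000-replicate
power simulation and a classifier/oracle sweep over more than 10^5
grid points — for the acceptance checks. On one CPU the full suite
runs in a few minutes.

## Worked example

```{r example, eval = FALSE}
cfg <- generator_config(seed = 1)
trial <- generate_trial(cfg)
res <- run_pipeline(trial$breaths, trial$subjects,
                    population = "itt", out_dir = "run1")
res$comparisons$p_breaths_optimal
cat(render_table3(res), sep = "\n")
```

## Known limitations

* The published analysis's exact CI construction for the mean ratio is
  not documented; the delta-t default reproduces its printed bound,
  but printed P values may differ in the third decimal.
* Odds-ratio intervals are Wald-based and can differ materially from
  profile-likelihood intervals in sparse tables.
* Breaths recorded during brief disconnections or suctioning are not
  filtered beyond the plausibility bounds; no such filter is defined
  for the trial's endpoints.
* The generator's within-subject dynamics are declared assumptions,
  not estimates from real ventilator exports.
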