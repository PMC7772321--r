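---
title: "Methods: rumen-reticular temperature dynamics at estrus and ovulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rumen-reticular temperature dynamics at estrus and ovulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rumentherm)
```

## The problem

Lactating dairy cows show a transient rise in core body temperature around
behavioral estrus and a characteristic dip around ovulation. Rumen-reticular
boluses measure core temperature hourly without handling the animal, and
collar-mounted automated activity monitors (AAM) flag estrus from a 0-100
activity index reported in 2-h blocks. If the thermal signature were sharp
enough, a temperature-based alert could time ovulation — and hence
insemination — better than activity alone.

`rumentherm` implements that analysis as a reusable, tested pipeline:

1. **Preprocessing** — water-intake transient removal, a rolling 5-day hourly
   baseline (mean and SD), and a standardized change score.
2. **Episodes** — AAM episode detection at the 35-index threshold,
   true/false-estrus classification from ovarian ultrasound, and ovulation
   timing from follicle disappearance.
3. **Thermal features** — positive area under the curve (AUC), maximum
   positive temperature change (PTC) and maximum negative temperature change
   (NTC) relative to baseline, over the estrus window and the ovulation
   window.
4. **Environment** — the temperature-humidity index (THI), period maxima and
   the heat-stress category.
5. **Alerting** — directional standardized-change alerts at 0.5-3 SD
   thresholds with interval statistics.
6. **Reporting** — event accounting and descriptive cell means.

Because no cow-level dataset is publicly deposited, the package ships a
**synthetic herd generator** with full ground truth; every downstream stage is
validated against what was injected.

## Signal model

Hourly rumen-reticular temperature for one cow is modeled as

$$
T(t) = \mu + A_c \cos\!\frac{2\pi (t - \phi)}{24} + \varepsilon_t
      + \sum_j D\, e^{-(t - t_j)/\tau} \mathbf{1}[t \ge t_j]
      + R\, \frac{1 - \cos\!\frac{2\pi (t - t_0)}{d}}{2}
      + V\, \frac{1 + \cos\!\frac{2\pi (t - t_{ov})}{w}}{2},
$$

with basal temperature $\mu$, a circadian sinusoid of amplitude $A_c$ and
early-evening acrophase $\phi$, i.i.d. Gaussian reading noise
$\varepsilon_t$, drinking transients of depth $D < 0$ recovering with time
constant $\tau$, a raised-cosine estrus rise of amplitude $R$ spanning the
activity episode $[t_0, t_0 + d]$, and a raised-cosine ovulation dip of
amplitude $V < 0$ and width $w$ centred on the true ovulation time. Raised
cosines were chosen because they are smooth, compactly supported, and their
sampled maximum equals the configured amplitude exactly whenever the episode
midpoint falls on the hourly grid (episodes are scheduled on the 2-h block
grid with even-hour durations, so it always does) — which is what makes exact
amplitude-recovery tests possible.

### Parameters, defaults and where they come from

| parameter | default | unit | provenance |
|---|---|---|---|
| basal temperature $\mu$ | 38.6 | degC | typical reticulorumen level |
| estrus rise $R$ | 0.55 | degC | reported mean positive change at estrus |
| ovulation dip $V$ | -0.60 | degC | reported mean negative change at ovulation |
| episode duration | median 12 | h | reported median duration split |
| peak activity | median 80 | index | reported median peak split |
| ovulation delay | uniform 24-32 | h after onset | reported alert-to-ovulation range |
| false-alert fraction | 0.13 | — | 29 of 225 alerted events |
| THI coupling | 0.4 | — | chosen so the high-THI rise (0.55 x 1.4 = 0.77 degC) sits at the reported high-THI, high-expression scale |
| circadian amplitude $A_c$ | 0.15 | degC | free parameter (not reported); visually realistic daily swing |
| noise SD | 0.12 | degC | free parameter within the plausible 0.1-0.3 degC band |
| drinking depth $D$, constant $\tau$, rate | -1.2 degC, 1 h, 0.5/d | | free parameters, see below |

On an episode whose onset falls in a reporting period (early morning /
morning / evening) with maximum THI above 72, the injected rise amplitude is
multiplied by $1 + \texttt{thi\_coupling}$. Keying the coupling on the
*onset's own period* (rather than any period of that day) makes the
generator's heat-stress contrast coincide with how THI categories are later
matched to sampling times, which is also how the analysis labels events.

### Drinking transients and the water correction

Drinking depresses reticulorumen temperature sharply with fast recovery. The
correction, whose commercial counterpart is unpublished, is a fully stated
heuristic: a reading at least 0.8 degC below the median of the previous 3
valid readings opens a transient; following readings stay flagged until one
returns to within 0.2 degC of that pre-drop median or 3 h elapse. Flagged
readings are marked invalid — temperatures are never modified — and the
operation is idempotent.

The generator's drinking defaults deserve a note. Cows drink many times a
day, but hourly averaging hides most bouts; the generator simulates only the
occasional bouts deep enough to register at hourly sampling. Depth -1.2 degC
with a 1-h recovery constant affects 2 readings per bout (about -1.2 and
-0.44 degC), and 0.5 detectable bouts per day keeps the trailing baseline
window (which requires 90 of 120 valid readings) essentially always defined
while still exercising the correction: on synthetic data it recovers over 90
% of truly affected readings. Deeper/slower settings flag 3-4 consecutive
readings per bout, which under the 25 % window-missingness rule would
mechanically exclude a large share of events — a property of the
flag-as-invalid design, discussed under *Limitations*.

## Baseline and standardization

The baseline at hour $t$ is the mean and **population** SD of valid readings
in the trailing half-open window $[t - 120\,\mathrm{h}, t)$: one value per
hour computed from the previous 5 days of readings, all hours pooled. The
half-open convention keeps the current reading out of its own baseline, so
the estrus rise cannot inflate its baseline at onset. Hour-of-day-matched
baselines (5 points per hour) were rejected as far noisier. The SD convention
is arbitrary; population was fixed and documented. A baseline needs at least
`min_window_points = 90` valid readings (75 % of 120, mirroring the 25 %
missingness tolerance), otherwise it is undefined and propagates as NA.

The standardized change is $z_t = (T_t - \bar{B}_t) / \max(s_t, 0.05)$; the
0.05 degC floor prevents unbounded scores on flat stretches.

A known, unresolved property: a long estrus rise (and the later dip) leaks
into the trailing window of *subsequent* hours, biasing their baseline
slightly upward. For a 0.55 degC x 12 h rise the leak at the episode peak is
about $0.55 \cdot 3 / 120 \approx 0.014$ degC, and about 0.028 degC across
the ovulation window once the full rise is inside the trailing window. The
amplitude-recovery tests tolerate this (it is well inside their 0.03 degC
band); it is documented rather than corrected because the field procedure
computes the baseline the same way.

## Feature windows and conventions

* **Estrus window**: AAM onset to end of estrus (onset + duration), both
  inclusive. **Ovulation window**: from the exam preceding disappearance of
  the dominant follicle to the exam confirming it, both inclusive.
* **Positive AUC**: trapezoidal rule on $\max(y, 0)$ with $x$ in hours to the
  nearest second. Clamping sample values *before* integration is exact,
  order-independent, and matches the worked convention of the source
  procedure; the alternative of discarding trapezoids with negative average
  was not adopted. A useful identity: the hourly trapezoid of a raised-cosine
  pulse equals its analytic integral $R\,d/2$ exactly, because the endpoint
  cosine sums telescope — the basis of a closed-form test.
* **PTC / NTC**: unclamped extrema of $y$; a window wholly below baseline
  yields a negative PTC rather than 0, preserving information.
* **Missingness**: expected slots are $\lfloor t_{end} - t_{start} \rfloor +
  1$; an event missing more than 25 % of slots in *either* window is excluded
  from summaries (flagged, never silently dropped).

## Episodes, ovulation timing, categories

Episodes are maximal runs of 2-h blocks at or above 35 index; interior quiet
gaps shorter than 3 blocks (6 h) are absorbed so single-block dropouts do not
split one estrus. The AAM alert time is the start of the first qualifying
block. True estrus requires a follicle > 15 mm and no corpus luteum > 20 mm
at the alert exam. The dominant follicle is tracked across exams by nearest
diameter within +/- 25 %; ovulation time is the midpoint of the
disappearance pair; persistence through 6 exams resolves to *late* (new CL at
day 7) or *failed* (none). Peak >= 80 index is high expression and duration
>= 12 h is long: the median value belongs to the upper class in both splits
(the duration tie rule mirrors the peak rule).

## Alerts and intervals

A temperature alert is two hourly readings in a row at or beyond a threshold
(>= +k SD for estrus alerts, <= -k SD for ovulation alerts, k in 0.5-3),
searched from 12 h before the AAM alert to 12 h after ovulation. Three or
more qualifying readings in a row are one alert, timed at the first reading —
the earliest actionable time; only the first alert per event, direction and
threshold feeds the interval statistics anyway. "Exceeded" is read as
inclusive; hourly z-scores essentially never land exactly on a cut.
Intervals are alert time minus anchor (AAM alert or ovulation), so
AAM-anchored intervals are bounded below by -12 h by construction, and
summaries use the sample-SD convention of descriptive statistics. Because a
pair qualifying at threshold $k$ qualifies at every threshold below it,
alerted events nest across thresholds and the percent alerted is
non-increasing — both are tested.

## What the tests do and do not show

The package's validation herds are:

* a **study-condition herd** of 100 cows x 2 episodes (about the source
  cohort's 102 cows, 2.2 episodes each, 225 alerted events) with all defaults,
  on which the qualitative orderings are checked: mean AUC and PTC larger at
  estrus than around ovulation, NTC more negative around ovulation, heat
  stress amplifying the estrus response of expressive cows, alert nesting,
  and interval bounds;
* a **recovery cohort** of 500 single-episode cows with rise 0.55 degC and
  noise SD 0.1, circadian and drinking terms disabled so that reading noise
  is the only stochastic term — exactly what the Monte-Carlo oracles model.
  The mean PTC at estrus and mean NTC around ovulation must match the
  oracle's expected extreme-value statistics within 0.03 degC. The oracles
  replicate the episode-duration and exam-bracketing geometry but not the
  pipeline (no baselines, no feature code), so they are an independent check
  on the max/min bias, including the small baseline-leak offset above;
* 1,000 random short series on which the positive AUC must agree with a
  1-second Riemann sum of the clamped interpolant within 1e-6.

Problem sizes were chosen so the mean of 500 events has a standard error
(~0.004 degC) well inside the 0.03 degC tolerance, and the whole suite runs
in a few minutes on one core.

Passing these tests shows the pipeline computes what it claims on data whose
generating process is known. It does **not** show that real herds behave like
the generator: real estrus rises are asymmetric and confounded with activity
and feeding; real drinking patterns are autocorrelated; missingness is not at
random; and the published group contrasts are least-squares means from
repeated-measures mixed models, which this package deliberately replaces with
descriptive cell means (see *Non-goals*). Synthetic and reported magnitudes
should therefore not be compared number-for-number.

## Numerical and degenerate-input choices

* Baseline SDs are computed from median-centred sums of squares, so a
  constant series returns an SD of exactly 0.
* `positive_auc` requires at least 2 points and strictly increasing times;
  single-point windows yield NA features and flag the event.
* Windows with zero expected slots are rejected as errors.
* Weather construction *guarantees* the heat-stress day fraction: cool-day
  temperatures are capped so THI < 72 even at 100 % humidity, hot days have
  their 15:00 reading floored so THI > 74.
* Ties: THI exactly 72 is "low" (the heat-stress class is strictly above
  72); peak exactly 80 is "high"; duration exactly 12 h is "long".
* All randomness flows from one configuration seed; reruns are
  byte-identical, which the manifest test checks.

## Known limitations

* Under default drinking parameters roughly 10 % of events end up excluded by
  the 25 % missingness rule (flag-as-invalid removal plus dropout bursts),
  more than the ~3 % that bursty sensor dropout alone would produce. The
  commercial correction evidently repairs rather than removes readings; since
  it is unpublished, removal with full disclosure was preferred over
  inventing an imputation.
* Late ovulations carry no ovulation window and are excluded from features;
  the generator's default late fraction is 0.
* No mixed models, P-values or backward elimination: group summaries are
  descriptive `n` / mean / SD / SE cells only.
* No simulation of milk yield, body condition or hormone profiles; no
  ROC-style evaluation of alerts against non-estrus days.

## Reproducing the headline quantities

`scripts/acceptance.R` regenerates a study-condition herd from a supplied
seed, runs the full pipeline, and writes the mean AUC/PTC/NTC per window, the
percent of events alerted at each threshold and direction, the ledger
percentages and the mean AAM-to-ovulation interval as JSON. See the README
for the exact invocation.
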