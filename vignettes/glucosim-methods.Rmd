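---
title: "Methods: an extended minimal model of daily glucose homeostasis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an extended minimal model of daily glucose homeostasis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

glucosim simulates whole-day plasma glucose dynamics in healthy,
normal-weight adults under two exogenous drivers — carbohydrate intake and
physical activity — and builds Monte Carlo virtual populations on top of
the single-subject simulator. This vignette is the package's own account of
the model, its assumptions, the parameters that matter, and the design
choices made where the science left the design open.

## The model

The core is a Bergman-type minimal model of the glucose--insulin loop,
extended with a Roy--Parker-style exercise subsystem. Nine states are
integrated per minute of the day:

$$
\begin{aligned}
\dot I &= -\eta\,(I - I_b) + \gamma\,\max(G - h, 0)\,t_{\mathrm{ref}} - I_e\\
\dot X &= -p_2 X + p_3 (I - I_b)\\
\dot G &= -p_1 (G - G_b) - X\,G
        + \tfrac{W}{Vol_G}\left(G_{\mathrm{prod}} - G_{\mathrm{gly}}\right)
        - \tfrac{W}{Vol_G}\,G_{\mathrm{up}} + d(t)
\end{aligned}
$$

where $I$ is plasma insulin (uU/mL), $X$ the remote insulin action
(1/min) and $G$ plasma glucose (mg/dL), with basal values $I_b$, $G_b$.
Exercise enters through four linear first-order filters driven by the
oxygen-consumption proxy $PVO_{2max}$:

$$
\begin{aligned}
\dot G_{\mathrm{prod}} &= a_1 PVO_{2max} - a_2 G_{\mathrm{prod}}, &
\dot G_{\mathrm{up}} &= a_3 PVO_{2max} - a_4 G_{\mathrm{up}},\\
\dot I_e &= a_5 PVO_{2max} - a_6 I_e, &
\dot{PVO}_{2max} &= -0.8\, PVO_{2max} + 0.8\,u_{\mathrm{eff}}
\end{aligned}
$$

$G_{\mathrm{prod}}$ and $G_{\mathrm{up}}$ are the exercise-induced hepatic
glucose production and peripheral uptake rates (mg/kg/min, bridged into
concentration units by $W/Vol_G$), and $I_e$ is the exercise-induced
insulin removal rate. Prolonged exercise depletes liver glycogen: the
integrated intensity $A$ accumulates at rate $u$ while activity lasts, and
once $A$ exceeds the critical threshold
$A_{TH}(u) = \max(-1.152\,u^2 + 87.471\,u,\, 0)$ the glycogenolysis
decline $G_{\mathrm{gly}}$ grows at rate $K$, reducing net hepatic output.
At rest $A$ is reset rapidly (time constant `a_reset` = 0.001 min — read
as an effectively instantaneous reset marking the start of glycogen
replenishment; the alternative reading of a slow decay is available by
configuring `a_reset`) and $G_{\mathrm{gly}}$ recovers with time constant
$T_1$.

Meals appear through a two-pool absorption model: each intake of `DGS`
grams of slowly absorbed and `DGF` grams of rapidly absorbed carbohydrate
contributes

$$
d(t) = \frac{1000\,\beta}{Vol_G}\left[
  DGS\,\tfrac{r_1 r_2}{r_2 - r_1}(e^{-r_1\tau} - e^{-r_2\tau})
+ DGF\,\tfrac{r_3 r_4}{r_4 - r_3}(e^{-r_3\tau} - e^{-r_4\tau})\right]
$$

with $\tau$ the time since that intake. Each time kernel integrates to
exactly one, so one gram contributes $1000\beta/Vol_G$ mg/dL of total
appearance; the bioavailability multiplier $\beta$ defaults to 1. Exercise
intensity is expressed on a heart-rate scale, $u = 100\,HR/HR_{max}$, and
the metabolic equivalent of task developed at intensity $u$ is the fitted
Gaussian $MET(u) = a\,e^{-((u-b)/c)^2}$ with $a = 10.25$ MET,
$b = 89.26\%$, $c = 62.36\%$.

### Design choices the equations leave open

**The pancreatic release clock.** The release term $\gamma (G-h)\,t$ needs
a reference point for $t$; with absolute clock time it diverges over a
24-hour horizon. glucosim uses $t_{\mathrm{ref}}$ = minutes since the most
recent meal onset (zero before the first meal), together with the positive
part $\max(G-h,0)$ and a threshold $h$ that defaults to the subject's
basal glucose. This preserves the term's intent — a post-challenge
pancreatic response ramping with time — while making the fasted rest state
$(I_b, 0, G_b, 0, \ldots, 0)$ an exact equilibrium. Both $h$ and the
clock behavior are configurable through the parameter set.

**Intensity above basal.** A resting adult already consumes about 8% of
maximal oxygen uptake, and resting heart rate sits near 40% of maximum, so
feeding the raw heart-rate percentage into the exercise filters would
produce perpetual exercise fluxes and no rest equilibrium. The filters are
therefore driven by $u_{\mathrm{eff}} = \max(u - u_{\mathrm{basal}}, 0)$
with $u_{\mathrm{basal}} = 8$, and $A_{TH}$ is evaluated at
$u_{\mathrm{eff}}$. Between scheduled activities the intensity trace sits
at $u_{\mathrm{basal}}$, i.e. $u_{\mathrm{eff}} = 0$.

**The MET floor.** The fitted Gaussian evaluates to about 1.32 MET at
$u = 0$ and crosses the 1.5 MET sedentary cutoff already at $u \approx
2.8\%$; at the basal intensity of 8% it reads about 1.88 MET. Two
consequences are documented rather than hidden: (i) the trace-based
`active_hours` in a glycemic summary reports 24 h for a day that never
leaves basal intensity; (ii) lifestyle classification of schedules
(`schedule_active_hours()`) therefore counts only scheduled activity
periods above the cutoff, treating non-event time as rest — the same
per-activity bookkeeping used for the observed 20-person records, which
classify 7 active and 13 sedentary under the 8-hour rule.

## Parameters

The equations above are published without numeric values for the core
rates; glucosim ships a complete default set
(`model_params()`, mirrored in `inst/extdata/default_params.yaml`) chosen
once, as follows, and overridable individually or by YAML config:

* Exercise subsystem — the Roy--Parker constants as published:
  $a_1 = 0.00158$, $a_2 = 0.056$, $a_3 = 0.00195$, $a_4 = 0.0485$,
  $a_5 = 0.00125$, $a_6 = 0.075$, $K = 0.0108$ mg/kg/min per min,
  $T_1 = 6$ min. Net peripheral uptake exceeds the hepatic production gain
  ($a_3/a_4 > a_1/a_2$), so sustained activity lowers glucose.
* Glucose--insulin core — classical minimal-model magnitudes calibrated to
  normal physiology: $p_1 = 0.0317$, $p_2 = 0.03$, $p_3 = 3\times10^{-5}$
  (insulin sensitivity $p_3/p_2 = 10^{-3}$ per uU/mL, mid-range for
  healthy adults), $\eta = 0.2659$, $\gamma = 0.005$, $I_b = 15$ uU/mL,
  $Vol_G = 1.67$ dL/kg of body weight. The calibration targets were
  qualitative descriptions of healthy behavior: a 75 g slow-carbohydrate
  meal peaking roughly 30 mg/dL above basal within the first hour,
  insulin peaking in the 30--50 uU/mL range, daily cohort traces
  oscillating in the 80--120 mg/dL normoglycemic band, and dips toward the
  70 mg/dL hypoglycemia line only under prolonged activity late in the
  day. The calibration was performed once, before freezing the test suite.
* Absorption — slow pool $r_1 = 0.006$, $r_2 = 0.009$ (appearance peak
  about 135 min post-intake), fast pool $r_3 = 0.02$, $r_4 = 0.03$ (peak
  about 41 min). The pairs must differ within each pool; the kernel is
  singular otherwise and the constructor refuses it.

## Numerical integration

The right-hand side is discontinuous at activity starts/stops (piecewise
constant $u$), at meal onsets (the pancreatic clock resets) and at
$A = A_{TH}$ (the glycogenolysis branch). Naive adaptive stepping across
such switches causes solver chatter, so `simulate_day()` integrates
segment by segment with `deSolve::lsoda` (stiff-capable; the $-A/0.001$
reset branch has a stiff eigenvalue of $-1000$/min): segment boundaries
are placed at every meal and activity edge, and within an active segment
the crossing time of $A$ — which grows linearly there — is located
analytically and the segment split, so every branch of the vector field is
smooth on the interval the solver sees. Output is resampled onto a uniform
1-minute grid; default tolerances are `rtol = atol = 1e-8`, and halving or
tightening them moves the glucose trace by well under 0.1 mg/dL on the
bundled example day. Glucose is floored at a small epsilon with a warning
recorded in the result metadata (the default parameterization never
triggers it). Degenerate inputs — overlapping activities, singular kernel
rates, non-finite states — error early with diagnostic messages.

## The virtual-population generator

`generate_patient()` samples in the dependency order gender/occupation
→ age, height → BMI → weight → (basal glucose, carbohydrate quantity):

* Each factor is drawn from a normal with the group's published mean and
  SD, truncated at ±3 SD and at physiological limits (age within 20--75 y,
  basal glucose within 60--130 mg/dL). The distribution family is the
  package's choice — only means and SDs are published. The ±3 SD
  truncation shrinks each SD by about 2.7% and leaves symmetric-truncation
  means unbiased; the age floor at 20 y truncates asymmetrically and
  raises the sampled age mean by roughly a year, which the tests check
  against the closed-form truncated-normal moments.
* Weight is derived as $BMI \times height^2$ from the BMI draw rather than
  sampled independently, so the BMI identity holds exactly for every
  patient. (For active women the published weight mean is about 2.9 kg
  above $BMI \times height^2$ at the group means; the identity wins.)
* Conditioning of glucose and carbohydrate intake on BMI is exposed as a
  linear mean shift per SD of BMI (`bmi_slope`), defaulting to zero, which
  reproduces the group marginals exactly.

`generate_schedule()` turns a patient into a day: 3--4 meals in
breakfast/lunch/(snack)/dinner windows patterned on the bundled
office-worker day, the daily carbohydrate total split across meals by a
Dirichlet draw (snack weighted smaller), a per-meal slow fraction from
Beta(9, 1) (most intakes being predominantly slow-absorbing), and five
activities, each starting within 3 h of a meal onset, with type, intensity
and duration drawn from the lifestyle's named-activity table: long
low-to-moderate walks (100--160 min at 25--45% HRmax) plus occasional
short runs for active patients; desk work and domestic chores (30--80 min
at 12--28%) for sedentary ones. Those intensities keep the active group's
oxygen-consumption trace spanning roughly 8--80% of maximum and the
sedentary group's within 8--30%, and they make the groups coherent with
the 8-hour classifier by construction: five long walks total about 10 h
above 1.5 MET, five sedentary activities about 4.5 h.

What the generator emulates is the *population structure* of the study
conditions — group-level factor distributions, meal frequency, activity
placement. What it does not emulate: intra-day correlation of appetite
and activity, day-to-day variability, stress and fatigue effects on
glycemia, overweight physiology (the model is explicitly limited to
normal weight), or sensor noise. Passing tests therefore certify the
simulator and sampling machinery, not predictive accuracy for any real
individual.

## Cohort analysis and the exercise contrast

`run_cohort()` simulates every patient twice — full model, and with the
exercise subsystem disabled (`no_exercise`), which provably reduces the
integrator to the three-state glucose--insulin core — and aggregates
group envelopes, the fraction of patient-minutes inside the 80--120 mg/dL
band ("large majority" is operationalized as ≥ 90%, a named argument),
and per-patient contrast metrics. Failed simulations are excluded and
reported, with the run declared invalid above a 5% failure cap.

One closed-loop subtlety is worth stating plainly: exercise lowers the
*daily mean* glucose of every simulated patient, and lowers the trace
pointwise during and immediately after activity, but it does **not**
dominate the no-exercise trace at every minute of the day. A dip in
glucose suppresses the glucose-dependent pancreatic release term, so the
meal following a long walk can peak a few mg/dL *higher* than in the
no-exercise counterfactual. The effect persists with the insulin-removal
pathway switched off ($a_5 = 0$) — it is a property of the feedback loop,
not of a particular flux — and the tests assert the properties that do
hold (during-activity dominance, positive mean contrast) rather than the
naive pointwise one. The contrast is markedly larger for active-profile
days than for sedentary ones, reproducing the qualitative
active-vs-sedentary comparison.

## Problem sizes and reproducibility

The test suite runs the statistical-recovery checks at 10,000 patients
per group, schedule-contract and coherence checks at tens of schedules,
and the cohort behavior check at 20 patients per group — sizes chosen so
the full suite completes in a few minutes while keeping Monte Carlo
bounds tight ($3\sigma/\sqrt{n}$ throughout). All randomness flows
through R's RNG: a deck generated with the same seed is bit-identical,
and `run_cohort()` derives one stream per patient from its seed, so
cohort aggregates are exactly reproducible. `scripts/acceptance.R`
re-derives the headline quantities (the MET peak and the recovered
population means) from a fresh seeded run.

## Known limitations

* Healthy, normal-weight adults only; no diabetic physiology, no insulin
  dosing, no counter-regulatory hormones beyond the implicit basal terms.
* Intensity is piecewise-constant within an activity; no warm-up ramps.
* The glycogenolysis decline is unbounded during very long uninterrupted
  activity; schedules of several consecutive hours at high intensity can
  push glucose to the hypoglycemic floor — physiologically not absurd,
  but outside the calibrated regime.
* Single-day horizon; the clock-time scheduling makes multi-day extension
  mechanical but it is deliberately out of scope.
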