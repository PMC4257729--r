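---
title: "The growsim energy-balance and growth model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The growsim energy-balance and growth model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growsim)
```

## The model in one page

`growsim` integrates three state variables daily over the life course:
fat mass FM (kg), fat-free mass FFM (kg), and height H (m). Body weight is
BW = FM + FFM and BMI = BW/H². Two ideas organise the dynamics:

1. **Canalization.** Growth is drawn toward exogenous age-, sex- and
   race-indexed reference curves: height-for-age H\*, BMI-for-age, fat mass
   index (FMI = FM/H²) for age, and a physical-activity budget. Height is
   tightly canalized — a deficit relative to H\* generates catch-up growth.
   BMI is only partially canalized: the *indicated* BMI is a weighted blend
   `BMI* = λ·BMI + (1−λ)·BMI_ref` (λ = 0.5 by default), so an individual's
   target trajectory partly follows where they actually are.

2. **Energy allocation.** Each day, intake EI is assigned to demands in
   strict priority order — maintenance first (BMR, activity, thermic effect
   of feeding, adaptive thermogenesis, turnover), then deposition of
   *essential* mass (growth along the indicated trajectory), and only then
   deposition of *extra* mass from surplus. On the supply side EI is used
   completely before *extra* stores (mass above the indicated trajectory)
   are catabolized, and essential stores are touched only for survival.

The composition of deposited or catabolized mixed mass follows the marginal
partition fraction derived from the FMI model (below), and an independent
homeostatic exchange relaxes the FM/FFM split toward the composition
indicated by the current BMI. That second mechanism is what distinguishes
this architecture from pure partitioning models: after any perturbation of
composition at constant weight, the fat fraction returns to its indicated
curve.

## Body composition: the FMI family and the partition fraction

The expected fat mass index at a given BMI is modelled as a power law
anchored at the reference:

FMI\*(BMI) = (FMI_ref + race term + individual offset + aging term) ·
(BMI/BMI_ref)^γ

with γ = 2 by default. The anchor property (FMI\* = FMI_ref exactly when
BMI = BMI_ref for a neutral subject of the reference race) holds by
construction, FMI\* is strictly increasing in BMI, and the marginal mass
partition has the closed form

p_FFM = 1 − dFMI\*/dBMI = 1 − γ·FMI\*(BMI)/BMI,

the fraction of a marginal body-weight change (at fixed height) deposited
as, or drawn from, fat-free mass. Heavier subjects therefore gain
proportionally more fat (p_FFM falls with BMI for γ > 1). At pathological
BMIs the fraction is clipped to [0.01, 0.99] with a warning so that flows
stay defined in extreme starvation or overfeeding experiments. The
classical Forbes partition `p_FFM = 10.4/(10.4 + FM)` is provided as
`forbes_partition()` for side-by-side comparison only.

The aging term is linear in biological age past 20 y (default slope
0.01 kg/m² per year), a modest drift that shifts adult composition toward
fat at roughly constant weight; the exchange is carried out by the
composition correction, not by net weight change.

Energy densities: fat mass is 39.5 MJ/kg (triglyceride); the marginal FFM
density rises linearly from 1 MJ/kg at zero FFM (infant lean tissue is
mostly water) and saturates at the adult 5 MJ/kg at 47 kg FFM, continuous
at the junction. `body_energy()` integrates this density exactly.

## Energy demand

**BMR** is assembled from tissue compartments: brain, liver, heart and
kidneys at age-indexed mass fractions of the indicated body weight
(responding to weight deviation with per-organ slopes, 0 for brain and 0.5
for the others), weighted by tissue-specific metabolic rates
(1.004, 0.837, 1.841, 1.841 MJ/kg/day respectively) and by an age-dependent
relative cellularity (rising through childhood to 1, declining after 30 y —
this is what makes BMR fall in the elderly at fixed composition); fat mass
and residual fat-free mass contribute at 0.019 and 0.045 MJ/kg/day. These
default profiles were set so that the reference adult male
(1.78 m, ~73 kg) has a total energy expenditure near 10.9 MJ/day and an
80 kg subject near 11.5 MJ/day, the standard magnitudes for this
population; all of them are configuration inputs.

**Physical activity** uses an age-indexed reference budget (MJ/day, peaking
at 2.8 for adult males, 2.4 for females, declining in old age), scaled by
the subject's activity factor. By default the activity *cost* also scales
with current body weight relative to the reference weight-for-age
(`pa_scales_with_weight`), as in locomotion-cost formulations: a heavier
body pays more for the same activity pattern. Without this term a constant
20% overfeed produces runaway weight gain, because no demand component
grows fast enough with the gained mass.

**Thermic effect of feeding** is a fixed fraction of intake (default 0.10).

**Growth** charges positive indicated-mass velocities at the tissue energy
density divided by a deposition efficiency (0.98 for fat, 0.85 for
fat-free); negative velocities demand nothing. Indicated velocities are the
per-day change of the indicated masses from aging and desired height
growth, with the current-BMI contribution assumed to run parallel (in
relative terms) to the reference curve — this is what makes a
reference-fed child track the reference BMI curve exactly rather than at
half its rate, while leaving an off-reference adult free of spurious
drift.

**Adaptive thermogenesis** applies the fractional gap between intake and
all other demand to BMR, scaled by a coefficient (default 0.25): energy
sparing under deficit, dissipation under surplus, zero in balance. The
demand against which the gap is measured includes catch-up growth needs by
default (`at_includes_growth`); the adjustment is instantaneous, with no
lag state.

**Turnover** is separable (MJ per kg body weight per day) but defaults to
zero, folded into the residual BMR rate.

## Allocation, stores, and the composition correction

Each step classifies mass into extra (above indicated) and essential
(composing the indicated trajectory) stores. The greedy ladder then runs:
maintenance is served from intake, then from extra stores (drained with the
same p_FFM mass split as deposition, falling back to whichever store has
capacity), then from essential stores; essential deposition is funded from
intake and extra stores only — never from essential stores, which would be
a self-catabolism loop; leftover intake deposits extra mass. Deposition
pays the efficiency surcharge; catabolism releases the full tissue energy.
The ledger closes exactly (residual below 1e-9 MJ/day in the
property tests).

The composition correction is computed before the ladder and folded into it
as supply or demand: the fat flow is −(FM − FMI\*(BMI)·H²)/τ per day
(τ = 60 days), mass-conserving (dFFM = −dFM), with the energy difference
between the shrinking and growing compartments entering the ledger. Sixty
days is fast enough to restore composition within months after a
perturbation, slow enough not to dominate daily dynamics.

If essential stores are pressed to below 20% of the indicated masses the
run halts with a starvation-collapse flag rather than producing unphysical
near-zero masses; the model does not represent mortality.

## Height: stunting and catch-up

Desired height velocity is `min(v_ref + max(0, H* − H)/τ_H, 4·v_ref)`:
reference velocity plus a gap-closing term (τ_H = 180 days), capped at four
times the age-specific reference velocity — the cap applies to the total
velocity. The desired velocity is multiplied by a stunting factor that is 1
at or above 85% of BMI-for-age (the boundary is inclusive) and ramps
linearly to 0 at 60%, and by the fraction of growth energy the allocation
actually funded. Because the reference velocity is zero after the adult
growth stop (20 y biological), any deficit remaining then is permanent.

## Integration and numerical choices

* Explicit Euler, dt = 1 day; demands are computed from the start-of-step
  state. Halving the step changes the 700-day adult scenario by under
  0.03 kg.
* FFM flows are priced at the step-midpoint marginal density (one extra
  allocation pass when the density would change within the step), so the
  whole-run energy audit closes against the body-energy integral to better
  than 1e-6 relative.
* All curve interpolation is shape-preserving monotone Hermite
  (`splinefun(method = "monoH.FC")`): knot values are reproduced exactly
  and velocities do not oscillate between knots. Evaluation outside the
  tabulated span is an error, never an extrapolation — silent clamping
  hides configuration mistakes in life-span runs.
* Equilibrium intake solves EI = demand by bisection to 1e-6 MJ/day (the
  equation is linear in EI through the thermic-effect term, so the solution
  matches the closed form the integrator uses internally).
* All calibrations (intake multiplier, height factor, one-year reduction
  intake) use bisection with tolerance 1e-3 of the sought quantity, and are
  verified by round-trip simulation.
* Percentile tracking inverts the energy balance per step. The solve is
  anchored at the full-growth balance intake and searches only on the side
  the target requires: near balance the BMI response to intake is almost
  flat (mass gain and height-growth funding offset each other), and an
  unanchored root-finder can land on a spurious growth-stalled root.
  Targets that would need negative intake run at zero and are flagged —
  that is exactly the stunting regime seen when tracking low BMI
  percentiles.
* Intake multipliers in scenarios apply to the *reference individual's*
  intake-for-age series, computed once from a reference run. Multiplying
  the perturbed state's own equilibrium intake instead would chase its own
  tail (a permanent fractional surplus on an ever-growing demand) and
  diverge.

## The synthetic reference generator

`synthetic_reference()` produces growth-chart-shaped curves so every
analysis runs without downloaded tables: a monotone height curve built by
integrating a positive parametric velocity (infancy deceleration, mid-
childhood plateau, single adolescent spurt — 13.5 y male, 11.5 y female —
smooth taper to zero at 20 y), rescaled to hit the configured adult height
exactly; a BMI template with the infancy peak, the adiposity-rebound
minimum in mid childhood and a rise to the adult value (23.0 male / 21.7
female), affinely rescaled; sex-specific FMI templates (adult anchors 4.3
and 6.2 kg/m²); and an activity budget. The male defaults put the
reference adult at 1.78 m and BMI 23 (about 73 kg), and an 80 kg
30-year-old at 21% fat with 11.5 MJ/day expenditure.

What the generator does *not* emulate: growth-chart percentile families
beyond the median (only the 50th percentile drives the model), survey-based
race offsets (the shipped height offsets and FMI race terms are small
synthetic placeholders, overridable from configuration), seasonal or
short-term intake variation, and measurement noise. Tests passing on these
curves therefore demonstrate the mechanics of canalization, allocation and
calibration — not agreement with any particular population's charts; real
LMS tables can be dropped in via `load_lms_table()` without touching other
parameters.

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| `lambda_bmi` | — | 0.5 | partial canalization of BMI; 1 = no pull to reference |
| `gamma` | — | 2 | FMI-vs-BMI elasticity; sets how fat-heavy weight change is |
| `age_slope` | kg/m²/yr | 0.01 | post-childhood composition drift toward fat |
| `rho_fm`, `rho_ffm_adult` | MJ/kg | 39.5, 5 | tissue energy densities (FFM saturates at 47 kg) |
| `tef_fraction` | — | 0.10 | thermic effect of feeding |
| `at_coefficient` | — | 0.25 | strength of adaptive thermogenesis on BMR |
| `dep_eff_fm`, `dep_eff_ffm` | — | 0.98, 0.85 | deposition efficiencies |
| `tau_height` | days | 180 | height gap-closing time constant |
| `catchup_cap` | — | 4 | max multiple of reference height velocity |
| `stunt_threshold`, `stunt_floor` | — | 0.85, 0.60 | BMI/reference ratios bounding the stunting ramp |
| `correction_tau` | days | 60 | composition-correction time constant |
| `dt` | days | 1 | integration step |

## Problem sizes used by the test-suite

The shipped tests exercise full-childhood runs (birth to 18 y, daily
steps), the 700-day adult over/underfeeding protocol, 10⁴ randomized
allocation states for the priority and conservation properties, and
calibration round-trips at ages 2–4 y; percentile tracking is verified over
ages 2–8 y. These spans were chosen as the smallest that exhibit each
behaviour of interest (complete growth, crash-and-recovery, stunting with
catch-up) — results are unchanged on longer spans.

## Known limitations

* No mortality, pregnancy, disease, or macronutrient resolution; the model
  targets dynamics from weeks to decades, not hours.
* The composition equations behind the FMI family were estimated (in the
  literature) on cross-sectional data for ages ~8–50; outside that range
  they are smooth extrapolations of the same form.
* Adaptive thermogenesis is instantaneous; architectures with a lagged AT
  state produce smoother expenditure trajectories under abrupt intake
  changes.
* Stunting evidence is thin; the 4× catch-up cap and the 85% threshold are
  the two empirically anchored features, and the ramp floor (60%) and τ_H
  are design choices.
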