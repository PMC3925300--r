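---
title: "An hourly agent-based model of medfly outbreak extirpation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An hourly agent-based model of medfly outbreak extirpation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medflysim)
```

## The problem

When *Ceratitis capitata* (the Mediterranean fruit fly) is detected in an area
where it is not established, regulators impose a quarantine and eradication
programme — sterile-male releases, bait sprays, fruit stripping, intensified
trapping — and must decide how long to keep it in place. The standard rule
keeps the quarantine for the time three complete insect generations would need
under local temperatures, computed by degree-day accumulation. That rule
tracks only development; it knows nothing about mortality, reproduction, or
the countermeasures themselves.

`medflysim` simulates the invading population directly: every female insect is
an agent that develops, reproduces, and dies hour by hour, driven by the
ambient temperature series, and the quantity of interest is the time to
extirpation `t_e` — the first day by whose end no agents remain alive. Because
small populations are dominated by chance, the simulator is stochastic and is
run in batches; `t_m` (mean time to extirpation) and `t_0.95` (time by which
95 % of runs have extirpated) summarize a batch, and are compared with the
degree-day quarantine length computed from the same temperature series.

## The agent model

The simulation advances in 1-hour steps. In each hour, each agent, in
insertion order, passes through four events **in this order**: (1) possible
stage transition, (2) daily reproduction, (3) natural death, (4)
human-induced death. Agents that die are removed at the end of the hour and
affect nothing thereafter. Eggs laid during an hour join the population at the
end of that hour and are first processed in the next one.

### Development

Stages are egg → larva → pupa → immature adult → mature adult. Development
follows thermal-unit accumulation: each degree above the stage's base
temperature `T_min_x` counts one degree-hour during the hour, and nothing
accrues above `T_max` (35 °C), where development halts. The tabulated thermal
constants `K_x` are day-degrees, so an individual's transition threshold is
`24 K_x` degree-hours, multiplied by `1 + γ z` with `z` standard normal
(`γ = 0.05` by default; redrawn if non-positive). Accumulation in excess of a
threshold carries into the next stage, which avoids a systematic truncation
bias of up to one hour per stage. Transition is boundary-inclusive
(`accumulated ≥ threshold`). The adult entry `K_a` is the thermal time from
emergence to sexual maturity.

An alternative development mode (`D_m = "hourly_probability"`) makes the
transition a per-hour Bernoulli event with probability
`min(1, degree-hours this hour / 24 K_x)`, which matches the thermal-unit
mode's mean duration at constant temperature but with geometric spread. The
thermal-unit mode is the default and is what all bundled analyses use.

### Reproduction

Once per simulation day (at the configurable reproduction hour, default the
day's first hour) each fertile mature female lays a clutch drawn from a
normal with mean `r` and variance `r_var`, rounded and clamped at zero
(`r_var = 3.57` is a literature-survey estimate). Because only females are
simulated, a fraction `female_fraction` (default 0.5) of the eggs are
instantiated as agents; the egg counter records all eggs, the birth counter
records instantiated agents. The sources do not state whether `r` counts all
eggs or daughter eggs, so the split is an explicit parameter rather than a
hidden assumption.

After countermeasures begin (day `t_S` after the first find), two things
change for reproduction. Each fertile mature female is tested once per day and
permanently loses fertility with probability `r_red` — the sterile-insect
effect of wild females mating with released sterile males. And eggs laid
after `t_S` are themselves infertile under the default `offspring_policy =
"sterile"` (host fruit is stripped from the area); setting `"inherit"` lets
them reproduce under the same rules as their parents, which is the relevant
switch when the question is establishment rather than eradication. Within the
daily event the clutch is laid before the sterilization test; the geometric
decay of the fertile pool is the same either way, but a female always gets
the reproduction opportunity of the day she is tested. A consequence worth
knowing: immature agents present before `t_S` remain fertile, so each one
that survives to maturity lays at least one clutch before its first
sterilization test. This sustains a (sterile) immature cohort well after
intervention and dominates the late population.

### Mortality

Two natural-mortality modes exist. The fixed mode applies a stage-specific
daily rate `M_x`. The temperature mode — used for all outbreak analyses —
evaluates a stage-group quadratic `μ(T) = a2 T² + a1 T + a0` each hour (eggs
and larvae share a curve; pupae and adults have their own) and adds it to
`M*_x`, the mortality at the optimum temperature band, clamping into
`[0, 1]`. The composition is additive because the quadratics are essentially
zero at their vertices (the pupal curve actually dips to −4.5×10⁻⁵ at its
20.7 °C vertex and is clamped), so `M*_x` is exactly the mortality at
optimum and the quadratic contributes the temperature penalty.

Daily probabilities are converted to hourly ones by survival compounding,
`p_h = 1 − (1 − M)^{1/24}`, so that 24 independent hourly trials reproduce
the daily rate exactly. The raw-exponent alternative `M^{1/24}` (available
behind `literal_hourly_exponent` for comparison) is larger than the daily
rate itself and cannot be what a daily mortality means; it is not used.

After `t_S`, adults (both substages) face an additional daily mortality `S`
from bait sprays, insecticide and intensified trapping, applied through the
same hourly compounding. Immature stages face no human-induced mortality, as
the field programmes did not target them.

### Caps and bookkeeping

A hard cap `N_m` (default 10⁶) bounds the live population; egg creation is
truncated at the cap and the run is flagged. Daily outputs record stage
counts at each day's end plus the day's min/mean/max temperature; runs end at
extirpation or when the temperature series is exhausted (reported as
censored, never as an extirpation time).

## Parameters

| Symbol | Units | Default | Varied range | Meaning |
|---|---|---|---|---|
| `T_min_e,l,p,a` | °C | midpoints of ranges | 9.6–12.5, 5.0–10.8, 9.1–13.8, 7.9–9.9 | base developmental temperature |
| `K_e,l,p,a` | day-degrees | midpoints | 27.27–33.80, 94.50–186.78, 123.96–169.49, 58.20–105.71 | thermal constants |
| `T_max` | °C | 35 | fixed | development halts above |
| `γ` | proportion | 0.05 | fixed | individual threshold SD |
| `M*_e,l,p,a` | /day | midpoints | 0.0198–0.12, 0.0068–0.0946, 0.0016–0.0465, 0.0245–0.134 | mortality at optimum |
| `r` | eggs/day | 20 | 5–35 | clutch mean |
| `r_var` | eggs² | 3.57 | fixed | clutch variance |
| `r_red` | /day | — | 0.5–1.0 | daily fertility-loss probability |
| `S` | /day | — | 0.005–0.05 | human-induced adult mortality |
| `t_S` | days | scenario | fixed per outbreak | delay to countermeasures |
| trap sensitivity | per life span | — | 0.02–0.03 | capture probability of the grid |

`default_param_ranges()` returns the varied ranges; batch designs sample them
by Latin hypercube.

## Temperatures

Simulations consume a contiguous hourly series (`read_hourly_csv()` reads
station exports and flags absent hours). Missing hours are filled from daily
min/max climatology using a two-term Fourier diurnal shape
`Γ(t) = 0.44 − 0.46 sin(ωt + 0.9) + 0.11 sin(2ωt + 0.9)` with `ω = π/12`
(24-hour period, solar noon at `t = 12`), interpolating
`T(t) = Γ T_x' + (1 − Γ) T_n'` where hours up to 05:00 pair with the previous
day's maximum and hours after 14:00 with the next day's minimum. At the
series edges the same day's extreme substitutes, confining edge bias to 11
hours. `Γ` is applied verbatim, not clamped: it exits `[0, 1]` by a small
margin over the day, so interpolated hours can overshoot the daily extremes
by up to a few per cent of the diurnal range; the tests record this bound
rather than hiding it.

The synthetic generator (`synthesize_fixture()`) emulates the diurnal cycle
and day-to-day weather jitter (Gaussian on each extreme, SD 0.8 °C), with an
optional cold snap that depresses both extremes for a run of days. It does
**not** emulate seasonal trends, multi-day weather systems, humidity, or
microclimate differences between a weather station and the outbreak site —
so passing tests demonstrate the model's internal consistency under
controlled forcing, not forecast accuracy for any real site.

## Initialization from trap captures

Flies caught in the first three days are an instantaneous index of the adult
population: with grid sensitivity `s` (0.02–0.03 for the standard urban
trapping density) and an even sex ratio, adult females are
`N_0 = finds / s × 0.5`. The stable stage distribution at 24 °C
(0.436 eggs, 0.403 larvae, 0.137 pupae, 0.012 immature adults, 0.012 mature
adults) then scales `N_0` up to the full population,
`N = round(N_0 / 0.012)`, and apportions it per stage, with the rounding
residual assigned to the largest compartment. For example three finds at 2 %
sensitivity give 75 females and 6 250 insects in all. Reference
reconstructions of the California outbreak series match these totals exactly
at 2 % sensitivity; at 3 % two of the published values sit ~1 % below the
clean computation (1 375 vs 1 389; 2 760 vs 2 778), an intermediate-rounding
residual we document rather than force.

Within a stage, each agent starts at a uniformly distributed fraction of its
own threshold — a point-mass at stage entry would synchronize molts across
the cohort and produce artificial waves. Mature adults start fertile. An
alternative stage distribution is supplied as data (`age_structure()`), not
as a separate code path.

## Validation against a Leslie matrix

Under constant temperature, fixed stage mortalities and constant fecundity,
the agent model should reproduce a deterministic age-structured projection.
The bundled harness (`make_fixture_scenario("leslie_constant")`) uses
constant 24 °C, classic laboratory stage parameters
(`T_min` = 9.6/5.0/13.8/7.9 °C, `K` = 33.4/186.8/124.0/80.5 day-degrees,
fixed daily mortalities 0/0.6/0.2/0.15) and 100 mature females, against a
40-age-class Leslie matrix with fecundities on the first row and survivals on
the subdiagonal.

Two derivation details matter:

* **Class map.** Stage boundaries fall at the continuous durations the
  thermal constants imply at 24 °C — egg 2.3 d, larva 9.8 d, pupa 12.2 d,
  5 d to maturity — so mature females occupy classes 30–40. Because the agent
  model switches stage (and therefore mortality) mid-day while integer age
  classes switch at day ends, a class whose day straddles a boundary gets a
  duration-weighted geometric-mean survival. Without this the larval
  proportions disagree by up to 0.085; with it the two methods agree within
  about 0.01 over the first ten days.
* **Fecundity.** The harness sets a low constant rate of 0.1 female eggs per
  mature female per day (`r = 1`, `female_fraction = 0.1`) for both methods.
  This keeps every stage populated while keeping births below adult deaths,
  so both trajectories decrease monotonically over the 20-day window and the
  comparison isolates development timing and mortality rather than being
  dominated by an egg influx. It is a validation design choice, not a
  biological estimate.

The deterministic projection truncates at class 40 (day 10 for the initial
cohort), so the comparison window is days 1–10.

## The experiment layer

* **Sampling.** `lhs_sample()` stratifies each parameter range into `n` equal
  strata with one uniform draw per stratum, independently permuted across
  columns (backed by the `lhs` package). The initial population enters the
  design through the trap-sensitivity column, preserving the coupling between
  detection efficiency and inferred population size.
* **Batches.** Run `i` uses seed `base_seed + i`, so batches are reproducible
  and trivially parallel. Failures are recorded per row, never fatal.
* **Statistics.** `t_m` averages extirpated runs only. `t_q` counts censored
  (series-exhausted) runs as *not yet extirpated*: it is the smallest time by
  which at least `q` of **all** runs have extirpated, and is `NA` when the
  batch cannot attain `q` — a conservative choice that never converts a
  censored run into a finite extirpation time.
* **PRCC.** All columns and the response are rank-transformed; each
  parameter's coefficient is the correlation of its residuals with the
  response's residuals after linearly removing the other ranked parameters,
  with statistic `t = ρ √((N − 2 − k)/(1 − ρ²))` on `N − 2 − k` degrees of
  freedom and raw two-sided p-values (no multiplicity correction, matching
  standard practice for this analysis). By default only extirpated runs feed
  the PRCC, since censored runs carry no observed `t_e`; `extirpated_only =
  FALSE` uses every finite response.
* **Degree-day comparator.** `degree_day_quarantine_length()` accumulates
  `max(0, T − T_min)/24` day-degrees per hour and reports the day the total
  first reaches `generations × K_generation`. `K_generation` defaults to the
  egg-to-ovipositing-adult sum of the stage thermal constants, as the exact
  regulatory constants vary by jurisdiction; the worked examples use
  340 day-degrees above 12 °C, a typical regulatory setting.

## The cold-snap mechanism

A freeze pushes the two methods in opposite directions: sub-zero hours
sharply raise mortality (the quadratics grow fast below the optimum), while
the same hours accumulate no degree-days, lengthening the computed
quarantine. The bundled `cold_snap` fixture (a 3-day, 17 °C depression at day
45 of the warm scenario) demonstrates an instructive subtlety: at that depth
and timing the extra mortality and the development *delay* it imposes on the
terminal cohorts nearly cancel, and the median `t_e` barely moves. The
package's paired-contrast experiment therefore uses a hard freeze (depth
26 °C, extremes near −11/2 °C) placed at day 60 — the terminal third of the
~93-day median extirpation horizon, which is where the historical December
freeze sat relative to its outbreak's horizon — where mortality dominates and
the median drops by 6–8 days while the quarantine length grows by ~4 days.
Both effects are measured by `scripts/acceptance.R`.

## Numerical choices

* Thresholds are stored in degree-hours (`24 K`) so the hourly accumulation
  is dimensionally consistent with day-degree constants.
* Agent iteration is insertion order; all stochastic decisions draw from the
  single R RNG stream, so `set.seed()` makes entire runs reproducible
  regardless of collection internals.
* `t_S` is compared in whole days from simulation start; day boundaries are
  simulation-relative 24-hour blocks, not calendar midnights.
* Clutch draws round to the nearest integer and clamp at zero, which
  inflates the mean slightly when `r` is small relative to `√r_var`; the
  alternative (negative binomial) is not implemented.
* Egg truncation at the cap sets a loud flag (`CAP_EXCEEDED`) because the cap
  has no biological meaning.
* Extirpation requires **all** agents dead, including sterile ones; a
  fertile-only endpoint would end runs earlier and is deliberately not the
  default interpretation.

## Problem sizes

The bundled analyses are desk-scale by design: initial populations of about
80–100 insects (a 0.05 population scale on a one-find outbreak), batches of
1 000–2 000 runs, 100–200 replicates for paired contrasts, and 120–240-day
synthetic series. These sizes give stable medians and PRCC signs while
keeping the whole suite fast; scaling up is a matter of changing `runs`,
`population_scale` and the temperature series, not of changing code.

## Limitations

Only females are modelled; males matter only through the trapping-sensitivity
calibration and the sterile-male effect summarized in `r_red`. There is no
space: no fly movement, no trap geometry, no landscape, so reinvasion from
outside the quarantine area is out of scope. No density dependence or host
availability dynamics. Temperature is a single station series assumed
representative of the outbreak site. And the extirpation endpoint is a
modelling postulate — the simulator measures how long a doomed population
takes to die under the stated parameters, not whether it is doomed.
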