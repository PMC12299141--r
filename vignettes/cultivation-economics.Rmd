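---
title: "Scoring greenhouse cultivations: the net-profit model and its assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring greenhouse cultivations: the net-profit model and its assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ghprofit)
```

## The problem

Autonomous-greenhouse trials score competing control strategies on a
single economic objective: the average daily net profit per m² of
greenhouse over one dwarf-tomato cycle (transplant to a single final
harvest). The strategy controls lamps, heating, CO2 dosing, irrigation,
plant spacing and the harvest date; the evaluation needs nothing but the
compartment's 5-minute actuator trace, the realized density schedule, and
the destructive crop measurement at harvest. `ghprofit` implements that
evaluation, the retrospective harvest-date question, and a synthetic
generator that stands in for trial data.

## The model

### Objective

With days `d = 1..D` since transplanting, per-day fixed costs `F` and
variable costs `V_d`, per-pot area `a_d = 1/δ_d` from the density
schedule, and end-of-cycle gains per pot `G`:

$$\text{net profit} = \frac{G - \sum_{d=1}^{D}(F + V_d)\,a_d}{\sum_{d=1}^{D} a_d}
\quad [\text{EUR}/\text{m}^2/\text{day}].$$

The numerator is the profit of one pot; dividing by the accumulated
area-days converts it to greenhouse area and time at once. The same
objective evaluated from summary quantities is algebraically
`(G − C) · δ̄ / D` with `C` the cost per pot and `δ̄ = D / Σ a_d` the
(harmonic-type) average density — both forms are exposed
(`net_profit()`, `net_profit_summary()`) and tested for identity. The
harvest day accrues area and fixed cost like any other day.

### Costs

* **Fixed** (`fixed_costs()`): annual rates ÷ 365 — 18.125 EUR/m²/year
  base; 0.07 EUR per µmol/(m² s) of *installed* lamp intensity per year,
  where the installed intensity is the maximum dimming percentage ever
  used, scaled to the 200 µmol/(m² s) fixture; 1.50 EUR/m²/year per
  spacing step actually taken.
* **Lamp electricity** (`electricity_cost()`): each record's energy is
  `activation/100 × 200/3.2 / 1000 / 12` kWh/m² (3.2 µmol/J photon
  efficacy, 12 records per hour), priced by the tariff at the record's
  start timestamp: 0.30 EUR/kWh on Monday–Friday 07:00 (inclusive) to
  23:00 (exclusive) local time, 0.20 EUR/kWh otherwise, weekends entirely
  off-peak. The tariff clock is the civil time of a configurable zone
  (default `Europe/Amsterdam`), so daylight-saving transitions are priced
  by local clock.
* **Heating** (`heating_cost()`): pipe-rail delivery is approximated as
  `2 · max(0, T_pipe − T_air)` W/m² while the circulation pump runs, zero
  otherwise (pipe temperature is typically only reported while the pump
  runs; a missing pump channel is treated as "running whenever a pipe
  reading exists"). Energy is the record sum ÷ 1000 ÷ 12, priced at a
  flat 0.09 EUR/kWh.
* **CO2** (`co2_cost()`): the trace carries a cumulative dosing-duration
  counter in minutes; each positive per-record increment × 0.125 g/m²/min
  gives the mass, priced at 0.30 EUR/kg. Counter decreases (device
  resets) contribute nothing; the increment at the very first record is
  unknown and taken as zero.

### Fruit value and gains

`pot_price()` implements the piecewise value model: a pot is unsellable
(`P = 0`) when the ripeness fraction is below ⅓ or the ripe fresh weight
below 50 g; otherwise the price at the 150 g cap interpolates linearly on
the fruit dry-matter percentage between a low curve (≤ 7%) and a high
curve (≥ 8%), and weight above the cap earns nothing more. Ripeness
fractions slightly above 1 occur in real data because successive
destructive measurements use different plants; they are flagged on
ingestion and clamped only for gating. Gains are `G = P − 0.75` (plant
cost), optionally minus 0.10 EUR per manual intervention when that
penalty is enabled — it is off by default, keeping profitability and
robustness as separate questions.

The numeric endpoints of the two curves are not published.
`calibrate_price_caps()` recovers them by least squares from any results
table in which all strategies exceeded the weight cap, since then each
observed gain is `low + w(dmp) · (high − low) − 0.75` with
`w = clamp((dmp − 7)/(8 − 7), 0, 1)`. Calibrated on the six published
2024 strategies this gives 1.80 and 2.00 EUR with residuals at machine
precision, and — calibrating on five strategies only — predicts the
held-out strategy's gains exactly; those values are the package defaults.
Below the cap the price is taken proportional to `ffw/150` (gated at
50 g): no published strategy fell in that region, so this slope is a
modelling assumption that does not affect any reproduced number.

### Derived metrics

`average_density()` is `D / Σ a_d`; `annualized_yield()` extrapolates one
cycle to back-to-back cycles, `red_ffw · δ̄ / D · 365 / 1000` kg/m²/year;
`light_use_efficiency()` is grams of fresh weight per m² per mol of total
PAR, computed by definition only — published LUE figures depend on PAR and
weight inputs that are not fully stated in summary tables, so the package
does not attempt to pin them.

## Retrospective harvest optimization

`optimal_harvest_day()` answers "when should this compartment have been
harvested?" under the assumption that everything else about the
cultivation stays as realized: red fruit weight and ripeness fraction are
linearly interpolated between the sparse destructive measurements (no
extrapolation outside the observed window), the dry-matter percentage is
frozen at its final observed value, daily costs before the candidate day
are as realized and later costs are simply not incurred, and the realized
spacing-step charge is kept. Every integer candidate day in the window
(bounded above by the actual harvest day) is scanned exhaustively; ties
go to the earliest day, since shorter cycles admit more cycles per year.
Two comparative statics follow from the objective's form and are tested:
a uniform per-m²-day cost shift subtracts a constant from every
candidate's profit (the argmax is unchanged), and with flat gains and
positive costs the earliest day wins. When gains are negative throughout
(never-ripe windows) the latest day can be the least bad, because a fixed
loss is amortized over more area-days — the scanner reports it with a
warning rather than failing.

## The synthetic generator

`generate_trace()` emulates the structure the cost accounting consumes,
not greenhouse physics: lamps at a configurable mean dimming (Gaussian
per-record noise, clamped) during a photoperiod window; air temperature a
day/night square wave with noise; the heating pipe a fixed offset above
air during the dark hours with the pump on; the CO2 counter advancing
uniformly over the photoperiod. Defaults describe a plausible autumn
cycle consistent with the published trial ranges — 70-day duration
(70–80 across the benchmark suite), 16 h photoperiod, 21/18 °C day/night,
8 °C pipe offset, 120 dosing minutes/day, densities stepping
56→42→30→20. `generate_crop_series()` draws destructive observations from
a logistic total-weight trajectory (default saturation 260 g/pot near day
45) and a delayed logistic ripeness curve, with 5 g/pot measurement noise
and the trial-like default of three in-cycle dates plus harvest. The
generators are deterministic per seed, with independent sub-streams for
trace and crop so either can be regenerated alone.

What the generator does *not* emulate — sunlight and weather coupling,
ventilation CO2 losses, thermal feedback from lamps, irrigation, within-
canopy variation beyond i.i.d. noise — bounds what passing tests show:
they certify the accounting, pricing, objective and optimizer on inputs
with the right shapes, ranges and invariants, not the behaviour of a real
crop.

## Numerical and design choices

* Cultivation days are 24-hour windows counted from the trace's first
  record (which must be a local midnight), i.e. blocks of 288 records;
  with the fixed-offset timestamps the generator and reader use these
  coincide with calendar days. Tariffs, by contrast, always follow the
  civil clock.
* Trace ingestion fills gaps of up to 6 consecutive records (30 min) by
  last observation carried forward with a warning — except the cumulative
  CO2 counter, which is interpolated linearly so it stays non-decreasing;
  longer gaps are errors, as are out-of-order timestamps.
* Monetary arithmetic never rounds internally; human-readable report
  fields round half-up to 2 decimals (base R's `round()` is half-even,
  which is wrong for invoices).
* `calibrate_price_caps()` solves the 2-parameter system by QR least
  squares and errors when one curve is unconstrained (all observations on
  one side of the 7% knot).
* Logistic refits (`fit_logistic_growth()`) use Levenberg–Marquardt with
  data-driven starts. The parameter-recovery check samples the trajectory
  daily: recovering three parameters from the trial-like four dates is
  underpowered at realistic noise, and the recovery experiment's purpose
  is to certify the generator/fitter pair, not the trial's sampling plan.
* Test and benchmark problem sizes — 2–5-day traces for oracle
  comparisons, 20 bundles for the path-consistency check, 50 random
  trajectories for the optimizer re-scan — keep the full suite in a few
  seconds while exercising every code path.

## Limitations

The evaluation covers the trial's cost perimeter only: labor, transport,
insurance, variable energy contracts and investment costs are out of
scope, as is any physically faithful climate simulation. The sub-cap
price slope and the pipe-rail heat-transfer coefficient are assumptions
(documented above); the harvest optimizer inherits the linearity of the
interpolation between sparse measurements and cannot see dynamics between
observation dates.
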