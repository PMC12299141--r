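# ghprofit

Economic evaluation of greenhouse cultivation strategies, built around the
scoring used in autonomous-greenhouse competition trials of dwarf cherry
tomato: algorithms (or growers) control lamps, heating, CO2 dosing, plant
spacing and the harvest date of a compartment, and are judged on the
average daily net profit per m² of greenhouse. `ghprofit` is for
agronomists and controls researchers who need that objective as a tested,
reusable computation — to score their own trials or simulations, to
re-derive published rankings, or to ask retrospective questions such as
"when should this crop have been harvested?".

## The objective

A cultivation runs for `D` days after transplanting under a plant-density
schedule δ_d ∈ {56, 42, 30, 20} plants/m² (non-increasing, at most three
spacing steps); the area one pot occupies on day `d` is `a_d = 1/δ_d`.
The score is

```
net profit [EUR/m²/day] = ( G − Σ_{d=1..D} (F + V_d) · a_d ) / Σ_{d=1..D} a_d
```

* `G = P − 0.75` — gains per pot: the fruit value `P` minus the plant cost.
  `P` is 0 when fewer than ⅓ of fruits are ripe or ripe fresh weight is
  below 50 g/pot; otherwise it interpolates linearly on the fruit
  dry-matter percentage between a low curve (≤ 7%) and a high curve (≥ 8%),
  with no extra value above 150 g/pot. The cap prices (1.80 / 2.00 EUR)
  are calibrated from the trial's published results with
  `calibrate_price_caps()`.
* `F` — daily fixed costs: 18.125 EUR/m²/year base, 0.07 EUR per
  µmol/(m² s) of installed lamp intensity per year, 1.50 EUR/m²/year per
  spacing step, all ÷ 365.
* `V_d = L_d + H_d + C_d` — variable costs from the 5-minute actuator
  trace: lamp electricity (dimming % × 200 µmol/(m² s) ÷ 3.2 µmol/J,
  priced 0.30 EUR/kWh on workdays 07:00–23:00, 0.20 EUR/kWh otherwise),
  pipe-rail heating (2 W/m² per degree of positive pipe−air difference
  while the circulation pump runs, at 0.09 EUR/kWh), and CO2 dosing
  (0.125 g/m² per counted dosing minute at 0.30 EUR/kg).

On top of the objective the package provides the derived metrics used to
compare strategies (average plant density, annualized yield, light use
efficiency), a retrospective optimal-harvest-date scan over linearly
interpolated crop measurements, and a seeded synthetic-data generator so
the whole pipeline runs and is testable without any trial data.

## Worked example

```r
library(ghprofit)

cfg <- scenario_config(seed = 101, duration = 70, lamp_mean = 80,
                       density_events = data.frame(day = c(1, 35, 50, 60),
                                                   density = c(56, 42, 30, 20)))
trace    <- generate_trace(cfg)            # 70 days x 288 five-minute records
schedule <- generate_density_schedule(cfg)
obs      <- generate_crop_series(cfg)      # sparse destructive measurements

ev <- evaluate_cultivation(trace, schedule, obs, team = "demo")
ev
#> Cultivation evaluation: demo
#>   duration        70 days
#>   avg density     37.9 pots/m2
#>   gains           1.05 EUR/pot
#>   costs           0.58 EUR/pot
#>   net profit      0.25 EUR/m2/day
#>   annualized yield 47.0 kg/m2/year
```

The strategy earned 1.05 EUR per pot at harvest, spent 0.58 EUR per pot on
fixed costs, lamps, heating and CO2, and averaged 37.9 pots/m², for a net
profit of 0.25 EUR per m² of greenhouse per day. Was day 70 the right
moment to harvest?

```r
res <- optimal_harvest_day(obs, daily_cost_ledger(trace, n_changes = 3), schedule)
harvest_sensitivity_report(res)$label
#> "9 day(s) earlier: 0.25 -> 0.44, +0.18 (+71%)"
```

The ripe-fruit value had plateaued while daily costs kept accruing:
harvesting 9 days earlier would have raised the net profit from 0.25 to
0.44 EUR/m²/day. Published results tables can be re-ranked directly:

```r
rank_teams(team_results_2024())[, c("rank", "team", "net_profit")]
#>   rank       team net_profit
#> 1    1      IDEAS     0.3460
#> 2    2     MuGrow     0.1750
#> 3    3    Trigger     0.1336
#> 4    4  Reference     0.1299
#> 5    5 Agrifusion     0.1186
#> 6    6 Tomatonuts     0.0403
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/ghprofit` (`evaluate`, `rank`, `optimize-harvest`, `calibrate`,
`simulate`, `report`).

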