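# Trial cost book: all monetary constants of the evaluation.
base_fixed: 18.1250        # EUR/m2/year, greenhouse maintenance + depreciation
lamp_depreciation: 0.07    # EUR per umol/(m2 s) per year
spacing_step_cost: 1.50    # EUR/m2/year per spacing step
on_peak_price: 0.30        # EUR/kWh, workdays 07:00-23:00
off_peak_price: 0.20       # EUR/kWh
on_peak_start: 7
on_peak_end: 23
tz: Europe/Amsterdam
heat_price: 0.09           # EUR/kWh
co2_rate: 0.125            # g CO2 per m2 per dosing minute
co2_price: 0.30            # EUR/kg
plant_cost: 0.75           # EUR/pot
lamp_max_intensity: 200    # umol/(m2 s)
lamp_efficacy: 3.2         # umol/J
intervention_penalty: 0.10 # EUR/pot, disabled by default
intervention_penalty_enabled: false
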