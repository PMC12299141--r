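# Fruit-value price model. Cap prices are calibrated from the published
# end-of-trial summary (see calibrate_price_caps()).
ripeness_min: 0.3333333333333333
ffw_min: 50        # g/pot, below this the pot is unsellable
ffw_cap: 150       # g/pot, no extra value beyond this weight
dm_low: 7          # percent dry matter, low price curve at or below
dm_high: 8         # percent dry matter, high price curve at or above
price_low_at_cap: 1.80
price_high_at_cap: 2.00
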