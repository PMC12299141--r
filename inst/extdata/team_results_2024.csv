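team,red_ffw,dmp,rfp,gains,cost_per_pot,duration,avg_density,net_profit_printed
IDEAS,219,6.8,0.86,1.05,0.44,70,39.7,0.34
MuGrow,252,7.3,0.76,1.11,0.74,70,33.1,0.18
Trigger,268,5.9,1.01,1.05,0.73,80,33.4,0.13
Reference,275,6.6,0.81,1.05,0.67,74,25.3,0.13
Agrifusion,258,7.2,0.92,1.09,0.72,78,25.0,0.12
Tomatonuts,283,6.0,0.98,1.05,0.91,80,23.0,0.04
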