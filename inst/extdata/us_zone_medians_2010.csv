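pool,equatorial,arid,warm_temperate_fully_humid,warm_temperate_summer_dry,snow_fully_humid,snow_summer_dry
live_ag,14.02,8.05,29.25,33.83,28.56,29.63
live_bg,2.85,1.68,6,7.35,5.94,6.6
dead_wood,3.95,1.46,5.85,11.36,6.78,9.02
forest_floor,7.26,21.09,7.84,28.14,20.28,33.11
soc,158.01,24.12,45.95,49.8,94.76,44.12
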