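pool,cv_pct,n_zones
live_ag,43.3,6
live_bg,45.1,6
dead_wood,55.6,6
forest_floor,57.6,6
soc,73,6
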