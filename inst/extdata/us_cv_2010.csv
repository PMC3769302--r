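pool,cv_pct,n_zones
live_ag,43.1,6
live_bg,44.6,6
dead_wood,55.2,6
forest_floor,53.4,6
soc,70.9,6
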