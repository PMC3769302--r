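pool,stock_tg
live_ag,14541
live_bg,2876
dead_wood,2627
forest_floor,4941
soc,17572
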