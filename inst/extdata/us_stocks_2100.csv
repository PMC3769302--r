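pool,stock_tg
live_ag,21657
live_bg,4282
dead_wood,3298
forest_floor,5275
soc,18903
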