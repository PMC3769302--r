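pool,year,stock_tg
live_ag,1990,1000
live_ag,2000,1100
live_ag,2010,1200
live_bg,1990,200
live_bg,2000,250
live_bg,2010,300
dead_wood,1990,300
dead_wood,2000,300
dead_wood,2010,300
forest_floor,1990,400
forest_floor,2000,450
forest_floor,2010,500
soc,1990,5000
soc,2000,5100
soc,2010,5200
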