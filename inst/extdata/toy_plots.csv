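plot_id,zone_current,zone_future,expansion_ha,live_ag,live_bg,dead_wood,forest_floor,soc
T1,snow_fully_humid,snow_fully_humid,2428,10,2,3,5,50
T2,snow_fully_humid,warm_temperate_fully_humid,2428,20,4,6,10,80
T3,warm_temperate_fully_humid,warm_temperate_fully_humid,2428,30,6,9,15,120
T4,warm_temperate_fully_humid,warm_temperate_fully_humid,2428,40,8,12,20,160
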