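condition,measure,value,sem,units
control,FRAP,36.7,1.2,ug_Fe_per_mg_DW
low_temperature,FRAP,71.7,2.2,ug_Fe_per_mg_DW
low_temperature_water_stress,FRAP,70.6,2.5,ug_Fe_per_mg_DW
control,TPC,43.9,1.9,mg_GAE_per_g_DW
low_temperature,TPC,51.4,1.7,mg_GAE_per_g_DW
low_temperature_water_stress,TPC,58.9,1.9,mg_GAE_per_g_DW
control,DPPH,25.8,2.4,percent_inhibition
low_temperature,DPPH,38.4,3.4,percent_inhibition
low_temperature_water_stress,DPPH,31.5,1.7,percent_inhibition
control,lipoxygenase,40.2,3.3,percent_inhibition
low_temperature,lipoxygenase,71.1,7.9,percent_inhibition
low_temperature_water_stress,lipoxygenase,68.1,1.0,percent_inhibition
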