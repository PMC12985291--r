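"specimen_id","species","label","mean_wild","sd_wild"
"Tscincoides_01","T. scincoides","wild",0.82,0.06
"Tscincoides_02","T. scincoides","captive",0.18,0.06
"Tscincoides_03","T. scincoides","captive",0.18,0.06
"Tscincoides_04","T. scincoides","captive",0.18,0.06
"Tscincoides_05","T. scincoides","captive",0.18,0.06
"Tscincoides_06","T. scincoides","captive",0.18,0.06
"Tscincoides_07","T. scincoides","undetermined",0.58,0.05
"Tscincoides_08","T. scincoides","undetermined",0.58,0.05
"Tscincoides_09","T. scincoides","undetermined",0.66,0.18
"Tscincoides_10","T. scincoides","undetermined",0.66,0.18
"Trugosa_01","T. rugosa","wild",0.82,0.06
"Trugosa_02","T. rugosa","wild",0.82,0.06
"Trugosa_03","T. rugosa","wild",0.82,0.06
"Trugosa_04","T. rugosa","wild",0.82,0.06
"Trugosa_05","T. rugosa","wild",0.82,0.06
"Trugosa_06","T. rugosa","wild",0.82,0.06
"Trugosa_07","T. rugosa","captive",0.18,0.06
"Trugosa_08","T. rugosa","captive",0.18,0.06
"Trugosa_09","T. rugosa","captive",0.18,0.06
"Trugosa_10","T. rugosa","captive",0.18,0.06
"Trugosa_11","T. rugosa","captive",0.18,0.06
"Trugosa_12","T. rugosa","captive",0.18,0.06
"Trugosa_13","T. rugosa","captive",0.18,0.06
"Trugosa_14","T. rugosa","captive",0.18,0.06
"Trugosa_15","T. rugosa","undetermined",0.58,0.05
"Trugosa_16","T. rugosa","undetermined",0.58,0.05
"Trugosa_17","T. rugosa","undetermined",0.58,0.05
"Trugosa_18","T. rugosa","undetermined",0.58,0.05
"Trugosa_19","T. rugosa","undetermined",0.58,0.05
"Trugosa_20","T. rugosa","undetermined",0.66,0.18
"Trugosa_21","T. rugosa","undetermined",0.66,0.18
"Trugosa_22","T. rugosa","undetermined",0.66,0.18
"Trugosa_23","T. rugosa","undetermined",0.66,0.18
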