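beam,voltage_kV,current_uA,filter_element,filter_mm,duration_s
1,10,78.03,,0,20
2,40,60.75,Al,2,20
3,50,60.8,Cu,0.35,20
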