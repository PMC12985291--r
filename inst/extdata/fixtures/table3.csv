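treatment,surface_uSv,depth10mm_uSv
Control 1 direct XRF exposure,227000,
Control 2 no XRF exposure,177.2,156.09
Specimen 1,189.4,168.7
Specimen 2,175.1,203.9
Specimen 3,174,272.4
Specimen 4,250.5,
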