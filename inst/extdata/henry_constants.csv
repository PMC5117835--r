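gas,model,a1,a2,a3,h25_dimensionless,vant_hoff_k,temp_min_c,temp_max_c
methane,bunsen_fit,-67.1962,99.1624,27.9015,,,0,30
ethane,fixed_25c,,,,0.047,2300,0,40
propane,fixed_25c,,,,0.037,2700,0,40
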