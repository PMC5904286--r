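chip_id,target_id,theoretical_copies_per_ul,qualified_wells,positive_wells,is_ntc
Bl04_42512_1,Bl-04,42512,16079,12655,FALSE
Bl04_42512_2,Bl-04,42512,18091,14160,FALSE
Bl04_42512_3,Bl-04,42512,16760,13666,FALSE
Bl04_21256_1,Bl-04,21256,17967,9660,FALSE
Bl04_21256_2,Bl-04,21256,16361,9094,FALSE
Bl04_16028_1,Bl-04,16028,17694,5430,FALSE
Bl04_16028_2,Bl-04,16028,17999,5690,FALSE
Bl04_16028_3,Bl-04,16028,17250,5309,FALSE
Bl04_2657_1,Bl-04,2657,16337,1201,FALSE
Bl04_2657_2,Bl-04,2657,15531,1154,FALSE
Bl04_2657_3,Bl-04,2657,16843,1135,FALSE
Bl04_664_1,Bl-04,664,16228,377,FALSE
Bl04_664_2,Bl-04,664,17016,377,FALSE
Bl04_664_3,Bl-04,664,15074,330,FALSE
Bl04_332_1,Bl-04,332,16898,309,FALSE
Bl04_332_2,Bl-04,332,17551,279,FALSE
Bl04_332_3,Bl-04,332,18133,287,FALSE
Bl04_166_1,Bl-04,166,16489,242,FALSE
Bl04_166_2,Bl-04,166,18138,264,FALSE
Bl04_166_3,Bl-04,166,16308,240,FALSE
Bl04_NTC_1,Bl-04,,17167,201,TRUE
Bl04_NTC_2,Bl-04,,16677,173,TRUE
Bl04_NTC_3,Bl-04,,16288,197,TRUE
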