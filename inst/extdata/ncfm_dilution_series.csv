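chip_id,target_id,theoretical_copies_per_ul,qualified_wells,positive_wells,is_ntc
NCFM_30136_1,NCFM,30136,16653,11285,FALSE
NCFM_15068_1,NCFM,15068,17128,7763,FALSE
NCFM_15068_2,NCFM,15068,16738,7891,FALSE
NCFM_15068_3,NCFM,15068,17524,7914,FALSE
NCFM_7534_1,NCFM,7534,16723,4207,FALSE
NCFM_7534_2,NCFM,7534,16654,3889,FALSE
NCFM_7534_3,NCFM,7534,17102,4090,FALSE
NCFM_1883_1,NCFM,1883,17265,1024,FALSE
NCFM_1883_2,NCFM,1883,16606,1104,FALSE
NCFM_1883_3,NCFM,1883,17661,1056,FALSE
NCFM_942_1,NCFM,942,16814,567,FALSE
NCFM_942_2,NCFM,942,16851,557,FALSE
NCFM_942_3,NCFM,942,17647,521,FALSE
NCFM_471_1,NCFM,471,16852,317,FALSE
NCFM_471_2,NCFM,471,17946,296,FALSE
NCFM_471_3,NCFM,471,17884,407,FALSE
NCFM_235_1,NCFM,235,15851,171,FALSE
NCFM_235_2,NCFM,235,17448,189,FALSE
NCFM_235_3,NCFM,235,16457,189,FALSE
NCFM_NTC_1,NCFM,,17520,120,TRUE
NCFM_NTC_2,NCFM,,15634,139,TRUE
NCFM_NTC_3,NCFM,,17515,2,TRUE
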