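method,rsd_pct,n_replicates,detectable_difference_pct
Plate Count,15.0,3,
Plate Count,15.0,17,
Plate Count,15.0,25,
cdPCR Bl-04,4.0,3,
cdPCR NCFM,5.0,3,
Flow Cytometry,10.0,3,
Flow Cytometry,10.0,9,
Flow Cytometry,10.0,11,
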