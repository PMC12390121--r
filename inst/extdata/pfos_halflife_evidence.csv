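"study_label","tissue","half_life","sd","exposure_weight","type_weight","tissue_weight","duration_weight","divisor"
"single-dose body burden","body",114.2,22.84,1,3,3,1,1
"daily-dose steer plasma","plasma",120,4.1,1,3,1,3,3
"daily-dose heifer plasma","plasma",106,23.1,1,3,1,3,3
"daily-dose grouped muscle","muscle",165,33,1,3,3,3,3
"dietary serum","serum",74.1,13.4,3,1,1,3,2
"dietary muscle","muscle",77,15.4,3,1,3,3,2
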