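birth_weight: 35.450000000000003
birth_weight_sd: 3.27
gain_coeffs:
- 0.5584
- 0.003574
- -4.647e-06
- -5.328e-09
gain_cv: 0.35
late_gain: 0.32
late_gain_sd: 0.112
late_gain_start: 540.0
dmi_log_slope: 5.4702
dmi_log_intercept: -22.888999999999999
dmi_start_day: 66.0
dmi_sd_per_bw: 0.0013
cow_dmi_coeffs:
- 11.696999999999999
- 0.0196
- -0.0001
cow_dmi_cv: 0.062
milk_prod_coeffs:
- 1.445
- 0.3024
- -0.003686
- 1.63e-05
- -2.57e-08
milk_prod_cv: 0.355
milk_dm_fraction: 0.13
weaning_day: 240.0
soil_fraction: 0.0243
soil_sd_per_dmi: 0.005
water_rate_calf: 4.0
water_finisher: 40.840000000000003
water_finisher_sd: 12.869999999999999
water_lactating_cow: 56.469999999999999
water_lactating_cow_sd: 8.16
milk_transfer_factor: 0.0213
absorption_fraction: 1.0
half_life: 108.900000000000006
half_life_sd: 40.5
muscle_body_ratio: 0.231
muscle_body_ratio_sd: 0.09
muscle_bw_fraction: 0.361
muscle_bw_fraction_sd: 0.117
muscle_serum_ratio: 0.08
muscle_serum_ratio_sd: 0.016
dei: 0.0783
de_milk: 4.87
de_forage: 2.27
update_order: intake_first
trunc_lo: 0.05
trunc_hi: 0.95
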