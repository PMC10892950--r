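athlete,weeks_n,ecos_mean,ecos_sd,ecos_max,ecos_min,pct_ecos_swim_mean,pct_ecos_swim_sd,pct_ecos_bike_mean,pct_ecos_bike_sd,pct_ecos_run_mean,pct_ecos_run_sd,pct_ecos_z1_mean,pct_ecos_z1_sd,pct_ecos_z2_mean,pct_ecos_z2_sd,pct_ecos_z3_mean,pct_ecos_z3_sd,hours_mean,hours_sd,hours_max,hours_min,pct_time_z1_mean,pct_time_z1_sd,pct_time_z2_mean,pct_time_z2_sd,pct_time_z3_mean,pct_time_z3_sd,polarization_index
A,50,922,276,1361,271,36.6,13.2,29.3,10.7,34.1,14.9,50.8,13.9,9.7,6.5,40.5,14.5,12.2,2.7,17.6,5.5,80.2,6.9,7.5,4.2,12.3,6.0,1.92
B,48,770,226,1327,266,36.1,11.9,29.5,11.4,34.3,14.9,55.1,17.1,7.8,7.7,40.1,13.7,10.8,2.4,16.2,6.7,83.3,8.7,5.8,4.6,11.9,6.0,2.08
C,48,760,251,1176,274,37.5,16.9,27.8,10.4,34.8,13.2,53.4,16.8,5.7,4.1,43.2,14.4,10.4,2.7,15.9,5.4,82.7,8.5,4.5,3.3,12.8,7.4,2.13
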