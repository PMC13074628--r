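wavelength_nm,mu_a_water_cm1,source
1400,12.3868,hale_querry_grid
1450,14.5837,band_value_log_interpolated
1500,17.1740,hale_querry_grid
1600,6.7152,hale_querry_grid
1650,6.3415,band_value_log_interpolated
1700,5.9875,hale_querry_grid
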