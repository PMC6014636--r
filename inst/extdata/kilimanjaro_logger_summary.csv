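elevation_m,lon,lat,tmin_current_c,tmin_current_sd,tmin_future_c,tmin_future_sd,tmin_delta_c,tmax_current_c,tmax_current_sd,tmax_future_c,tmax_future_sd,tmax_delta_c
1081,37.461845,-3.357280,17.18,1.29,17.28,1.23,0.10,28.59,3.47,30.42,2.56,1.83
1249,37.474743,-3.341794,16.67,1.31,16.78,1.18,0.11,29.53,3.72,29.63,2.39,0.10
1419,37.469891,-3.327607,15.31,1.48,15.58,1.14,0.27,27.41,2.78,27.98,2.38,0.57
1533,37.465210,-3.312971,14.60,1.44,14.94,1.29,0.34,26.58,4.20,27.34,2.32,0.76
1705,37.456239,-3.286082,13.85,1.44,14.02,1.34,0.17,25.58,3.29,26.34,2.14,0.76
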