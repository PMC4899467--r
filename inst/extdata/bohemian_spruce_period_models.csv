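response,term,estimate,r2m,r2c,aic
d13c,intercept,19.635,0.52,0.87,143
d13c,pollution,-1.876,0.52,0.87,143
d13c,post1,-0.696,0.52,0.87,143
d13c,post2,-0.480,0.52,0.87,143
ci,intercept,204.310,0.80,0.94,672
ci,pollution,-4.060,0.80,0.94,672
ci,post1,35.217,0.80,0.94,672
ci,post2,44.241,0.80,0.94,672
iwue,intercept,61.944,0.58,0.89,578
iwue,pollution,24.604,0.58,0.89,578
iwue,post1,21.056,0.58,0.89,578
iwue,post2,20.807,0.58,0.89,578
biomass_increment,intercept,9.945,0.05,0.71,4157
biomass_increment,pollution,1.141,0.05,0.71,4157
biomass_increment,post1,2.468,0.05,0.71,4157
biomass_increment,Plesne,3.702,0.05,0.71,4157
biomass_increment,pollution:Plesne,-1.966,0.05,0.71,4157
biomass_increment,post1:Plesne,0.083,0.05,0.71,4157
interannual_variability,intercept,0.170,0.22,0.51,-1648
interannual_variability,pollution,0.090,0.22,0.51,-1648
interannual_variability,post1,0.041,0.22,0.51,-1648
temperature_correlation,intercept,-0.018,0.21,0.29,-221
temperature_correlation,pollution,0.236,0.21,0.29,-221
temperature_correlation,post1,0.167,0.21,0.29,-221
temperature_correlation,Plesne,0.224,0.21,0.29,-221
temperature_correlation,pollution:Plesne,-0.159,0.21,0.29,-221
temperature_correlation,post1:Plesne,-0.080,0.21,0.29,-221
precipitation_correlation,intercept,0.111,0.12,0.12,-279
precipitation_correlation,pollution,-0.024,0.12,0.12,-279
precipitation_correlation,post1,0.039,0.12,0.12,-279
precipitation_correlation,Plesne,0.065,0.12,0.12,-279
precipitation_correlation,pollution:Plesne,0.029,0.12,0.12,-279
precipitation_correlation,post1:Plesne,0.091,0.12,0.12,-279
cloud_cover_correlation,intercept,-0.039,0.18,0.18,-140
cloud_cover_correlation,pollution,-0.214,0.18,0.18,-140
cloud_cover_correlation,post1,-0.183,0.18,0.18,-140
cloud_cover_correlation,Plesne,-0.067,0.18,0.18,-140
drought_correlation,intercept,0.029,0.26,0.27,-189
drought_correlation,pollution,-0.009,0.26,0.27,-189
drought_correlation,post1,0.137,0.26,0.27,-189
drought_correlation,Plesne,0.013,0.26,0.27,-189
drought_correlation,pollution:Plesne,0.039,0.26,0.27,-189
drought_correlation,post1:Plesne,0.197,0.26,0.27,-189
increment_vs_discrimination,intercept,120.677,0.09,0.84,290
increment_vs_discrimination,pollution,-108.637,0.09,0.84,290
increment_vs_discrimination,post1,12.427,0.09,0.84,290
increment_vs_discrimination,delta13C,-5.285,0.09,0.84,290
increment_vs_discrimination,pollution:delta13C,5.473,0.09,0.84,290
increment_vs_discrimination,post1:delta13C,-0.871,0.09,0.84,290
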