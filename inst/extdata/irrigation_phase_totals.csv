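year,point_id,scheduling,phase_I,phase_II,phase_III,total,supply_ratio_pct
2015,1,farmer,89,119,44,252,47.08
2015,2,farmer,NA,NA,NA,NA,NA
2015,3,farmer,86,118,44,248,46.60
2015,4,farmer,NA,NA,NA,NA,NA
2015,CR1,farmer,83,108,41,232,44.68
2015,CR2,farmer,82,108,41,231,44.56
2015,CR3,farmer,81,106,40,227,44.08
2016,1,NAIS,64,154,51,300,60.72
2016,2,NAIS,69,154,50,306,61.42
2016,3,NAIS,66,150,47,298,60.49
2016,4,NAIS,60,134,43,231,52.71
2016,CR1,AIS,63,113,22,198,48.87
2016,CR2,AIS,68,139,25,232,52.82
2016,CR3,AIS,68,121,26,215,50.85
2017,1,NAIS,148,109,174,431,60.85
2017,2,NAIS,148,110,177,435,61.30
2017,3,NAIS,147,111,176,434,61.18
2017,4,NAIS,148,110,177,435,61.30
2017,CR1,AIS,169,87,149,405,57.94
2017,CR2,AIS,175,87,148,410,58.50
2017,CR3,AIS,185,85,173,444,62.30
2017,CR4,AIS,113,158,99,414,54.03
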