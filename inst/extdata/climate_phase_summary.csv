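year,phase,t_mean,rh_mean,rainfall,eto_pm,eto_h,etc
2015,I,17.8,63.1,99.1,559.2,598.1,315.8
2015,II,25.1,52.2,12.1,414.5,412.7,238.2
2015,III,16.3,75.5,141.5,225.2,255.5,188.9
2015,annual,16.2,69.5,327.9,1304.7,1391.4,834.3
2016,I,15.9,70.8,204.2,501.6,519.0,319.8
2016,II,25.8,51.8,10.5,389.7,276.8,241.5
2016,III,16.7,72.7,121.0,239.1,276.8,197.9
2016,annual,16.1,72.1,475.3,1225.1,1340.1,860.6
2017,I,18.2,62.6,76.4,579.2,597.1,351.1
2017,II,25.8,51.4,25.8,395.1,411.1,267.3
2017,III,16.7,63.3,51.8,251.2,299.6,189.1
2017,annual,16.4,65.9,265.4,1330.5,1433.5,894.2
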