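control_point,year,variable,mean,se,letters
T1,2015,yield_kg_ha,9105,449,ab
T2,2015,yield_kg_ha,12146,760,a
CR1,2015,yield_kg_ha,10240,2037,ab
CR2,2015,yield_kg_ha,6740,1324,b
CR3,2015,yield_kg_ha,10788,1453,ab
T1,2016,yield_kg_ha,12507,759,a
T2,2016,yield_kg_ha,13284,854,a
CR1,2016,yield_kg_ha,9732,1362,a
CR2,2016,yield_kg_ha,5490,1274,b
CR3,2016,yield_kg_ha,10937,1687,a
T1,2017,yield_kg_ha,15575,625,b
T2,2017,yield_kg_ha,17809,725,b
CR1,2017,yield_kg_ha,18244,726,b
CR2,2017,yield_kg_ha,21478,1324,a
CR3,2017,yield_kg_ha,18535,2062,ab
CR4,2017,yield_kg_ha,15277,683,b
T1,2015,fruits_per_tree,2160,131,ab
T2,2015,fruits_per_tree,3231,297,a
CR1,2015,fruits_per_tree,2625,511,ab
CR2,2015,fruits_per_tree,1628,285,b
CR3,2015,fruits_per_tree,2621,486,ab
T1,2016,fruits_per_tree,4454,383,a
T2,2016,fruits_per_tree,4580,510,a
CR1,2016,fruits_per_tree,2884,302,ab
CR2,2016,fruits_per_tree,1345,388,b
CR3,2016,fruits_per_tree,3966,1202,a
T1,2017,fruits_per_tree,5208,298,b
T2,2017,fruits_per_tree,6457,230,ab
CR1,2017,fruits_per_tree,6714,435,a
CR2,2017,fruits_per_tree,7568,548,a
CR3,2017,fruits_per_tree,6449,958,ab
CR4,2017,fruits_per_tree,5089,164,b
T1,2015,oil_kg_ha,1725,84,ab
T2,2015,oil_kg_ha,2205,140,a
CR1,2015,oil_kg_ha,1362,271,bc
CR2,2015,oil_kg_ha,1024,201,c
CR3,2015,oil_kg_ha,1899,256,ab
T1,2016,oil_kg_ha,2211,104,a
T2,2016,oil_kg_ha,2423,174,a
CR1,2016,oil_kg_ha,1372,201,b
CR2,2016,oil_kg_ha,914,230,b
CR3,2016,oil_kg_ha,2071,276,a
T1,2017,oil_kg_ha,3047,61,
T2,2017,oil_kg_ha,3375,171,
CR1,2017,oil_kg_ha,3090,148,
CR2,2017,oil_kg_ha,3468,141,
CR3,2017,oil_kg_ha,3508,345,
CR4,2017,oil_kg_ha,3033,154,
T1,2015,wp_yield,36,1.78,ab
T2,2015,wp_yield,49,3.06,a
CR1,2015,wp_yield,44,8.78,ab
CR2,2015,wp_yield,29,5.73,b
CR3,2015,wp_yield,48,6.40,ab
T1,2016,wp_yield,41,2.50,a
T2,2016,wp_yield,50,3.22,a
CR1,2016,wp_yield,49,6.87,a
CR2,2016,wp_yield,23.66,5.49,b
CR3,2016,wp_yield,50.86,7.85,a
T1,2017,wp_yield,36,1.44,c
T2,2017,wp_yield,41,1.67,bc
CR1,2017,wp_yield,45,1.79,b
CR2,2017,wp_yield,52,3.22,a
CR3,2017,wp_yield,42,4.64,bc
CR4,2017,wp_yield,37,1.65,c
T1,2015,wp_oil,7,0.33,ab
T2,2015,wp_oil,8,0.56,a
CR1,2015,wp_oil,7,1.43,ab
CR2,2015,wp_oil,4,0.87,b
CR3,2015,wp_oil,6,1.20,ab
T1,2016,wp_oil,7.29,0.34,ab
T2,2016,wp_oil,9.14,0.65,ab
CR1,2016,wp_oil,6.93,1.01,b
CR2,2016,wp_oil,3.94,0.99,c
CR3,2016,wp_oil,9.63,1.28,a
T1,2017,wp_oil,7.03,0.14,b
T2,2017,wp_oil,7.76,0.39,ab
CR1,2017,wp_oil,7.63,0.37,ab
CR2,2017,wp_oil,8.45,0.34,a
CR3,2017,wp_oil,7.90,0.78,ab
CR4,2017,wp_oil,7.32,0.37,ab
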