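control_point,position,sensor_id,year,high_ref,low_ref
CR1,A030,S1,2016,0.371,0.171
CR1,A060,S2,2016,0.362,0.248
CR1,A030,S3,2016,0.325,0.150
CR1,A060,S4,2016,0.369,0.188
CR1,B030,S5,2016,0.314,0.167
CR2,A030,S6,2016,0.400,0.280
CR2,A060,S7,2016,0.359,0.283
CR2,A030,S8,2016,0.385,0.165
CR2,A060,S9,2016,0.318,0.238
CR2,B030,S10,2016,0.298,0.178
CR3,A030,S11,2016,0.337,0.104
CR3,A060,S12,2016,0.312,0.202
CR3,A030,S13,2016,0.447,0.219
CR3,A060,S14,2016,0.313,0.073
CR3,B030,S15,2016,0.446,0.227
CR1,A030,S1,2017,0.399,0.296
CR1,A060,S2,2017,0.357,0.221
CR1,A030,S3,2017,0.356,0.252
CR1,A060,S4,2017,0.318,0.175
CR1,B030,S5,2017,0.303,0.246
CR2,A030,S6,2017,0.399,0.296
CR2,A060,S7,2017,0.357,0.221
CR2,A030,S8,2017,0.356,0.252
CR2,A060,S9,2017,0.318,0.175
CR2,B030,S10,2017,0.303,0.246
CR3,A030,S11,2017,0.328,0.183
CR3,A060,S12,2017,0.252,0.137
CR3,A030,S13,2017,0.365,0.283
CR3,A060,S14,2017,0.277,0.133
CR3,B030,S15,2017,0.362,0.233
CR4,A030,S16,2017,0.325,0.296
CR4,A060,S17,2017,0.356,0.221
CR4,A030,S18,2017,0.331,0.252
CR4,A060,S19,2017,0.362,0.175
CR4,B030,S20,2017,0.301,0.246
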