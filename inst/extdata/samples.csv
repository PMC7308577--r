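sample_id,sample_type,water_content_pct_wet,pH,toc_pct,rate_constant
KS-13,forest_soil,29.7,5.28,4.8,1.1
SG-1,forest_soil,31,5,5.2,1.25
CL,forest_soil,46.1,5.4,7,1.25
IG-C,volcanic_ash,25.3,4.1,0.1,0.07
IG-2A,forest_soil,46.1,4.4,6.5,1.18
OY-1-C,volcanic_ash,28.5,3.6,0.1,0.01
OY-1-A,forest_soil,33.6,4.2,6.3,0.66
KP-1,scoria,10.2,4.9,0.1,0.05
KP-3,scoria,17.8,4.9,0.38,0.22
KP-5,scoria,13.9,4.6,0.64,0.36
F-1140,forest_soil,55.6,4.8,11.7,1.71
F-1300,forest_soil,46.8,5.4,9.1,1.4
F-1480,scoria,10.5,5.4,0.29,0.6
F-3020,scoria,6,5.9,0.1,0.27
F-3230,scoria,9.8,6.1,0.1,0.27
F-3590,scoria,10.1,5.5,0.1,0.35
F-3750,scoria,16.6,5.6,0.1,0.26
Pond-A,pond_water,NA,7.6,19.7,0.051
Pond-B,pond_water,NA,7.7,11.3,0.035
Pond-C,pond_water,NA,7.4,0.4,0.019
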