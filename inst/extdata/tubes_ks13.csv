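sample_id,level_exponent,replicate,day,turbid,degradation_ratio_pct,residual_ppmv,initial_ppmv
KS-13,2,1,4,1,97,NA,30
KS-13,2,1,11,1,95,NA,30
KS-13,2,1,18,1,85,NA,30
KS-13,2,1,40,1,85,NA,30
KS-13,2,2,4,1,100,NA,30
KS-13,2,2,11,1,100,NA,30
KS-13,2,2,18,1,100,NA,30
KS-13,2,2,40,1,100,NA,30
KS-13,2,3,4,1,100,NA,30
KS-13,2,3,11,1,100,NA,30
KS-13,2,3,18,1,100,NA,30
KS-13,2,3,40,1,100,NA,30
KS-13,3,1,4,1,100,NA,30
KS-13,3,1,11,1,100,NA,30
KS-13,3,1,18,1,100,NA,30
KS-13,3,1,40,1,82,NA,30
KS-13,3,2,4,1,100,NA,30
KS-13,3,2,11,1,100,NA,30
KS-13,3,2,18,1,100,NA,30
KS-13,3,2,40,1,83,NA,30
KS-13,3,3,4,1,100,NA,30
KS-13,3,3,11,1,100,NA,30
KS-13,3,3,18,1,100,NA,30
KS-13,3,3,40,1,89,NA,30
KS-13,4,1,4,1,74,NA,30
KS-13,4,1,11,1,62,NA,30
KS-13,4,1,18,1,55,NA,30
KS-13,4,1,40,1,49,NA,30
KS-13,4,2,4,1,96,NA,30
KS-13,4,2,11,1,73,NA,30
KS-13,4,2,18,1,72,NA,30
KS-13,4,2,40,1,62,NA,30
KS-13,4,3,4,1,44,NA,30
KS-13,4,3,11,1,44,NA,30
KS-13,4,3,18,1,41,NA,30
KS-13,4,3,40,1,34,NA,30
KS-13,5,1,4,1,41,NA,30
KS-13,5,1,11,1,91,NA,30
KS-13,5,1,18,1,92,NA,30
KS-13,5,1,40,1,88,NA,30
KS-13,5,2,4,1,42,NA,30
KS-13,5,2,11,1,57,NA,30
KS-13,5,2,18,1,42,NA,30
KS-13,5,2,40,1,37,NA,30
KS-13,5,3,4,1,38,NA,30
KS-13,5,3,11,1,82,NA,30
KS-13,5,3,18,1,90,NA,30
KS-13,5,3,40,1,91,NA,30
KS-13,6,1,4,1,22,NA,30
KS-13,6,1,11,1,40,NA,30
KS-13,6,1,18,1,41,NA,30
KS-13,6,1,40,1,37,NA,30
KS-13,6,2,4,1,23,NA,30
KS-13,6,2,11,1,43,NA,30
KS-13,6,2,18,1,41,NA,30
KS-13,6,2,40,1,31,NA,30
KS-13,6,3,4,1,28,NA,30
KS-13,6,3,11,1,42,NA,30
KS-13,6,3,18,1,46,NA,30
KS-13,6,3,40,1,39,NA,30
KS-13,7,1,4,1,58,NA,30
KS-13,7,1,11,1,100,NA,30
KS-13,7,1,18,1,69,NA,30
KS-13,7,1,40,1,52,NA,30
KS-13,7,2,4,1,25,NA,30
KS-13,7,2,11,1,72,NA,30
KS-13,7,2,18,1,74,NA,30
KS-13,7,2,40,1,NA,NA,30
KS-13,7,3,4,1,22,NA,30
KS-13,7,3,11,1,29,NA,30
KS-13,7,3,18,1,24,NA,30
KS-13,7,3,40,1,65,NA,30
KS-13,8,1,4,0,24,NA,30
KS-13,8,1,11,0,29,NA,30
KS-13,8,1,18,0,27,NA,30
KS-13,8,1,40,0,29,NA,30
KS-13,8,2,4,1,23,NA,30
KS-13,8,2,11,1,28,NA,30
KS-13,8,2,18,1,57,NA,30
KS-13,8,2,40,1,39,NA,30
KS-13,8,3,4,0,23,NA,30
KS-13,8,3,11,0,26,NA,30
KS-13,8,3,18,0,26,NA,30
KS-13,8,3,40,0,26,NA,30
KS-13,9,1,4,0,25,NA,30
KS-13,9,1,11,0,28,NA,30
KS-13,9,1,18,0,26,NA,30
KS-13,9,1,40,0,28,NA,30
KS-13,9,2,4,0,25,NA,30
KS-13,9,2,11,0,27,NA,30
KS-13,9,2,18,0,26,NA,30
KS-13,9,2,40,0,26,NA,30
KS-13,9,3,4,1,24,NA,30
KS-13,9,3,11,1,27,NA,30
KS-13,9,3,18,1,26,NA,30
KS-13,9,3,40,1,46,NA,30
KS-13,10,1,4,0,25,NA,30
KS-13,10,1,11,0,27,NA,30
KS-13,10,1,18,0,30,NA,30
KS-13,10,1,40,0,27,NA,30
KS-13,10,2,4,0,25,NA,30
KS-13,10,2,11,0,26,NA,30
KS-13,10,2,18,0,26,NA,30
KS-13,10,2,40,0,27,NA,30
KS-13,10,3,4,0,26,NA,30
KS-13,10,3,11,0,26,NA,30
KS-13,10,3,18,0,26,NA,30
KS-13,10,3,40,0,27,NA,30
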