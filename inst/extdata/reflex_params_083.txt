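G_SOL 1.45725883354
G_TA 2.02809778583
loff_TA 0.537158971314
G_SOLTA 1.33840254334
G_GAS 2.36303553131
G_VAS 0.490746565083
q_ko 0.831452950529
k_ko 2.39565381934
k_dsVAS 0.0730723504588
th_ref 0.0116161747111
k_p 1.0523209379
k_d 0.102409406174
c_GLU_bal 0.743262745849
c_HFL_bal 0.633865431179
c_HAM_bal 2.51372602926
ds_HFL 0.0879990010162
ds_GLU 0.225597301564
sw_BFSH 0.157527774303
frac_BFSH 0.454328362
G_HFL 0.139683426935
loff_HFL 0.361127241548
G_HAMHFL 0.233102048354
loff_HAM 1.45417797986
G_HAM 0.12493214587
G_GLU_sw 0.232993337039
k_lean_HFL 0.349940483612
s0_VAS 0.0879634371297
s0_SOL 0.0117429675059
s0_GAS 0.0204688002454
s0_HAM 0.00931541547694
s0_GLU 0.0244153674543
s0_HFL 0.0214667766338
s0_RF 0.0198177046289
s0_BFSH 0.0227104780086
s0_TA 0.0239277527209
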