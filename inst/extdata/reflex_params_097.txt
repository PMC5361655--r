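G_SOL 1.64437021653
G_TA 2.48916570417
loff_TA 0.675205830442
G_SOLTA 1.60627590877
G_GAS 2.02467394295
G_VAS 0.482472358944
q_ko 0.611900940336
k_ko 4.78212922374
k_dsVAS 0.0936547094485
th_ref 0.0236041352928
k_p 1.47631700536
k_d 0.0691212738928
c_GLU_bal 0.719092015368
c_HFL_bal 0.490792684397
c_HAM_bal 2.1069557911
ds_HFL 0.0909964444336
ds_GLU 0.390551426139
sw_BFSH 0.222796528758
frac_BFSH 0.297207020037
G_HFL 0.23486437008
loff_HFL 0.243031970899
G_HAMHFL 0.177408166927
loff_HAM 1.65988086655
G_HAM 0.129158833669
G_GLU_sw 0.350787508986
k_lean_HFL 0.253197296642
s0_VAS 0.0717711200551
s0_SOL 0.0186010434895
s0_GAS 0.0225131869707
s0_HAM 0.0101547648578
s0_GLU 0.0171096114586
s0_HFL 0.0191887318092
s0_RF 0.0138580285786
s0_BFSH 0.0224418340704
s0_TA 0.0217555383686
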