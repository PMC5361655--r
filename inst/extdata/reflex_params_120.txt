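G_SOL 2.17178436527
G_TA 1.58160908641
loff_TA 0.608210091692
G_SOLTA 2.00741320003
G_GAS 1.47655514184
G_VAS 0.523451890724
q_ko 0.701998654933
k_ko 8.60747805184
k_dsVAS 0.085537298554
th_ref 0.0185144722693
k_p 0.979237035578
k_d 0.0632868736998
c_GLU_bal 0.783080411726
c_HFL_bal 0.539773993599
c_HAM_bal 3.35122677707
ds_HFL 0.08161017912
ds_GLU 0.37757407914
sw_BFSH 0.274238031154
frac_BFSH 0.299792622743
G_HFL 0.167188606201
loff_HFL 0.33484331333
G_HAMHFL 0.13265784307
loff_HAM 1.10836740407
G_HAM 0.102705598044
G_GLU_sw 0.279358791228
k_lean_HFL 0.260123196673
s0_VAS 0.0642043804657
s0_SOL 0.0179371998915
s0_GAS 0.0141878029158
s0_HAM 0.0043996849723
s0_GLU 0.0124351891663
s0_HFL 0.018187115647
s0_RF 0.0093448422375
s0_BFSH 0.0316280399466
s0_TA 0.0267254942334
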