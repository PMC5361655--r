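G_SOL 1.97888689522
G_TA 2.31544196466
loff_TA 0.812227539438
G_SOLTA 1.77518332231
G_GAS 1.842011761
G_VAS 0.44350059271
q_ko 0.540355163909
k_ko 4.61146642733
k_dsVAS 0.121419216686
th_ref 0.0179965881894
k_p 1.16722760972
k_d 0.0444842529547
c_GLU_bal 0.931517762743
c_HFL_bal 0.433110943162
c_HAM_bal 1.76313843024
ds_HFL 0.0918717945999
ds_GLU 0.466382685852
sw_BFSH 0.213963950935
frac_BFSH 0.265577637615
G_HFL 0.1815329209
loff_HFL 0.29170569534
G_HAMHFL 0.200593360442
loff_HAM 1.26464765293
G_HAM 0.151341297633
G_GLU_sw 0.275941159396
k_lean_HFL 0.309743881661
s0_VAS 0.060554449101
s0_SOL 0.0183745103846
s0_GAS 0.0256929921217
s0_HAM 0.0112529212517
s0_GLU 0.0150760693666
s0_HFL 0.0189947191355
s0_RF 0.0126735581089
s0_BFSH 0.0198813317013
s0_TA 0.0220441462671
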