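G_SOL 2.13960055516
G_TA 2.01084591796
loff_TA 0.581441499881
G_SOLTA 1.61904400471
G_GAS 1.7114103219
G_VAS 0.520599402215
q_ko 0.868123067035
k_ko 7.45573024323
k_dsVAS 0.0965315407923
th_ref 0.026750058083
k_p 1.0640759999
k_d 0.0575226549824
c_GLU_bal 0.690066472557
c_HFL_bal 0.496828125572
c_HAM_bal 2.82056423213
ds_HFL 0.0985434333606
ds_GLU 0.369061582547
sw_BFSH 0.255583885927
frac_BFSH 0.240451072268
G_HFL 0.162112777554
loff_HFL 0.30222070907
G_HAMHFL 0.147206059795
loff_HAM 1.2476197786
G_HAM 0.109494120905
G_GLU_sw 0.208207311658
k_lean_HFL 0.336618956704
s0_VAS 0.0772955662022
s0_SOL 0.0194379711932
s0_GAS 0.017972710597
s0_HAM 0.00609790043765
s0_GLU 0.0097935878929
s0_HFL 0.0221408760063
s0_RF 0.0132597381397
s0_BFSH 0.0304230775424
s0_TA 0.0313321994406
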