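system,T_K,ksv_1e4,ka_1e4
BPA,298,0.76,0.98
BPA,310,0.66,3.67
BPS,298,3.57,0.54
BPS,310,2.94,3.30
BPE,310,1.06,2.30
BPF,298,0.51,1.41
BPB,298,1.01,10.51
BPB,310,0.38,2.90
BPAF,298,,4.16
BPAF,310,0.58,2.79
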