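sample,ratio,alpha_helix,beta_sheet,beta_turn,random_coil
control,0:1,9.39,44.64,14.48,31.55
BPA,10:1,9.15,44.24,14.22,32.39
BPS,10:1,8.91,46.03,14.37,30.69
BPE,10:1,7.88,48.59,14.13,29.39
BPF,10:1,8.38,52.89,15.11,23.62
BPB,10:1,10.60,55.50,16.75,17.15
BPAF,10:1,2.40,65.47,20.93,11.20
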