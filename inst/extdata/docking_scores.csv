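chemical,score
BPA,-7.8
BPS,-7.6
BPE,-7.6
BPF,-7.6
BPB,-7.9
BPAF,-8.6
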