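chemical,metric,source
BPA,delta_tm50,printed
BPAF,delta_tm50,printed
BPS,delta_tm50,figure_estimate_synthetic
BPE,delta_tm50,figure_estimate_synthetic
BPF,delta_tm50,figure_estimate_synthetic
BPB,delta_tm50,figure_estimate_synthetic
BPE,wound_healing,printed
BPS,wound_healing,printed
BPAF,wound_healing,printed
BPA,wound_healing,figure_estimate_synthetic
BPF,wound_healing,figure_estimate_synthetic
BPB,wound_healing,figure_estimate_synthetic
BPAF,transwell_invasion,printed
BPA,transwell_invasion,figure_estimate_synthetic
BPS,transwell_invasion,figure_estimate_synthetic
BPE,transwell_invasion,figure_estimate_synthetic
BPF,transwell_invasion,figure_estimate_synthetic
BPB,transwell_invasion,figure_estimate_synthetic
BPF,pgr_mrna,printed
BPAF,pgr_mrna,printed
BPA,pgr_mrna,figure_estimate_synthetic
BPS,pgr_mrna,figure_estimate_synthetic
BPE,pgr_mrna,figure_estimate_synthetic
BPB,pgr_mrna,figure_estimate_synthetic
BPAF,pr_protein,printed
BPA,pr_protein,figure_estimate_synthetic
BPS,pr_protein,figure_estimate_synthetic
BPE,pr_protein,figure_estimate_synthetic
BPF,pr_protein,figure_estimate_synthetic
BPB,pr_protein,figure_estimate_synthetic
BPA,cck8_proliferation,figure_estimate_synthetic
BPS,cck8_proliferation,figure_estimate_synthetic
BPE,cck8_proliferation,figure_estimate_synthetic
BPF,cck8_proliferation,figure_estimate_synthetic
BPB,cck8_proliferation,figure_estimate_synthetic
BPAF,cck8_proliferation,figure_estimate_synthetic
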