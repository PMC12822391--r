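chemical,docking_score,mmgbsa_dG,PR_dG_298,alpha_helix,beta_sheet,beta_turn,random_coil,delta_tm50,cck8_proliferation,wound_healing,transwell_invasion,pgr_mrna,pr_protein
BPA,-7.8,-28.32,-22.769,9.15,44.24,14.22,32.39,1.97,1.20,1.80,1.30,1.30,1.10
BPS,-7.6,-21.76,-21.293,8.91,46.03,14.37,30.69,1.00,1.15,2.00,1.20,1.20,1.00
BPE,-7.6,-25.11,,7.88,48.59,14.13,29.39,0.50,1.20,2.54,1.40,1.40,1.05
BPF,-7.6,-26.98,-23.671,8.38,52.89,15.11,23.62,0.90,1.25,1.90,1.50,4.12,1.20
BPB,-7.9,-29.27,-28.647,10.60,55.50,16.75,17.15,1.20,1.30,1.90,1.60,1.50,1.15
BPAF,-8.6,-29.38,-26.351,2.40,65.47,20.93,11.20,1.89,1.40,2.50,2.06,3.55,1.88
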