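chemical,e_vdw,e_ele,g_sol_polar,g_sol_nonpolar,g_binding,e_vdw_sem,e_ele_sem,g_sol_polar_sem,g_sol_nonpolar_sem,g_binding_sem
BPA,-33.24,-15.18,23.50,-3.40,-28.32,0.25,0.32,0.20,0.01,0.27
BPAF,-36.91,-14.92,26.61,-4.16,-29.38,0.27,0.26,0.18,0.01,0.24
BPE,-29.80,-18.47,26.43,-3.28,-25.11,0.22,0.40,0.28,0.01,0.25
BPB,-35.50,-13.42,23.29,-3.64,-29.27,0.29,0.38,0.29,0.01,0.27
BPS,-34.37,-24.10,40.04,-3.33,-21.76,0.23,0.56,0.47,0.01,0.27
BPF,-32.40,-17.49,26.29,-3.39,-26.98,0.27,0.25,0.17,0.01,0.28
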