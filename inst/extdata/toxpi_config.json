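{
  "docking_score": {"class": "in_silico_binding", "transform": "negate"},
  "mmgbsa_dG": {"class": "in_silico_binding", "transform": "negate"},
  "PR_dG_298": {"class": "chemical_analysis", "transform": "negate"},
  "alpha_helix": {"class": "chemical_analysis", "transform": "absdiff_vs_control", "control_value": 9.39},
  "beta_sheet": {"class": "chemical_analysis", "transform": "absdiff_vs_control", "control_value": 44.64},
  "beta_turn": {"class": "chemical_analysis", "transform": "absdiff_vs_control", "control_value": 14.48},
  "random_coil": {"class": "chemical_analysis", "transform": "absdiff_vs_control", "control_value": 31.55},
  "delta_tm50": {"class": "in_vitro_binding", "transform": "identity"},
  "cck8_proliferation": {"class": "cytotoxicity", "transform": "identity"},
  "wound_healing": {"class": "cytotoxicity", "transform": "identity"},
  "transwell_invasion": {"class": "cytotoxicity", "transform": "identity"},
  "pgr_mrna": {"class": "pr_expression", "transform": "identity"},
  "pr_protein": {"class": "pr_expression", "transform": "identity"}
}
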