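# Shared fixtures built in code.

# standard titration ladder, mol/L
uM <- 1e-6
ladder <- c(0, 1, 5, 10, 15, 20) * uM

# noiseless single-site static-quenching series: F = f0 / (1 + K*Q)
static_series <- function(K, f0 = 1000, concs = ladder) {
  data.frame(conc = concs, intensity = f0 / (1 + K * concs))
}

# noiseless enhancement series: Fx = f0 + (finf - f0) * K*Q / (1 + K*Q)
enh_series <- function(K, f0 = 1000, finf = 2000, concs = ladder) {
  data.frame(conc = concs,
             intensity = f0 + (finf - f0) * K * concs / (1 + K * concs))
}

# printed reference values for the six analog systems (kJ/mol based)
printed_dG <- list(
  BPA = c(`298` = -22.769, `310` = -27.089),
  BPS = c(`298` = -21.293, `310` = -26.815),
  BPE = c(`310` = -25.885),
  BPF = c(`298` = -23.671),
  BPB = c(`298` = -28.647, `310` = -26.482),
  BPAF = c(`298` = -26.351, `310` = -26.383))
printed_dH <- c(BPA = 84.510, BPS = 115.854, BPB = -82.412, BPAF = -25.568)
printed_dS <- c(BPA = 0.360, BPS = 0.460, BPB = -0.180, BPAF = 0.003)
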