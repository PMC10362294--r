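# Shared helpers for the suite.

# Small, fast parameter set for property tests: physics unchanged, just the
# default object.
tfp <- function(...) tf_params(...)

# Brute-force oracle for the energy-budget split: scan the LPET fraction on a
# fine grid and return the split/fluxes that minimize the ATP-NADPH
# inconsistency, treating V_NF as given. Independent of the closed-form
# algebra in close_energy_budget().
budget_oracle <- function(V_PET, V_NF, params, n_grid = 1e6 + 1) {
  aL <- params$atp_per_e_LPET; aA <- params$atp_per_e_AET
  nL <- params$nadph_per_e_LPET
  aN <- params$atp_per_N_NF; nN <- params$nadph_per_N_NF
  aC <- params$atp_per_C_CF; nC <- params$nadph_per_C_CF
  m  <- params$atp_maintenance
  x <- seq(0, 1, length.out = n_grid)
  atp_left   <- V_PET * (aA + x * (aL - aA)) - m - V_NF * aN
  nadph_left <- V_PET * x * nL - V_NF * nN
  vcf_atp   <- atp_left / aC
  vcf_nadph <- nadph_left / nC
  i <- which.min(abs(vcf_atp - vcf_nadph))
  list(x_LPET = x[i], V_CF = max(0, (vcf_atp[i] + vcf_nadph[i]) / 2),
       residual = abs(vcf_atp[i] - vcf_nadph[i]))
}

# Energy-budget bookkeeping for a flux row: ATP and NADPH
# production - consumption (RP ATP is waste heat and excluded).
energy_residuals <- function(V_PET, bud, params) {
  aL <- params$atp_per_e_LPET; aA <- params$atp_per_e_AET
  nL <- params$nadph_per_e_LPET
  atp_supply <- V_PET * (bud$x_LPET * aL + (1 - bud$x_LPET) * aA) +
    bud$V_RESP * params$atp_per_C_RESP
  atp_use <- params$atp_maintenance + bud$V_NF * params$atp_per_N_NF +
    bud$V_CF * params$atp_per_C_CF
  nadph_supply <- V_PET * bud$x_LPET * nL
  nadph_use <- bud$V_NF * params$nadph_per_N_NF +
    bud$V_CF * params$nadph_per_C_CF
  c(atp = atp_supply - atp_use, nadph = nadph_supply - nadph_use)
}
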