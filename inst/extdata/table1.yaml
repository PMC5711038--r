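# Default experiment configuration: published parameter set.
# Concentrations in nM, rates in 1/s; kon of substrates in 1/M/s.
# Kca is derived from detailed balance (Kca = Kca_prime * Ksr / Ksr_prime).
experiment: table1_consistency
params:
  Ksr: 2.25e-4        # Cul1.SR dissociation constant
  ksr: 9.0e-7         # Cul1.SR dissociation rate
  Ksr_prime: 650      # SR dissociation constant from the ternary complex
  ksr_prime: 1.3      # SR dissociation rate from the ternary complex
  Kca_prime: 50       # Cand1 dissociation constant from the ternary complex
  kca_prime: 0.04     # Cand1 dissociation rate from the ternary complex
  kca: 1.0e-5         # Cul1.Cand1 dissociation rate
  gamma: 1
totals:
  cul1: 300
  cand1: 390
  sr: [100, 560]
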