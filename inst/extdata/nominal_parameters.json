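{
  "description": "Nominal Balloon model parameterization (Friston et al. 2000 values), theta convention with reciprocals for alpha and tau.",
  "theta": {
    "theta1": 5,
    "theta2": 0.5,
    "theta3": 1.25,
    "theta4": 2.5,
    "theta5": 1,
    "theta6": 0.8,
    "theta7": 0.02
  },
  "physical": {
    "alpha": 0.2,
    "epsilon": 0.5,
    "kappa_s": 1.25,
    "kappa_f": 2.5,
    "tau": 1,
    "E0": 0.8,
    "V0": 0.02
  }
}
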