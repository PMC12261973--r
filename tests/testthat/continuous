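{
  "settings": {
    "randomization": "cluster",
    "outcome": "continuous",
    "link": "identity",
    "rho": 0.2,
    "N": 44,
    "M_k": [12, 6, 4, 2],
    "balance": "strict",
    "design_mode": "fixed",
    "reps": 10,
    "seed": 3,
    "alpha": 0.05,
    "beta1": 0.25,
    "sigma2": 1,
    "pi_I": 0.3,
    "pi_C": 0.4
  },
  "summary": [
    {
      "working": "independence",
      "reps": 10,
      "n_converged": 10,
      "nonconvergence_rate": 0,
      "npd_rate": 0,
      "median_deff_obs": 1.27337435022142,
      "deff_exp": 1.27272727272727,
      "median_rel_diff_pct": 0.0508418031114931,
      "power_obs": 0,
      "power_exp": 0.110050051915199,
      "power_diff_pp": -11.0050051915199,
      "clamped_per_rep": 0
    },
    {
      "working": "exchangeable",
      "reps": 10,
      "n_converged": 10,
      "nonconvergence_rate": 0,
      "npd_rate": 0,
      "median_deff_obs": 1.09922693020223,
      "deff_exp": 1.23694779116466,
      "median_rel_diff_pct": -11.1339267466377,
      "power_obs": 0.1,
      "power_exp": 0.111940774333162,
      "power_diff_pp": -1.19407743331621,
      "clamped_per_rep": 0
    }
  ]
}
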