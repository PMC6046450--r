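{
  "n_nests": 4,
  "n_cf_pairs": 1,
  "nestlings_per_nest": 6,
  "n_otus": 60,
  "n_contaminants": 6,
  "phylum_props": [0.3, 0.28, 0.3, 0.07, 0.05],
  "firmicutes_up": 2,
  "proteobacteria_down": 0.35,
  "diversity_drop": 0.6,
  "tail_exponent": 8,
  "lambda": 0.7,
  "lambda_concentration": 12,
  "nestmate_influence": 0.3,
  "nest_concentration": 50,
  "bird_concentration": 35,
  "otu_lognormal_sd": 1.4,
  "depth": 2000,
  "n_blanks": 2,
  "blank_rate": 50,
  "n_negatives": 2,
  "contaminant_neg_mean": 80,
  "contaminant_trace_rate": 0.2,
  "negative_crosstalk": 100,
  "sma_slope": 1.87,
  "mean_tarsus": 19.3,
  "tarsus_sd": 0.6,
  "mass_noise_sd": 0.015,
  "condition_coupling": 0.15,
  "neg_gain_frac": 0.025,
  "seed": 20
}
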